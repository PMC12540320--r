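# 1-D CNN family: SE block, forward pass, gradients, training loop.

# reference forward pass written independently of the compiled backend
r_forward <- function(spec, p, xmat) {
  N <- nrow(xmat); L <- spec$n_bands
  A <- matrix(as.vector(t(xmat)), N * L, 1)
  shift <- function(M, o) {
    out <- matrix(0, nrow(M), ncol(M))
    for (n in seq_len(N)) {
      rows <- ((n - 1) * L + 1):(n * L)
      src <- rows + o
      ok <- src >= rows[1] & src <= rows[L]
      out[rows[ok], ] <- M[src[ok], , drop = FALSE]
    }
    out
  }
  for (l in seq_len(spec$n_conv)) {
    M <- cbind(shift(A, -1), A, shift(A, +1))
    A <- pmax(sweep(M %*% p$conv_w[[l]], 2, p$conv_b[[l]], "+"), 0)
  }
  C <- ncol(A)
  if (spec$use_se) {
    for (n in seq_len(N)) {
      rows <- ((n - 1) * L + 1):(n * L)
      map <- t(A[rows, , drop = FALSE])
      A[rows, ] <- t(se_block(map, p$se_w1, p$se_b1, p$se_w2, p$se_b2))
    }
  }
  Fm <- matrix(0, N, L * C)
  for (c in seq_len(C))
    Fm[, ((c - 1) * L + 1):(c * L)] <- t(matrix(A[, c], L, N))
  H1 <- pmax(sweep(Fm %*% p$fc1_w, 2, p$fc1_b, "+"), 0)
  sweep(H1 %*% p$fc2_w, 2, p$fc2_b, "+")
}

tiny_spec <- function(variant = "cnn2c_se") {
  model_spec(variant, n_classes = 3L, n_bands = 12L,
             conv_channels = c(2L, 4L, 4L)[1:switch(variant, cnn1c = 1,
                                                    cnn3c = 3, 2)],
             fc_width = 5L, se_ratio = 2L)
}

test_that("se_block matches a step-by-step matrix-arithmetic oracle", {
  set.seed(40)
  C <- 4L; L <- 8L; mid <- 2L
  map <- matrix(rnorm(C * L), C, L)
  w1 <- matrix(rnorm(C * mid), C, mid); b1 <- rnorm(mid)
  w2 <- matrix(rnorm(mid * C), mid, C); b2 <- rnorm(C)
  out <- se_block(map, w1, b1, w2, b2)
  # oracle: squeeze -> bottleneck -> gates, written out element by element
  s <- sapply(seq_len(C), function(c) mean(map[c, ]))
  z1 <- sapply(seq_len(mid), function(j) sum(w1[, j] * s) + b1[j])
  h <- ifelse(z1 > 0, z1, 0)
  g <- sapply(seq_len(C), function(c) 1 / (1 + exp(-(sum(w2[, c] * h) + b2[c]))))
  expect_equal(attr(out, "gates"), g, tolerance = 1e-12)
  for (c in seq_len(C))
    expect_equal(out[c, ], map[c, ] * g[c], tolerance = 1e-12)
  expect_true(all(g > 0 & g < 1))
})

test_that("se_block limits: saturated gates give identity, constant channels pool to v", {
  map <- matrix(c(rep(2.5, 6), rep(-1, 6)), 2, 6, byrow = TRUE)
  # huge positive excitation output -> gates ~ 1 -> identity map
  w1 <- matrix(1, 2, 1); b1 <- 0
  w2 <- matrix(0, 1, 2); b2 <- c(50, 50)
  out <- se_block(map, w1, b1, w2, b2)
  expect_equal(unclass(out), map, tolerance = 1e-10, ignore_attr = TRUE)
  # squeeze of a constant channel is exactly its value: visible through a
  # pass-through bottleneck
  w1p <- diag(2); b1p <- c(0, 0)
  out2 <- se_block(map, w1p, b1p, matrix(c(1, 0, 0, 1), 2, 2), c(0, 0))
  # channel 1 pools to 2.5 -> relu 2.5; channel 2 pools to -1 -> relu 0
  expect_equal(attr(out2, "gates"),
               c(1 / (1 + exp(-2.5)), 1 / (1 + exp(0))), tolerance = 1e-12)
})

test_that("compiled forward equals the R reference for every variant", {
  set.seed(41)
  x <- matrix(rnorm(7 * 12), 7, 12)
  for (vn in c("cnn1c", "cnn2c", "cnn3c", "cnn2c_se")) {
    spec <- tiny_spec(vn)
    p <- cnn_init(spec, 1)
    got <- seedspec:::.cnn_forward_cpp(p, seedspec:::.cnn_conf(spec), x)
    expect_equal(dim(got), c(7L, 3L))
    expect_equal(got, r_forward(spec, p, x), tolerance = 1e-5,
                 label = vn)
  }
})

test_that("scores of a zero-weight model give the uniform softmax", {
  spec <- model_spec("cnn2c", n_classes = 30L, n_bands = 20L,
                     conv_channels = c(2L, 3L), fc_width = 4L)
  p <- cnn_init(spec, 1)
  p$fc2_w[] <- 0; p$fc2_b[] <- 0
  sc <- seedspec:::.cnn_forward_cpp(p, seedspec:::.cnn_conf(spec),
                                    matrix(rnorm(5 * 20), 5, 20))
  pr <- softmax_rows(sc)
  expect_equal(pr, matrix(1 / 30, 5, 30), tolerance = 1e-7)
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)
  expect_equal(cross_entropy(pr, sample(1:30, 5, TRUE)), log(30),
               tolerance = 1e-6)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  spec <- tiny_spec("cnn2c_se")
  x <- matrix(rnorm(8 * 12), 8, 12)
  y <- sample(1:3, 8, replace = TRUE)
  conf <- seedspec:::.cnn_conf(spec)
  p <- cnn_init(spec, 1)
  g <- seedspec:::.cnn_grad_cpp(p, conf, x, y)
  loss_of <- function(pp)
    cross_entropy(softmax_rows(seedspec:::.cnn_forward_cpp(pp, conf, x)), y)
  eps <- 1e-3
  set.seed(43)
  for (name in c("conv_w", "fc1_w", "fc2_w", "se_w1", "se_w2", "fc2_b",
                 "se_b1", "conv_b")) {
    for (l in if (name %in% c("conv_w", "conv_b")) 1:2 else NA) {
      w <- if (is.na(l)) p[[name]] else p[[name]][[l]]
      gw <- as.vector(if (is.na(l)) g[[name]] else g[[name]][[l]])
      idx <- sample(length(w), min(4, length(w)))
      for (i in idx) {
        p2 <- p; p3 <- p
        if (is.na(l)) { p2[[name]][i] <- w[i] + eps; p3[[name]][i] <- w[i] - eps }
        else { p2[[name]][[l]][i] <- w[i] + eps; p3[[name]][[l]][i] <- w[i] - eps }
        fd <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
        expect_equal(gw[i], fd, tolerance = 0.05,
                     label = sprintf("grad %s[%s][%d]", name, l, i))
      }
    }
  }
})

test_that("training memorises a small separable problem and is reproducible", {
  v <- make_varieties(2, rng_seed = 50, class_sep = 2)
  s <- gen_spectrum_set(v, 40, zero_noise(seed = 50))
  spec <- model_spec("cnn2c", n_classes = 2L, n_bands = 320L)
  ts <- train_spec(iterations = 500L, rng_seed = 1)
  m <- cnn_train(spec, s, ts)
  expect_equal(mean(cnn_predict(m, s) == s$labels), 1)
  expect_length(m$loss_trace, 500L)
  expect_true(all(is.finite(m$loss_trace)))
  expect_lt(tail(m$loss_trace, 1), 0.05)
  # determinism: identical trace and weights for a repeated run
  m2 <- cnn_train(spec, s, ts)
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_identical(m$params$fc1_w, m2$params$fc1_w)
})

test_that("early stopping halts on a stagnant validation loss", {
  v <- make_varieties(2, rng_seed = 51, class_sep = 2)
  s <- gen_spectrum_set(v, 30, zero_noise(seed = 51))
  sp <- split_4to1(s, 1)
  spec <- model_spec("cnn1c", n_classes = 2L, n_bands = 320L)
  m <- cnn_train(spec, sp$train,
                 train_spec(iterations = 3000L, rng_seed = 1,
                            early_stop_patience = 3L, eval_every = 50L),
                 validation = sp$test)
  expect_lt(m$iterations_run, 3000L)
  expect_gt(m$best_iter, 0L)
  expect_equal(mean(cnn_predict(m, sp$test) == sp$test$labels), 1)
})

test_that("dropout and L1 run and remain deterministic", {
  v <- make_varieties(2, rng_seed = 52, class_sep = 2)
  s <- gen_spectrum_set(v, 20, zero_noise(seed = 52))
  spec <- model_spec("cnn1c", n_classes = 2L, n_bands = 320L)
  ts <- train_spec(iterations = 120L, rng_seed = 9, dropout_p = 0.3,
                   l1_lambda = 1e-4)
  m1 <- cnn_train(spec, s, ts)
  m2 <- cnn_train(spec, s, ts)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_true(all(is.finite(m1$loss_trace)))
})

test_that("model contracts: band mismatch and bad labels error", {
  s <- tiny_set()
  spec <- model_spec("cnn1c", n_classes = 2L, n_bands = 320L)
  expect_error(cnn_train(spec, s), "n_classes")
  spec2 <- model_spec("cnn1c", n_classes = 3L, n_bands = 10L)
  expect_error(cnn_train(spec2, s), "bands")
  expect_error(model_spec("cnn2c", conv_channels = 16L), "channel")
})

test_that("the SE ratio ablation produces the study's table layout", {
  s <- tiny_set(n_classes = 3L, seeds_per_class = 20L)
  plan <- make_folds(s, 3L, rng_seed = 1)
  tab <- ablate_se_ratio(s, ratios = c(4L, 16L), plan = plan,
                         tspec = train_spec(iterations = 60L, rng_seed = 1),
                         n_classes = 3L)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("ratio", "train", "test", "precision", "recall",
                      "f1", "time"))
  reports <- attr(tab, "reports")
  expect_length(reports, 2L)
  expect_equal(reports[[1]]$n_folds, 3L)
})
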