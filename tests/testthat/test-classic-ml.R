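# KNN (transforms, distances) and the extreme learning machine.

test_that("transforms learn their statistics from training rows only", {
  train <- matrix(c(0, 1, 2, 3), 2, 2)   # per-band ranges [0,1], [2,3]
  test <- matrix(c(2, 5), 1, 2)           # outside the training range
  tf <- fit_transform("min_max", train)
  expect_equal(apply_transform(tf, test), matrix(c(2, 3), 1, 2))
  tf <- fit_transform("mean_center", train)
  expect_equal(apply_transform(tf, test), matrix(c(1.5, 2.5), 1, 2))
  # log transform is finite on noisy (slightly negative) reflectance
  expect_true(all(is.finite(apply_transform(fit_transform("log", train),
                                            matrix(c(-0.01, 0.5), 1)))))
})

test_that("distances satisfy identity and symmetry", {
  set.seed(30)
  m <- matrix(rnorm(40), 8, 5)
  for (kind in c("standardized_euclidean", "correlation", "mahalanobis")) {
    d <- spectral_distances(m, m, kind)
    expect_equal(unname(diag(d)), rep(0, 8), tolerance = 1e-6)
    expect_equal(d, t(d), tolerance = 1e-8)
  }
})

test_that("full shrinkage Mahalanobis reduces to standardized Euclidean", {
  set.seed(31)
  tr <- matrix(rnorm(200), 20, 10)
  te <- matrix(rnorm(50), 5, 10)
  dm <- spectral_distances(te, tr, "mahalanobis", cov_shrinkage = 1)
  de <- spectral_distances(te, tr, "standardized_euclidean")
  # lambda = 1 shrinks to the diagonal of the covariance; the only
  # difference is the n vs n-1 variance normalisation, a global factor
  expect_equal(dm / de, matrix(sqrt(20 / 19), 5, 20), tolerance = 1e-8)
})

test_that("knn resolves the hand-enumerated three-point example", {
  g <- wavelength_grid(2, 400, 500)
  train <- spectrum_set(rbind(c(0, 0), c(0, 1), c(5, 5)), c(1L, 1L, 2L), g)
  test <- spectrum_set(rbind(c(0, 0.4)), 3L, g)
  # brute force: distances 0.4, 0.6, ~6.8 -> labels 1,1,2 -> majority 1
  expect_equal(knn_predict(train, test, k = 3,
                           distance = "standardized_euclidean"), 1L)
  # single training point, k = 1
  one <- spectrum_set(rbind(c(1, 2)), 9L, g)
  expect_equal(knn_predict(one, test, k = 1), 9L)
  expect_error(knn_predict(one, test, k = 2), "k must be")
})

test_that("knn at k=1 classifies its own training set perfectly", {
  s <- tiny_set()
  for (tf in c("none", "mean_center", "min_max", "log"))
    for (d in c("standardized_euclidean", "correlation", "mahalanobis")) {
      pred <- knn_predict(s, s, k = 1, transform = tf, distance = d)
      expect_equal(pred, s$labels,
                   label = sprintf("k=1 self, %s/%s", tf, d))
    }
})

test_that("knn vote ties break by summed distance then smaller label", {
  g <- wavelength_grid(1, 400, 400)
  # two labels, one neighbour each, equidistant -> distance sum ties ->
  # smaller label wins
  train <- spectrum_set(rbind(1, 3), c(2L, 1L), g)
  expect_equal(knn_predict(train, spectrum_set(rbind(2), 1L, g), k = 2),
               1L)
  # closer pair wins when sums differ
  train2 <- spectrum_set(rbind(0.8, 1.2, 3, 3.1), c(2L, 2L, 1L, 1L), g)
  expect_equal(knn_predict(train2, spectrum_set(rbind(1), 1L, g), k = 4),
               2L)
})

test_that("knn grid search sweeps the full factorial and is reproducible", {
  s <- tiny_set()
  tab <- knn_grid_search(s, k_range = 1:4,
                         transforms = c("mean_center", "log"),
                         distances = c("standardized_euclidean",
                                       "correlation"),
                         n_repeats = 2, rng_seed = 42)
  expect_equal(nrow(tab), 4 * 2 * 2)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  # well-separated classes: perfect for small k
  expect_true(all(tab$accuracy[tab$k <= 2] == 1))
  tab2 <- knn_grid_search(s, k_range = 1:4,
                          transforms = c("mean_center", "log"),
                          distances = c("standardized_euclidean",
                                        "correlation"),
                          n_repeats = 2, rng_seed = 42)
  expect_identical(tab, tab2)
})

test_that("ELM output weights solve the least-squares problem", {
  s <- tiny_set()
  model <- elm_train(s, hidden_nodes = 20, rng_seed = 3)
  h <- seedspec:::.elm_hidden(s$spectra, model$input_weights, model$biases)
  targets <- matrix(0, nrow(h), length(model$classes))
  targets[cbind(seq_len(nrow(h)), match(s$labels, model$classes))] <- 1
  # normal-equations oracle
  beta_ne <- solve(crossprod(h), crossprod(h, targets))
  r_model <- norm(h %*% model$output_weights - targets, "F")
  r_ne <- norm(h %*% beta_ne - targets, "F")
  expect_lt(abs(r_model - r_ne) / r_ne, 1e-8)
  # any perturbation increases the residual
  set.seed(32)
  for (i in 1:5) {
    pert <- model$output_weights +
      matrix(rnorm(length(model$output_weights), 0, 0.01),
             nrow(model$output_weights))
    expect_gte(norm(h %*% pert - targets, "F"), r_model)
  }
})

test_that("a square invertible hidden layer interpolates exactly", {
  set.seed(33)
  g <- wavelength_grid(6, 400, 900)
  x <- matrix(rnorm(8 * 6), 8, 6)
  s <- spectrum_set(x, rep(1:4, 2), g)
  model <- elm_train(s, hidden_nodes = 8, rng_seed = 1)
  h <- seedspec:::.elm_hidden(x, model$input_weights, model$biases)
  targets <- matrix(0, 8, 4)
  targets[cbind(1:8, rep(1:4, 2))] <- 1
  expect_equal(h %*% model$output_weights, targets, tolerance = 1e-6)
  expect_equal(elm_predict(model, s), s$labels)
})

test_that("ELM is deterministic and nested in hidden_nodes", {
  s <- tiny_set()
  m1 <- elm_train(s, 30, rng_seed = 7)
  m2 <- elm_train(s, 30, rng_seed = 7)
  expect_identical(m1$output_weights, m2$output_weights)
  # shared seed prefix: first nodes of a wider net equal the narrower net
  m3 <- elm_train(s, 45, rng_seed = 7)
  expect_identical(m3$input_weights[, 1:30], m1$input_weights)
  expect_identical(m3$biases[1:30], m1$biases)
  # and training residual never increases with width
  res <- sapply(c(10, 20, 40), function(hn) {
    m <- elm_train(s, hn, rng_seed = 7)
    h <- seedspec:::.elm_hidden(s$spectra, m$input_weights, m$biases)
    t <- matrix(0, nrow(h), length(m$classes))
    t[cbind(seq_len(nrow(h)), match(s$labels, m$classes))] <- 1
    norm(h %*% m$output_weights - t, "F")
  })
  expect_true(all(diff(res) <= 1e-8))
})

test_that("ELM predictions are invariant to training-row order", {
  s <- tiny_set()
  perm <- sample(seq_along(s$labels))
  sp <- subset_spectra(s, perm)
  m1 <- elm_train(s, 25, rng_seed = 2)
  m2 <- elm_train(sp, 25, rng_seed = 2)
  expect_equal(elm_predict(m1, s), elm_predict(m2, s), tolerance = 0)
})

test_that("the node sweep {100, 150, 200} runs and reports accuracies", {
  s <- tiny_set(n_classes = 4L, seeds_per_class = 30L)
  sp <- split_4to1(s, 1)
  accs <- sapply(c(100L, 150L, 200L), function(hn) {
    m <- elm_train(sp$train, hn, rng_seed = 1)
    mean(elm_predict(m, sp$test) == sp$test$labels)
  })
  expect_length(accs, 3L)
  expect_true(all(accs > 0.5))  # easy synthetic classes
})
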