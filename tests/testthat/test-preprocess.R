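# Smoothing operators and Savitzky-Golay derivatives.

test_that("SG window-5 order-2 weights equal the classic (-3,12,17,12,-3)/35", {
  expect_equal(sg_coefficients(5, 2), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
})

test_that("SG weights agree with a per-window least-squares fit oracle", {
  # oracle: fit the polynomial with lm() over one window and read the
  # centre value / derivatives of the fitted polynomial
  set.seed(20)
  for (cfg in list(c(7, 2), c(11, 3), c(9, 4))) {
    w <- cfg[1]; p <- cfg[2]
    h <- (w - 1) / 2
    y <- rnorm(w)
    t <- (-h):h
    fit <- lm(y ~ poly(t, p, raw = TRUE))
    co <- coef(fit)
    expect_equal(sum(sg_coefficients(w, p, 0) * y), unname(co[1]),
                 tolerance = 1e-8)
    expect_equal(sum(sg_coefficients(w, p, 1) * y), unname(co[2]),
                 tolerance = 1e-8)
    if (p >= 2)
      expect_equal(sum(sg_coefficients(w, p, 2) * y), unname(2 * co[3]),
                   tolerance = 1e-8)
  }
})

test_that("SG smoothing fixes polynomials of degree <= polyorder at interior", {
  x <- seq_len(41)
  for (cfg in list(c(5, 2), c(11, 3), c(13, 4))) {
    w <- cfg[1]; p <- cfg[2]
    h <- (w - 1) / 2
    interior <- (h + 1):(41 - h)
    for (deg in 0:p) {
      y <- (x / 10)^deg
      expect_equal(sg_smooth(y, w, p)[interior], y[interior],
                   tolerance = 1e-9)
    }
  }
})

test_that("SG smoothing matches signal::sgolayfilt at interior bands", {
  skip_if_not_installed("signal")
  set.seed(21)
  y <- cumsum(rnorm(60))
  got <- sg_smooth(y, 11, 3)
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  interior <- 6:55
  expect_equal(got[interior], ref[interior], tolerance = 1e-10)
})

test_that("all smoothers leave constants unchanged", {
  y <- rep(0.42, 30)
  expect_equal(sg_smooth(y), y)
  expect_equal(gaussian_smooth(y), y)
  expect_equal(median_smooth(y), y)
  expect_equal(moving_average(y), y)
})

test_that("gaussian kernel sums to one and matches a brute-force window sum", {
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- gaussian_smooth(imp, sigma = 2, window = 11)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # brute-force oracle at an interior point of a random spectrum
  set.seed(22)
  y <- runif(41)
  h <- 5
  w <- dnorm(-h:h, sd = 2); w <- w / sum(w)
  i <- 21
  expect_equal(gaussian_smooth(y, 2, 11)[i], sum(w * y[(i - h):(i + h)]),
               tolerance = 1e-12)
})

test_that("median filter matches sort-and-pick and handles its examples", {
  expect_equal(median_smooth(c(1, 9, 1), 3)[2], 1)
  mono <- seq(0.1, 0.9, length.out = 20)
  expect_equal(median_smooth(mono, 5)[3:18], mono[3:18])
  set.seed(23)
  y <- runif(30)
  got <- median_smooth(y, 5)
  pad <- c(y[3:2], y, y[29:28])
  oracle <- sapply(1:30, function(i) median(pad[i:(i + 4)]))
  expect_equal(got, oracle)
})

test_that("moving average matches direct summation", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3)[2:4], c(2, 3, 4))
  set.seed(24)
  y <- rnorm(25)
  pad <- c(y[3:2], y, y[24:23])
  oracle <- sapply(1:25, function(i) mean(pad[i:(i + 4)]))
  expect_equal(moving_average(y, 5), oracle, tolerance = 1e-12)
})

test_that("SG derivatives recover slopes and curvatures at interior bands", {
  # mirror padding reflects the signal, so derivative exactness holds away
  # from the edges
  x <- seq_len(41)
  h <- 5
  interior <- (h + 1):(41 - h)
  expect_equal(sg_derivative(3 + 0.25 * x, 1, 11, 3)[interior],
               rep(0.25, length(interior)), tolerance = 1e-9)
  y <- 0.05 * x^2
  expect_equal(sg_derivative(y, 2, 11, 3)[interior],
               rep(0.1, length(interior)), tolerance = 1e-9)
  # agrees with central differences on a smooth curve
  s <- sin(x / 7)
  d1 <- sg_derivative(s, 1, 9, 3)
  cd <- (s[3:41] - s[1:39]) / 2
  expect_lt(max(abs(d1[5:37] - cd[4:36])), 5e-3)
  # spacing scales derivative units
  expect_equal(sg_derivative(3 + 0.25 * x, 1, 11, 3, spacing = 2)[interior],
               rep(0.125, length(interior)), tolerance = 1e-9)
})

test_that("smoothers are equivariant to shifts and (where linear) to scale", {
  set.seed(25)
  y <- runif(40)
  for (f in list(function(z) sg_smooth(z, 9, 3),
                 function(z) gaussian_smooth(z, 1.5, 9),
                 function(z) moving_average(z, 5),
                 function(z) median_smooth(z, 5))) {
    expect_equal(f(y + 0.7), f(y) + 0.7, tolerance = 1e-10)
  }
  for (f in list(function(z) sg_smooth(z, 9, 3),
                 function(z) gaussian_smooth(z, 1.5, 9),
                 function(z) moving_average(z, 5))) {
    expect_equal(f(3.2 * y), 3.2 * f(y), tolerance = 1e-10)
  }
})

test_that("apply_preprocess maps row-wise and preserves structure", {
  s <- tiny_set()
  expect_equal(apply_preprocess(preprocess_config("none"), s)$spectra,
               s$spectra)
  for (m in c("sg", "gaussian", "median", "moving_average",
              "derivative1", "derivative2")) {
    out <- apply_preprocess(preprocess_config(m), s)
    expect_equal(dim(out$spectra), dim(s$spectra))
    expect_identical(out$labels, s$labels)
    expect_identical(out$grid$values, s$grid$values)
  }
  # row-wise: first row equals smoothing of first spectrum alone
  out <- apply_preprocess(preprocess_config("sg"), s)
  expect_equal(out$spectra[1, ], sg_smooth(s$spectra[1, ], 11, 3))
})

test_that("invalid preprocessing configurations are rejected", {
  expect_error(preprocess_config("sg", window = 4), "odd")
  expect_error(preprocess_config("sg", window = 3, polyorder = 3), "polyorder")
  expect_error(preprocess_config("gaussian", sigma = 0), "sigma")
  expect_error(sg_smooth(1:5, 11, 3), "shorter")
  expect_error(sg_derivative(1:30, 3), "order")
})
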