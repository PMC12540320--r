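# Spectral preprocessing: the four smoothers and Savitzky-Golay
# derivatives applied per spectrum before classification.
#
# All operators use mirror padding at the edges so a 320-band spectrum
# stays 320 bands, and all are implemented as vectorised convolutions over
# the rows of a spectrum matrix (median filtering excepted, being
# nonlinear).

#' Savitzky-Golay convolution weights
#'
#' Solves the local least-squares polynomial fit directly: for window
#' positions `-h..h` the returned weights `w` satisfy
#' `sum(w * y) = d-th derivative (in window steps) of the degree-`polyorder`
#' polynomial fitted to `y`, evaluated at the window centre.
#'
#' @param window odd window length (bands).
#' @param polyorder polynomial degree, `< window`.
#' @param deriv derivative order (0 = smoothing).
#' @return numeric weight vector of length `window`.
#' @export
#' @examples
#' round(sg_coefficients(5, 2) * 35)  # the classic (-3, 12, 17, 12, -3)
sg_coefficients <- function(window, polyorder, deriv = 0L) {
  window <- check_odd_window(window)
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  h <- (window - 1L) %/% 2L
  t <- (-h):h
  V <- outer(t, 0:polyorder, `^`)
  # row deriv+1 of the pseudo-inverse gives the fit coefficient a_deriv
  a <- solve(crossprod(V), t(V))[deriv + 1L, ]
  a * factorial(deriv)
}

# Convolve each row of `mat` with weights `w` (odd length), mirror-padded.
.conv_rows <- function(mat, w) {
  p <- (length(w) - 1L) %/% 2L
  n <- nrow(mat); b <- ncol(mat)
  if (b <= p) stop("spectrum shorter than window")
  pad <- cbind(mat[, (p + 1L):2L, drop = FALSE], mat,
               mat[, (b - 1L):(b - p), drop = FALSE])
  out <- matrix(0, n, b)
  for (j in seq_along(w))
    out <- out + w[j] * pad[, j:(j + b - 1L), drop = FALSE]
  out
}

.as_row_matrix <- function(x) {
  if (is.matrix(x)) list(m = x, vec = FALSE)
  else list(m = matrix(x, nrow = 1L), vec = TRUE)
}

.unwrap <- function(m, was_vec) if (was_vec) drop(m) else m

#' Spectral smoothers
#'
#' Row-wise smoothing of spectra with mirror-padded edges. `x` may be a
#' single spectrum (vector) or a matrix with one spectrum per row.
#'
#' * `sg_smooth()`: local least-squares polynomial (Savitzky-Golay) fit,
#'   exact on polynomials of degree `<= polyorder`.
#' * `gaussian_smooth()`: convolution with a truncated, renormalised
#'   Gaussian kernel (`sigma` in bands).
#' * `median_smooth()`: sliding-window median.
#' * `moving_average()`: centred boxcar mean.
#'
#' @param x numeric vector or matrix of spectra (rows).
#' @param window odd window length in bands.
#' @param polyorder SG polynomial degree (`< window`).
#' @param sigma Gaussian scale in bands (`> 0`).
#' @return smoothed spectrum/spectra, same shape as `x`.
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 3L) {
  xx <- .as_row_matrix(x)
  .unwrap(.conv_rows(xx$m, sg_coefficients(window, polyorder, 0L)), xx$vec)
}

#' @rdname sg_smooth
#' @export
gaussian_smooth <- function(x, sigma = 2, window = 11L) {
  if (sigma <= 0) stop("sigma must be positive")
  window <- check_odd_window(window)
  h <- (window - 1L) %/% 2L
  w <- stats::dnorm((-h):h, sd = sigma)
  w <- w / sum(w)
  xx <- .as_row_matrix(x)
  .unwrap(.conv_rows(xx$m, w), xx$vec)
}

#' @rdname sg_smooth
#' @export
median_smooth <- function(x, window = 5L) {
  window <- check_odd_window(window)
  p <- (window - 1L) %/% 2L
  xx <- .as_row_matrix(x)
  m <- xx$m
  b <- ncol(m)
  out <- t(apply(m, 1L, function(row) {
    pad <- mirror_pad(row, p)
    vapply(seq_len(b),
           function(i) stats::median(pad[i:(i + window - 1L)]), 0)
  }))
  .unwrap(out, xx$vec)
}

#' @rdname sg_smooth
#' @export
moving_average <- function(x, window = 5L) {
  window <- check_odd_window(window)
  xx <- .as_row_matrix(x)
  .unwrap(.conv_rows(xx$m, rep(1 / window, window)), xx$vec)
}

#' Savitzky-Golay spectral derivative
#'
#' Derivative of the local fitted polynomial at the window centre, scaled
#' by the band spacing, so units are reflectance per nm (for order 1) or
#' per nm^2 (order 2).
#'
#' @param x spectrum vector or matrix of row spectra.
#' @param order derivative order, 1 or 2.
#' @param window odd window length.
#' @param polyorder fit degree (`>= order`, `< window`).
#' @param spacing band spacing used to scale from per-band to per-nm units
#'   (default 1 = per band).
#' @return derivative spectrum/spectra, same shape as `x`.
#' @export
sg_derivative <- function(x, order = 1L, window = 11L, polyorder = 3L,
                          spacing = 1) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  w <- sg_coefficients(window, polyorder, order) / spacing^order
  xx <- .as_row_matrix(x)
  .unwrap(.conv_rows(xx$m, w), xx$vec)
}

#' Preprocessing configuration
#'
#' @param method one of `"none"`, `"sg"`, `"gaussian"`, `"median"`,
#'   `"moving_average"`, `"derivative1"`, `"derivative2"`.
#' @param window odd window length in bands.
#' @param polyorder SG polynomial degree.
#' @param sigma Gaussian scale in bands.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(method = c("none", "sg", "gaussian", "median",
                                         "moving_average", "derivative1",
                                         "derivative2"),
                              window = NULL, polyorder = 3L, sigma = 2) {
  method <- match.arg(method)
  window <- window %||% switch(method,
                               sg = 11L, gaussian = 11L, median = 5L,
                               moving_average = 5L, derivative1 = 11L,
                               derivative2 = 11L, 1L)
  if (method != "none") {
    window <- check_odd_window(window)
    if (method %in% c("sg", "derivative1", "derivative2") &&
        polyorder >= window)
      stop("polyorder must be < window")
    if (method == "gaussian" && sigma <= 0) stop("sigma must be positive")
  }
  structure(list(method = method, window = window,
                 polyorder = as.integer(polyorder), sigma = sigma),
            class = "preprocess_config")
}

#' Apply a preprocessing configuration to a spectrum set
#'
#' Row-wise application; labels and the wavelength grid are untouched.
#'
#' @param config a [preprocess_config()].
#' @param set a [spectrum_set()].
#' @return the preprocessed [spectrum_set()].
#' @export
apply_preprocess <- function(config, set) {
  m <- switch(config$method,
    none = set$spectra,
    sg = sg_smooth(set$spectra, config$window, config$polyorder),
    gaussian = gaussian_smooth(set$spectra, config$sigma, config$window),
    median = median_smooth(set$spectra, config$window),
    moving_average = moving_average(set$spectra, config$window),
    derivative1 = sg_derivative(set$spectra, 1L, config$window,
                                config$polyorder,
                                spacing = mean(diff(set$grid$values))),
    derivative2 = sg_derivative(set$spectra, 2L, config$window,
                                config$polyorder,
                                spacing = mean(diff(set$grid$values))))
  spectrum_set(m, set$labels, set$grid,
               provenance = c(set$provenance,
                              paste("preprocess:", config$method)))
}
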