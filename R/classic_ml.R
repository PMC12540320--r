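# Classical baselines: k-nearest neighbours with configurable transform
# and distance, and the extreme learning machine.

#' Fit a per-band data transform on training spectra
#'
#' Transform statistics are learned from the training rows only, then
#' applied unchanged to test rows (strict fit/apply separation).
#'
#' * `mean_center`: subtract the per-band training mean.
#' * `min_max`: rescale each band to \[0, 1\] using training min/max.
#' * `log`: `log(x + 1e-6)` (no fitted statistics); intended for
#'   reflectance in (0, 1].
#' * `none`: identity.
#'
#' @param kind transform name.
#' @param train_matrix training spectra (rows = samples).
#' @return an object of class `transform_spec`.
#' @export
fit_transform <- function(kind = c("none", "mean_center", "min_max", "log"),
                          train_matrix) {
  kind <- match.arg(kind)
  params <- switch(kind,
    none = list(),
    log = list(eps = 1e-6),
    mean_center = list(mean = colMeans(train_matrix)),
    min_max = {
      lo <- apply(train_matrix, 2, min)
      hi <- apply(train_matrix, 2, max)
      rng <- hi - lo
      rng[rng < 1e-12] <- 1
      list(min = lo, range = rng)
    })
  structure(list(kind = kind, params = params), class = "transform_spec")
}

#' @rdname fit_transform
#' @param spec a fitted `transform_spec`.
#' @param m spectra matrix to transform.
#' @export
apply_transform <- function(spec, m) {
  switch(spec$kind,
         none = m,
         log = log(pmax(m, 0) + spec$params$eps),  # reflectance is >= 0

         mean_center = sweep(m, 2, spec$params$mean),
         min_max = sweep(sweep(m, 2, spec$params$min), 2,
                         spec$params$range, "/"))
}

# Ledoit-Wolf-type analytic shrinkage of the sample covariance toward its
# own diagonal; returns the shrunk covariance. With 320 bands and at most
# a few thousand training rows the raw sample covariance is
# ill-conditioned, so Mahalanobis distances use this estimate.
shrunk_covariance <- function(m, lambda = NULL) {
  n <- nrow(m)
  xc <- sweep(m, 2, colMeans(m))
  s <- crossprod(xc) / n
  if (is.null(lambda)) {
    # Schafer-Strimmer estimate of the optimal shrinkage of off-diagonals
    x2 <- crossprod(xc^2) / n
    var_s <- (x2 - s^2) / n
    num <- sum(var_s) - sum(diag(var_s))
    den <- sum(s^2) - sum(diag(s)^2)
    lambda <- if (den <= 0) 1 else min(1, max(0, num / den))
  }
  sh <- (1 - lambda) * s
  diag(sh) <- diag(s)
  attr(sh, "lambda") <- lambda
  sh
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
.sq_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Pairwise distances between test and training spectra
#'
#' * `standardized_euclidean`: Euclidean after scaling each band by its
#'   training standard deviation.
#' * `correlation`: `1 - Pearson correlation` between spectra.
#' * `mahalanobis`: quadratic-form distance under the (shrunk) training
#'   covariance (see `cov_shrinkage`).
#'
#' @param test,train spectra matrices (rows = samples).
#' @param kind distance name.
#' @param cov_shrinkage Mahalanobis shrinkage intensity in \[0, 1\];
#'   `NULL` = analytic (Ledoit-Wolf-type) choice.
#' @return `nrow(test)` x `nrow(train)` distance matrix.
#' @export
spectral_distances <- function(test, train,
                               kind = c("standardized_euclidean",
                                        "correlation", "mahalanobis"),
                               cov_shrinkage = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    standardized_euclidean = {
      s <- apply(train, 2, stats::sd)
      s[s < 1e-12] <- 1
      sqrt(.sq_dists(sweep(test, 2, s, "/"), sweep(train, 2, s, "/")))
    },
    correlation = {
      zr <- function(m) {
        mc <- m - rowMeans(m)  # correlation centres per row, not band
        den <- sqrt(rowSums(mc^2))
        den[den < 1e-12] <- 1
        mc / den
      }
      1 - tcrossprod(zr(test), zr(train))
    },
    mahalanobis = {
      sh <- shrunk_covariance(train, cov_shrinkage)
      u <- chol(sh)
      wt <- function(m) t(backsolve(u, t(m), transpose = TRUE))
      sqrt(.sq_dists(wt(test), wt(train)))
    })
}

#' k-nearest-neighbour classification
#'
#' Majority vote among the `k` nearest training spectra under the
#' configured transform and distance. Vote ties are broken by the smaller
#' summed neighbour distance, then by the smaller class id.
#'
#' @param train,test [spectrum_set()]s.
#' @param k neighbourhood size (`<= nrow(train)`).
#' @param transform transform name (see [fit_transform()]), fitted on the
#'   training rows.
#' @param distance distance name (see [spectral_distances()]).
#' @param cov_shrinkage Mahalanobis shrinkage (`NULL` = analytic).
#' @return integer vector of predicted labels.
#' @export
knn_predict <- function(train, test, k = 17L, transform = "none",
                        distance = "standardized_euclidean",
                        cov_shrinkage = NULL) {
  k <- as.integer(k)
  n <- nrow(train$spectra)
  if (n == 0L) stop("empty training set")
  if (k < 1L || k > n) stop("k must be in 1..nrow(train)")
  tf <- fit_transform(transform, train$spectra)
  tr <- apply_transform(tf, train$spectra)
  te <- apply_transform(tf, test$spectra)
  d <- spectral_distances(te, tr, distance, cov_shrinkage)
  .vote_rows(d, train$labels, k)
}

.vote_rows <- function(d, labels, k) {
  apply(d, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    lab <- labels[nb]
    counts <- table(lab)
    win <- names(counts)[counts == max(counts)]
    if (length(win) > 1L) {
      sums <- vapply(win, function(w) sum(row[nb[lab == as.integer(w)]]), 0)
      win <- win[sums == min(sums)]
    }
    min(as.integer(win))
  })
}

#' Factorial KNN configuration sweep
#'
#' Evaluates every (k, transform, distance) cell over repeated stratified
#' 4:1 splits and reports the mean test accuracy per cell, plus the argmax
#' configuration.
#'
#' @param set a [spectrum_set()].
#' @param k_range candidate neighbourhood sizes.
#' @param transforms,distances candidate names.
#' @param n_repeats number of random stratified splits averaged per cell.
#' @param rng_seed seed for the splits.
#' @return data frame of mean accuracies with attribute `"best"` (the
#'   argmax row).
#' @export
knn_grid_search <- function(set, k_range = 1:20,
                            transforms = c("mean_center", "min_max", "log"),
                            distances = c("standardized_euclidean",
                                          "correlation", "mahalanobis"),
                            n_repeats = 10L, rng_seed = 1L) {
  cells <- expand.grid(k = k_range, transform = transforms,
                       distance = distances, stringsAsFactors = FALSE)
  acc <- matrix(0, nrow(cells), n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- split_4to1(set, rng_seed + r - 1L)
    combos <- unique(cells[c("transform", "distance")])
    for (i in seq_len(nrow(combos))) {
      tf <- fit_transform(combos$transform[i], sp$train$spectra)
      tr <- apply_transform(tf, sp$train$spectra)
      te <- apply_transform(tf, sp$test$spectra)
      d <- spectral_distances(te, tr, combos$distance[i])
      for (k in k_range) {
        pred <- .vote_rows(d, sp$train$labels, k)
        row <- which(cells$k == k &
                       cells$transform == combos$transform[i] &
                       cells$distance == combos$distance[i])
        acc[row, r] <- mean(pred == sp$test$labels)
      }
    }
  }
  cells$accuracy <- rowMeans(acc)
  attr(cells, "best") <- cells[which.max(cells$accuracy), ]
  cells
}

#' Train an extreme learning machine
#'
#' Single hidden layer with sigmoid activation; input weights and biases
#' are drawn uniformly in \[-1, 1\] (per hidden node, so nested node
#' counts share a random-draw prefix for a common seed) and frozen. The
#' output weights are the minimum-norm least-squares solution of
#' `H beta = T` for one-hot targets, obtained via the SVD pseudoinverse.
#'
#' @param train a [spectrum_set()].
#' @param hidden_nodes hidden layer width.
#' @param rng_seed seed for the random hidden layer.
#' @return an object of class `elm_model`.
#' @export
elm_train <- function(train, hidden_nodes = 150L, rng_seed = 1L) {
  hidden_nodes <- as.integer(hidden_nodes)
  if (hidden_nodes < 1L) stop("hidden_nodes must be >= 1")
  x <- train$spectra
  if (nrow(unique(x)) == 1L)
    warning("all training spectra are identical; ELM fit is degenerate")
  b <- ncol(x)
  wb <- with_seed(rng_seed,
                  matrix(runif((b + 1L) * hidden_nodes, -1, 1),
                         b + 1L, hidden_nodes))
  w <- wb[seq_len(b), , drop = FALSE]
  bias <- wb[b + 1L, ]
  classes <- sort(unique(train$labels))
  h <- .elm_hidden(x, w, bias)
  targets <- matrix(0, nrow(x), length(classes))
  targets[cbind(seq_len(nrow(x)), match(train$labels, classes))] <- 1
  beta <- .pinv_solve(h, targets)
  structure(list(input_weights = w, biases = bias, output_weights = beta,
                 classes = classes, hidden_nodes = hidden_nodes,
                 rng_seed = rng_seed),
            class = "elm_model")
}

.elm_hidden <- function(x, w, bias) {
  z <- sweep(x %*% w, 2, bias, "+")
  1 / (1 + exp(-z))
}

# minimum-norm least-squares via SVD pseudoinverse
.pinv_solve <- function(a, b, tol = 1e-10) {
  sv <- svd(a)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

#' @rdname elm_train
#' @param model a fitted `elm_model`.
#' @param test a [spectrum_set()].
#' @return `elm_predict`: integer vector of predicted labels (argmax of
#'   the output scores; ties to the smaller class id).
#' @export
elm_predict <- function(model, test) {
  h <- .elm_hidden(test$spectra, model$input_weights, model$biases)
  scores <- h %*% model$output_weights
  model$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d hidden nodes, %d classes\n",
              x$hidden_nodes, length(x$classes)))
  invisible(x)
}
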