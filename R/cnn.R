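# 1-D convolutional classifiers with optional squeeze-and-excitation
# channel attention.
#
# The family: cnn1c / cnn2c / cnn3c stack 1, 2 or 3 convolution+ReLU
# layers (kernel 3, stride 1, padding 1, so the 320-band length is
# preserved), flatten, and finish with two fully connected layers
# (fc_width -> n_classes). cnn2c_se inserts one SE block after the last
# convolution's activation: each channel is pooled to its mean (squeeze),
# the pooled vector passes through a bottleneck C -> C/r -> C with ReLU
# then sigmoid (excitation), and the resulting gates rescale the channels.
# Training is Adam on the softmax cross-entropy, mini-batches of 64,
# initial learning rate 0.01, in a compiled single-precision backend.

#' Model specification for the CNN family
#'
#' @param variant one of `"cnn1c"`, `"cnn2c"`, `"cnn3c"`, `"cnn2c_se"`.
#' @param se_ratio SE bottleneck reduction ratio r (gate bottleneck width
#'   is `max(1, floor(C/r))`); used by `cnn2c_se` only.
#' @param conv_channels output channels per conv layer; defaults 16, 32, 64
#'   for successive layers.
#' @param fc_width width of the first fully connected layer.
#' @param n_classes number of output classes.
#' @param n_bands input spectrum length.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(variant = c("cnn2c_se", "cnn1c", "cnn2c", "cnn3c"),
                       se_ratio = 16L, conv_channels = NULL,
                       fc_width = 256L, n_classes = 30L, n_bands = 320L) {
  variant <- match.arg(variant)
  n_conv <- switch(variant, cnn1c = 1L, cnn2c = 2L, cnn2c_se = 2L,
                   cnn3c = 3L)
  conv_channels <- as.integer(conv_channels %||% c(16L, 32L, 64L)[1:n_conv])
  if (length(conv_channels) != n_conv)
    stop("need ", n_conv, " conv channel counts for ", variant)
  use_se <- variant == "cnn2c_se"
  if (use_se && se_ratio < 1) stop("se_ratio must be >= 1")
  structure(list(variant = variant, n_conv = n_conv,
                 conv_channels = conv_channels,
                 fc_width = as.integer(fc_width),
                 n_classes = as.integer(n_classes),
                 n_bands = as.integer(n_bands),
                 use_se = use_se, se_ratio = as.integer(se_ratio)),
            class = "model_spec")
}

#' Training specification
#'
#' Defaults follow the study configuration: Adam, initial learning rate
#' 0.01, batch size 64, 10,000 mini-batch update steps, cross-entropy loss.
#' Dropout, L1 weight regularization and early stopping are available but
#' off by default.
#'
#' @param learning_rate initial Adam step size.
#' @param lr_decay inverse-time decay rate: the step size at iteration `t`
#'   is `learning_rate / (1 + lr_decay * t)`, the standard annealing that
#'   lets an aggressive initial rate converge early and settle late
#'   (0 = constant rate).
#' @param lr_warmup linear ramp-up of the step size over the first
#'   `lr_warmup` iterations; prevents the first full-size Adam steps from
#'   saturating every ReLU before the network has organised (0 = off).
#' @param batch_size mini-batch size (sampled with replacement).
#' @param iterations number of parameter-update steps.
#' @param l1_lambda L1 penalty on weights (0 = off).
#' @param dropout_p dropout probability after the first FC layer (0 = off).
#' @param max_grad_norm clip the global gradient norm to this value before
#'   each Adam step (0 = off). Engages only during loss spikes; keeps the
#'   aggressive 0.01 learning rate from killing ReLU units.
#' @param early_stop_patience stop after this many non-improving validation
#'   evaluations (`NULL` = off; requires a validation set).
#' @param eval_every validation evaluation interval in iterations.
#' @param rng_seed seed for weight init, batch sampling and dropout.
#' @return an object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.01, lr_decay = 2e-3,
                       lr_warmup = 100L, batch_size = 64L,
                       iterations = 10000L, l1_lambda = 0,
                       dropout_p = 0, max_grad_norm = 5,
                       early_stop_patience = NULL,
                       eval_every = 100L, rng_seed = 1L) {
  stopifnot(learning_rate > 0, lr_decay >= 0, lr_warmup >= 0,
            batch_size >= 1,
            iterations >= 1,
            l1_lambda >= 0, dropout_p >= 0, dropout_p < 1,
            max_grad_norm >= 0)
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_warmup = as.integer(lr_warmup),
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 l1_lambda = l1_lambda, dropout_p = dropout_p,
                 max_grad_norm = max_grad_norm,
                 early_stop_patience = early_stop_patience,
                 eval_every = as.integer(eval_every),
                 rng_seed = as.integer(rng_seed)),
            class = "train_spec")
}

.se_mid <- function(channels, ratio) max(1L, channels %/% ratio)

#' Initialize network weights
#'
#' Half-scale He initialization for the ReLU layers and Xavier-style for
#' the sigmoid-gated excitation output; biases start at zero. The 0.5
#' factor tames the loss spikes that full He initialization produces under
#' Adam at the configured 0.01 learning rate.
#'
#' @param spec a [model_spec()].
#' @param rng_seed integer seed.
#' @return named list of parameter matrices/vectors.
#' @export
cnn_init <- function(spec, rng_seed = 1L) {
  with_seed(rng_seed, {
    he <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.5 * sqrt(2 / nr)), nr, nc)
    xavier <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(1 / nr)), nr, nc)
    cin <- c(1L, spec$conv_channels)
    conv_w <- lapply(seq_len(spec$n_conv), function(l)
      he(3L * cin[l], spec$conv_channels[l]))
    conv_b <- lapply(spec$conv_channels, function(c) numeric(c))
    c_last <- spec$conv_channels[spec$n_conv]
    p <- list(conv_w = conv_w, conv_b = conv_b,
              fc1_w = he(spec$n_bands * c_last, spec$fc_width),
              fc1_b = numeric(spec$fc_width),
              fc2_w = xavier(spec$fc_width, spec$n_classes),
              fc2_b = numeric(spec$n_classes))
    if (spec$use_se) {
      mid <- .se_mid(c_last, spec$se_ratio)
      p$se_w1 <- he(c_last, mid)
      p$se_b1 <- numeric(mid)
      p$se_w2 <- xavier(mid, c_last)
      p$se_b2 <- numeric(c_last)
    }
    p
  })
}

.cnn_conf <- function(spec, tspec = NULL) {
  conf <- list(n_conv = spec$n_conv, channels = spec$conv_channels,
               n_bands = spec$n_bands, fc_width = spec$fc_width,
               n_classes = spec$n_classes, use_se = spec$use_se)
  if (!is.null(tspec)) {
    conf$learning_rate <- tspec$learning_rate
    conf$lr_decay <- tspec$lr_decay
    conf$lr_warmup <- tspec$lr_warmup
    conf$batch_size <- tspec$batch_size
    conf$iterations <- tspec$iterations
    conf$l1_lambda <- tspec$l1_lambda
    conf$dropout_p <- tspec$dropout_p
    conf$eval_every <- tspec$eval_every
    conf$patience <- as.integer(tspec$early_stop_patience %||% 0L)
    conf$max_grad_norm <- tspec$max_grad_norm
  }
  conf
}

# per-band standardization fitted on training spectra
.fit_standardizer <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s < 1e-8] <- 1
  list(mean = mu, sd = s)
}
.apply_standardizer <- function(std, m) {
  sweep(sweep(m, 2, std$mean), 2, std$sd, "/")
}

#' Train a CNN classifier
#'
#' Fits the per-band standardizer on the training spectra, initializes
#' weights from `tspec$rng_seed`, and runs `tspec$iterations` Adam update
#' steps on the softmax cross-entropy. Deterministic for a fixed seed.
#'
#' @param spec a [model_spec()].
#' @param train a [spectrum_set()] with labels in `1:n_classes`.
#' @param tspec a [train_spec()].
#' @param validation optional [spectrum_set()] used for the validation loss
#'   trace and early stopping.
#' @param standardize fit/apply per-band z-scoring (default `TRUE`).
#' @return an object of class `cnn_model` with elements `spec`, `params`,
#'   `standardizer`, `loss_trace`, `val_trace`, `iterations_run`.
#' @export
cnn_train <- function(spec, train, tspec = train_spec(),
                      validation = NULL, standardize = TRUE) {
  if (nrow(train$spectra) == 0L) stop("empty training set")
  if (any(train$labels < 1L | train$labels > spec$n_classes))
    stop("labels must lie in 1..n_classes")
  if (ncol(train$spectra) != spec$n_bands)
    stop("spectra have ", ncol(train$spectra), " bands, model expects ",
         spec$n_bands)
  std <- if (standardize) .fit_standardizer(train$spectra)
         else list(mean = rep(0, spec$n_bands), sd = rep(1, spec$n_bands))
  x <- .apply_standardizer(std, train$spectra)
  xv <- NULL; yv <- NULL
  if (!is.null(validation)) {
    xv <- .apply_standardizer(std, validation$spectra)
    yv <- validation$labels
  }
  params <- cnn_init(spec, tspec$rng_seed)
  fit <- with_seed(tspec$rng_seed, {
    .cnn_train_cpp(params, .cnn_conf(spec, tspec), x, train$labels, xv, yv)
  })
  if (any(!is.finite(fit$loss_trace)))
    warning("training loss became non-finite; consider a lower learning rate")
  structure(list(spec = spec, params = fit$params, standardizer = std,
                 loss_trace = fit$loss_trace,
                 val_trace = data.frame(iter = fit$val_iter,
                                        loss = fit$val_loss,
                                        accuracy = fit$val_accuracy),
                 iterations_run = fit$iterations_run,
                 best_iter = fit$best_iter),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s, %d iterations, final batch loss %.4f\n",
              x$spec$variant, x$iterations_run,
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict with a trained CNN
#'
#' @param model a [cnn_model][cnn_train()].
#' @param set a [spectrum_set()].
#' @param type `"class"` for labels, `"prob"` for softmax probabilities,
#'   `"score"` for raw logits.
#' @return labels, or an N x n_classes matrix.
#' @export
cnn_predict <- function(model, set, type = c("class", "prob", "score")) {
  type <- match.arg(type)
  x <- .apply_standardizer(model$standardizer, set$spectra)
  scores <- .cnn_forward_cpp(model$params, .cnn_conf(model$spec), x)
  switch(type,
         score = scores,
         prob = softmax_rows(scores),
         class = max.col(scores, ties.method = "first"))
}

#' Row-wise softmax
#'
#' @param scores numeric matrix of logits.
#' @return matrix of probabilities; rows sum to 1.
#' @export
softmax_rows <- function(scores) {
  z <- exp(scores - apply(scores, 1, max))
  z / rowSums(z)
}

#' Squeeze-and-excitation block (reference forward pass)
#'
#' Operates on a single C x L activation map: squeeze pools each channel
#' to its mean, the excitation bottleneck (`w1`: C x mid, ReLU; `w2`:
#' mid x C, sigmoid) turns the pooled vector into per-channel gates in
#' (0, 1), and the map is rescaled channel-wise.
#'
#' @param features C x L numeric matrix (channels x positions).
#' @param w1,b1 squeeze-to-bottleneck weights (C x mid) and bias.
#' @param w2,b2 bottleneck-to-gate weights (mid x C) and bias.
#' @return the gated C x L map, with the gate vector in attribute
#'   `"gates"`.
#' @export
se_block <- function(features, w1, b1, w2, b2) {
  if (nrow(features) < 1L) stop("need at least one channel")
  s <- rowMeans(features)                      # squeeze
  h <- pmax(as.vector(s %*% w1) + b1, 0)       # excitation bottleneck
  g <- 1 / (1 + exp(-(as.vector(h %*% w2) + b2)))
  out <- features * g
  attr(out, "gates") <- g
  out
}

#' SE reduction-ratio ablation
#'
#' Re-runs cross-validated training of the SE-gated two-convolution model
#' for each reduction ratio and tabulates the resulting metrics.
#'
#' @param set a [spectrum_set()].
#' @param ratios reduction ratios to test.
#' @param plan a [make_folds()] plan (default 10-fold on `set`).
#' @param tspec a [train_spec()].
#' @param n_classes number of classes.
#' @return data frame with one row per ratio in the study's table layout
#'   (mean and max/min deviations per metric), plus the full
#'   [cross_validate()] reports in attribute `"reports"`.
#' @export
ablate_se_ratio <- function(set, ratios = c(4L, 8L, 16L, 32L),
                            plan = NULL, tspec = train_spec(),
                            n_classes = max(set$labels)) {
  plan <- plan %||% make_folds(set, 10L, rng_seed = tspec$rng_seed)
  reports <- lapply(ratios, function(r) {
    spec <- model_spec("cnn2c_se", se_ratio = r, n_classes = n_classes,
                       n_bands = set$grid$n_bands)
    cross_validate(cnn_factory(spec, tspec), set, plan)
  })
  tab <- do.call(rbind, lapply(seq_along(ratios), function(i)
    cbind(data.frame(ratio = ratios[i]), format_report_row(reports[[i]]))))
  attr(tab, "reports") <- reports
  tab
}

#' Compare CNN variants and baselines
#'
#' @param set a [spectrum_set()].
#' @param factories named list of model factories (see [cnn_factory()],
#'   [elm_factory()], [knn_factory()]).
#' @param plan a [make_folds()] plan.
#' @return data frame, one row per factory, in the study's table layout;
#'   full reports in attribute `"reports"`.
#' @export
compare_models <- function(set, factories, plan = NULL) {
  plan <- plan %||% make_folds(set, 10L, rng_seed = 1L)
  reports <- lapply(factories, function(f) cross_validate(f, set, plan))
  tab <- do.call(rbind, lapply(names(factories), function(nm)
    cbind(data.frame(model = nm), format_report_row(reports[[nm]]))))
  attr(tab, "reports") <- reports
  tab
}

#' Model factories for cross-validation
#'
#' Each factory is a `function(train, test)` returning test predictions
#' (and training-set predictions, for train-accuracy columns), the
#' contract [cross_validate()] consumes.
#'
#' @param spec a [model_spec()] (`cnn_factory`).
#' @param tspec a [train_spec()] (`cnn_factory`).
#' @param hidden_nodes,rng_seed ELM configuration (`elm_factory`).
#' @param k,transform,distance KNN configuration (`knn_factory`).
#' @return a factory function.
#' @export
cnn_factory <- function(spec, tspec = train_spec()) {
  force(spec); force(tspec)
  function(train, test) {
    model <- cnn_train(spec, train, tspec)
    list(test_pred = cnn_predict(model, test),
         train_pred = cnn_predict(model, train))
  }
}

#' @rdname cnn_factory
#' @export
elm_factory <- function(hidden_nodes = 150L, rng_seed = 1L) {
  force(hidden_nodes); force(rng_seed)
  function(train, test) {
    model <- elm_train(train, hidden_nodes, rng_seed)
    list(test_pred = elm_predict(model, test),
         train_pred = elm_predict(model, train))
  }
}

#' @rdname cnn_factory
#' @export
knn_factory <- function(k = 17L, transform = "log",
                        distance = "mahalanobis") {
  force(k); force(transform); force(distance)
  function(train, test) {
    list(test_pred = knn_predict(train, test, k = k, transform = transform,
                                 distance = distance))
  }
}
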