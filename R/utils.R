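# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators are pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Mirror-pad a vector by `p` points on each side (reflection without
# repeating the edge point), the edge rule used by every smoother here.
mirror_pad <- function(x, p) {
  n <- length(x)
  if (p >= n) stop("signal shorter than padding window")
  c(x[(p + 1):2], x, x[(n - 1):(n - p)])
}

check_odd_window <- function(window, min = 3L) {
  window <- as.integer(window)
  if (window < min || window %% 2L == 0L)
    stop("window must be an odd integer >= ", min)
  window
}

`%||%` <- function(a, b) if (is.null(a)) b else a
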