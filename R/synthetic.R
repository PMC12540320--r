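# Synthetic spectra and tray cubes.
#
# Emulates a VNIR (380-1018 nm, 320 band) reflectance study of seed
# varieties: each variety has a smooth class-mean reflectance curve built
# from spline knots plus a few Gaussian absorption dips (standing in for
# varietal differences in starch/protein/lipid/moisture absorption), and
# each scanned seed is a distorted copy of its class mean -- multiplicative
# scatter, baseline shift, linear tilt, and band-correlated sensor noise,
# the artifact families that spectral preprocessing is meant to remove.

#' Variety model
#'
#' Parameters of one synthetic variety's mean reflectance curve: a smooth
#' baseline interpolated through evenly spaced knots, minus Gaussian
#' absorption dips at class-specific positions.
#'
#' @param class_id integer class label.
#' @param baseline_knots knot values of the smooth baseline, in \[0, 1\].
#' @param feature_centers absorption-dip centres in nm.
#' @param feature_depths dip magnitudes (reflectance units).
#' @param feature_widths dip Gaussian widths in nm.
#' @return an object of class `variety_model`.
#' @export
variety_model <- function(class_id, baseline_knots, feature_centers,
                          feature_depths, feature_widths) {
  stopifnot(length(feature_centers) == length(feature_depths),
            length(feature_centers) == length(feature_widths),
            all(baseline_knots >= 0 & baseline_knots <= 1))
  structure(list(class_id = as.integer(class_id),
                 baseline_knots = as.numeric(baseline_knots),
                 feature_centers = as.numeric(feature_centers),
                 feature_depths = as.numeric(feature_depths),
                 feature_widths = as.numeric(feature_widths)),
            class = "variety_model")
}

# Seed-coat-like baseline: low reflectance in the blue, rising through the
# red into a broad NIR plateau with a mild moisture-related droop.
.base_knot_values <- c(0.18, 0.24, 0.34, 0.46, 0.56, 0.60, 0.58, 0.53)

#' Generate a panel of synthetic varieties
#'
#' Draws `n_classes` distinct [variety_model()]s. Between-class separation is
#' controlled by `class_sep`, which scales both the knot jitter around the
#' shared baseline and the depth of the class-specific absorption dips;
#' `class_sep = 0` collapses all classes onto one curve.
#'
#' @param n_classes number of varieties (labelled `1:n_classes`).
#' @param rng_seed integer seed; the same seed reproduces the same panel.
#' @param class_sep separation scale (default 1 = the package's calibrated
#'   benchmark difficulty).
#' @param n_knots number of baseline knots.
#' @param n_features_range integer range of absorption dips per class.
#' @param feature_width_range dip width range in nm; narrow dips make the
#'   fine spectral structure that rewards convolutional feature learning.
#' @param feature_depth_range dip depth range (reflectance units), scaled
#'   by `class_sep`.
#' @param grid wavelength grid used to verify the mean stays in \[0, 1\].
#' @return list of `n_classes` pairwise-distinct `variety_model`s.
#' @export
#' @examples
#' v <- make_varieties(30, rng_seed = 7)
#' length(v)  # 30
make_varieties <- function(n_classes, rng_seed, class_sep = 1,
                           n_knots = 8L, n_features_range = c(5L, 8L),
                           feature_width_range = c(3, 8),
                           feature_depth_range = c(0.015, 0.045),
                           grid = wavelength_grid()) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  with_seed(rng_seed, {
    lapply(seq_len(n_classes), function(k) {
      knots <- .base_knot_values[round(seq(1, length(.base_knot_values),
                                           length.out = n_knots))]
      knots <- knots + class_sep * 0.026 * runif(n_knots, -1, 1)
      n_feat <- sample(seq(n_features_range[1], n_features_range[2]), 1L)
      variety_model(
        class_id = k,
        baseline_knots = pmin(pmax(knots, 0.05), 0.90),
        feature_centers = runif(n_feat, 480, 990),
        feature_depths = class_sep * runif(n_feat, feature_depth_range[1],
                                           feature_depth_range[2]),
        feature_widths = runif(n_feat, feature_width_range[1],
                               feature_width_range[2]))
    })
  })
}

#' Mean reflectance curve of a variety
#'
#' @param variety a [variety_model()].
#' @param grid a [wavelength_grid()].
#' @return numeric vector of length `grid$n_bands`, values in \[0, 1\].
#' @export
variety_mean_spectrum <- function(variety, grid = wavelength_grid()) {
  wl <- grid$values
  kx <- seq(wl[1], wl[length(wl)], length.out = length(variety$baseline_knots))
  base <- stats::spline(kx, variety$baseline_knots, xout = wl,
                        method = "natural")$y
  dips <- rep(0, length(wl))
  for (j in seq_along(variety$feature_centers)) {
    dips <- dips + variety$feature_depths[j] *
      exp(-0.5 * ((wl - variety$feature_centers[j]) /
                    variety$feature_widths[j])^2)
  }
  pmin(pmax(base - dips, 0.01), 0.99)
}

#' Noise model for synthetic spectra
#'
#' Per-spectrum distortions applied on top of the class mean: additive
#' band-wise sensor noise (optionally short-range correlated), a constant
#' baseline shift, a linear tilt across the spectral range, and a
#' multiplicative scatter factor. All scales are in reflectance units;
#' setting every scale to 0 reproduces the class means exactly.
#'
#' @param additive_sd standard deviation of per-band additive noise.
#' @param baseline_shift_sd sd of the per-spectrum constant offset.
#' @param slope_sd sd of the per-spectrum linear tilt (total swing across
#'   the full spectral range).
#' @param scatter_sd sd of the per-spectrum multiplicative factor around 1.
#' @param wiggle_sd sd of a per-spectrum smooth low-frequency distortion
#'   curve (a natural spline through `wiggle_knots` random values), the
#'   residual scattering curvature that baseline and scatter corrections
#'   leave behind; it perturbs local sample geometry far more than global
#'   class structure.
#' @param wiggle_knots number of spline knots of the wiggle curve.
#' @param shift_sd sd (in bands) of a per-spectrum shift of the whole
#'   spectrum along the wavelength axis, applied by linear interpolation
#'   with edge extension -- wavelength-calibration drift between scans.
#' @param session_sd sd of a smooth per-acquisition-session offset curve.
#'   Each class's seeds are scanned in `n_sessions` separate tray
#'   acquisitions, and every (class, session) pair receives its own smooth
#'   drift curve -- the batch effect of re-imaging a tray. Splits each
#'   class into sub-clusters without moving its overall mean much.
#' @param n_sessions number of acquisition sessions per class.
#' @param corr_window odd width (bands) of the boxcar used to correlate the
#'   additive noise; 1 = white noise. The kernel is renormalised so the
#'   marginal per-band sd stays `additive_sd`.
#' @param seed integer RNG seed; identical seed + parameters give identical
#'   output.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.014, baseline_shift_sd = 0.08,
                        slope_sd = 0.08, scatter_sd = 0.18,
                        wiggle_sd = 0.03, wiggle_knots = 7L,
                        shift_sd = 1, session_sd = 0.08, n_sessions = 3L,
                        corr_window = 5L, seed = 1L) {
  stopifnot(additive_sd >= 0, baseline_shift_sd >= 0, slope_sd >= 0,
            scatter_sd >= 0, wiggle_sd >= 0, wiggle_knots >= 3,
            session_sd >= 0, n_sessions >= 1, shift_sd >= 0)
  corr_window <- as.integer(corr_window)
  if (corr_window < 1L || corr_window %% 2L == 0L)
    stop("corr_window must be a positive odd integer")
  structure(list(additive_sd = additive_sd,
                 baseline_shift_sd = baseline_shift_sd,
                 slope_sd = slope_sd, scatter_sd = scatter_sd,
                 wiggle_sd = wiggle_sd, wiggle_knots = as.integer(wiggle_knots),
                 shift_sd = shift_sd,
                 session_sd = session_sd, n_sessions = as.integer(n_sessions),
                 corr_window = corr_window, seed = as.integer(seed)),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function(seed = 1L) {
  noise_model(0, 0, 0, 0, wiggle_sd = 0, shift_sd = 0, session_sd = 0,
              corr_window = 1L, seed = seed)
}

# smooth random curve over b bands: natural spline through k ~ N(0, sd) knots
.smooth_random_curve <- function(b, k, sd) {
  stats::spline(seq(1, b, length.out = k), rnorm(k, 0, sd),
                xout = seq_len(b), method = "natural")$y
}

# One distorted copy of a mean spectrum; assumes the RNG state is managed
# by the caller.
.distort_spectrum <- function(mu, noise, tilt_axis) {
  b <- length(mu)
  if (noise$shift_sd > 0) {
    d <- rnorm(1, 0, noise$shift_sd)     # shift in bands
    mu <- stats::approx(seq_len(b), mu, xout = seq_len(b) + d,
                        rule = 2)$y
  }
  eps <- rnorm(b, 0, noise$additive_sd)
  if (noise$corr_window > 1L && noise$additive_sd > 0) {
    k <- rep(1, noise$corr_window)
    k <- k / sqrt(sum(k^2))            # preserves marginal sd
    eps <- as.numeric(stats::filter(mirror_pad(eps, (noise$corr_window - 1) %/% 2),
                                    k, sides = 2))
    eps <- eps[!is.na(eps)]
  }
  out <- mu * (1 + rnorm(1, 0, noise$scatter_sd)) +
    rnorm(1, 0, noise$baseline_shift_sd) +
    rnorm(1, 0, noise$slope_sd) * tilt_axis +
    eps
  if (noise$wiggle_sd > 0)
    out <- out + .smooth_random_curve(b, noise$wiggle_knots, noise$wiggle_sd)
  out
}

#' Generate a spectrum set from variety models
#'
#' Draws `seeds_per_class` noisy spectra per variety. The default study
#' design (30 varieties x 90 seeds) yields 2,700 spectra of 320 bands,
#' with balanced labels.
#'
#' @param varieties list of [variety_model()]s.
#' @param seeds_per_class spectra per variety.
#' @param noise a [noise_model()]; its `seed` drives all randomness.
#' @param grid a [wavelength_grid()].
#' @return a [spectrum_set()].
#' @export
#' @examples
#' v <- make_varieties(2, rng_seed = 1)
#' s <- gen_spectrum_set(v, 3, zero_noise())
#' dim(s$spectra)  # 6 x 320
gen_spectrum_set <- function(varieties, seeds_per_class = 90L,
                             noise = noise_model(),
                             grid = wavelength_grid()) {
  if (length(varieties) == 0L) stop("variety list is empty")
  seeds_per_class <- as.integer(seeds_per_class)
  if (seeds_per_class < 1L) stop("seeds_per_class must be >= 1")
  tilt <- seq(-0.5, 0.5, length.out = grid$n_bands)
  means <- lapply(varieties, variety_mean_spectrum, grid = grid)
  n <- length(varieties) * seeds_per_class
  spectra <- matrix(0, n, grid$n_bands)
  labels <- integer(n)
  with_seed(noise$seed, {
    r <- 0L
    for (k in seq_along(varieties)) {
      session_of <- rep(seq_len(noise$n_sessions), length.out = seeds_per_class)
      offsets <- lapply(seq_len(noise$n_sessions), function(j)
        if (noise$session_sd > 0)
          .smooth_random_curve(grid$n_bands, 5L, noise$session_sd)
        else numeric(grid$n_bands))
      for (s in seq_len(seeds_per_class)) {
        r <- r + 1L
        spectra[r, ] <- .distort_spectrum(means[[k]], noise, tilt) +
          offsets[[session_of[s]]]
        labels[r] <- varieties[[k]]$class_id
      }
    }
  })
  spectrum_set(spectra, labels, grid,
               provenance = sprintf("synthetic: %d classes x %d seeds, seed %d",
                                    length(varieties), seeds_per_class,
                                    noise$seed))
}

#' Tray layout
#'
#' Geometry of a scanned seed tray: a `rows` x `cols` grid of equal
#' rectangles on a dark background, mirroring the 5 x 6 arrangement used
#' when imaging 30 seeds per scan.
#'
#' @param rows,cols grid dimensions.
#' @param seed_extent_px `c(lines, samples)` size of each seed rectangle.
#' @param gap_px pixels between adjacent rectangles.
#' @param margin_px pixels between the grid and the cube border.
#' @param background_level reflectance of the dark tray background.
#' @return an object of class `tray_layout`.
#' @export
tray_layout <- function(rows = 5L, cols = 6L, seed_extent_px = c(8L, 8L),
                        gap_px = 3L, margin_px = 3L,
                        background_level = 0.04) {
  stopifnot(rows >= 1, cols >= 1, all(seed_extent_px >= 1), gap_px >= 0,
            margin_px >= 0, background_level >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 seed_extent_px = as.integer(seed_extent_px),
                 gap_px = as.integer(gap_px),
                 margin_px = as.integer(margin_px),
                 background_level = background_level),
            class = "tray_layout")
}

#' @rdname tray_layout
#' @export
tray_cube_shape <- function(layout) {
  c(lines = 2L * layout$margin_px + layout$rows * layout$seed_extent_px[1] +
      (layout$rows - 1L) * layout$gap_px,
    samples = 2L * layout$margin_px + layout$cols * layout$seed_extent_px[2] +
      (layout$cols - 1L) * layout$gap_px)
}

#' Generate a synthetic tray scan with reference frames
#'
#' Renders one seed per tray position (cycling through `varieties` in
#' row-major order) into a raw-counts cube, together with the matching
#' white-reference and dark-reference cubes, so that dark/white calibration
#' followed by grid-ROI extraction recovers the generated spectra.
#'
#' The sensor model is `raw = illumination * reflectance + dark_current`
#' per pixel and band; the white reference images a unit-reflectance panel.
#'
#' @param varieties list of [variety_model()]s; one seed is drawn per tray
#'   cell, so `rows * cols` must not exceed `length(varieties)` times the
#'   number of repeats you intend (cells beyond `length(varieties)` reuse
#'   varieties cyclically).
#' @param layout a [tray_layout()].
#' @param noise a [noise_model()]; per-seed distortions plus per-pixel
#'   additive noise at `additive_sd`.
#' @param grid a [wavelength_grid()].
#' @param illumination per-band illumination counts; default a smooth lamp
#'   curve peaking in the red. Scalar or length `n_bands`.
#' @param dark_current per-band dark counts; scalar or length `n_bands`.
#' @return list with elements `raw`, `white`, `dark` (three [hyper_cube()]s)
#'   and `truth` (data frame of 0-based half-open ROI bounds and labels, in
#'   row-major tray order).
#' @export
gen_tray_cube <- function(varieties, layout = tray_layout(),
                          noise = noise_model(), grid = wavelength_grid(),
                          illumination = NULL, dark_current = 100) {
  shape <- tray_cube_shape(layout)
  rois <- grid_rois(layout, shape)
  wl <- grid$values
  if (is.null(illumination)) {
    illumination <- 2500 * (0.45 + exp(-0.5 * ((wl - 680) / 240)^2))
  }
  illumination <- rep_len(illumination, grid$n_bands)
  dark_current <- rep_len(dark_current, grid$n_bands)
  if (any(illumination <= 0)) stop("illumination must be positive")

  means <- lapply(varieties, variety_mean_spectrum, grid = grid)
  tilt <- seq(-0.5, 0.5, length.out = grid$n_bands)
  nl <- shape[["lines"]]; ns <- shape[["samples"]]; nb <- grid$n_bands

  refl <- array(layout$background_level, dim = c(nl, ns, nb))
  truth <- rois
  with_seed(noise$seed, {
    for (i in seq_len(nrow(rois))) {
      k <- ((i - 1L) %% length(varieties)) + 1L
      seed_spec <- .distort_spectrum(means[[k]], noise, tilt)
      truth$label[i] <- varieties[[k]]$class_id
      li <- (rois$line_start[i] + 1L):rois$line_stop[i]
      si <- (rois$sample_start[i] + 1L):rois$sample_stop[i]
      npx <- length(li) * length(si)
      px <- matrix(rep(seed_spec, each = npx), npx, nb)
      if (noise$additive_sd > 0)
        px <- px + matrix(rnorm(npx * nb, 0, noise$additive_sd), npx, nb)
      refl[li, si, ] <- array(px, dim = c(length(li), length(si), nb))
    }
  })

  il <- array(rep(illumination, each = nl * ns), dim = c(nl, ns, nb))
  dk <- array(rep(dark_current, each = nl * ns), dim = c(nl, ns, nb))
  list(raw = hyper_cube(refl * il + dk, grid),
       white = hyper_cube(il + dk, grid),
       dark = hyper_cube(dk, grid),
       truth = truth)
}

#' The calibrated synthetic benchmark
#'
#' The package's default study design: 30 varieties x 90 seeds = 2,700
#' spectra of 320 bands at the calibrated difficulty (see the methods
#' vignette), on which the classifier family lands in its published
#' operating regime -- the convolutional models near (not at) ceiling,
#' the extreme learning machine below them, and raw-covariance
#' Mahalanobis k-nearest neighbours far behind.
#'
#' @param rng_seed integer seed controlling both the variety panel and
#'   the noise draws.
#' @param n_classes,seeds_per_class study dimensions.
#' @param class_sep difficulty dial (1 = calibrated default).
#' @return a [spectrum_set()].
#' @export
#' @examples
#' b <- synthetic_benchmark(1)
#' dim(b$spectra)  # 2700 x 320
synthetic_benchmark <- function(rng_seed = 1L, n_classes = 30L,
                                seeds_per_class = 90L, class_sep = 1) {
  v <- make_varieties(n_classes, rng_seed = rng_seed + 1000L,
                      class_sep = class_sep)
  gen_spectrum_set(v, seeds_per_class, noise_model(seed = rng_seed))
}
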