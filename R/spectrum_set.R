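#' Wavelength grid
#'
#' Band-centre wavelengths of a hyperspectral sensor. The default grid is the
#' 320-band visible/near-infrared range 380--1018 nm (uniform 2 nm spacing)
#' common to push-broom VNIR imagers used for seed phenotyping.
#'
#' @param n_bands number of spectral bands.
#' @param from,to wavelengths (nm) of the first and last band centre.
#' @param values optional explicit vector of band centres; overrides
#'   `n_bands`/`from`/`to`. Must be strictly increasing.
#' @return an object of class `wavelength_grid` with fields `values` (nm)
#'   and `n_bands`.
#' @export
#' @examples
#' g <- wavelength_grid()
#' g$n_bands          # 320
#' diff(g$values)[1]  # 2 nm
wavelength_grid <- function(n_bands = 320L, from = 380, to = 1018,
                            values = NULL) {
  if (is.null(values)) {
    n_bands <- as.integer(n_bands)
    if (n_bands < 1L) stop("n_bands must be >= 1")
    values <- if (n_bands == 1L) from else seq(from, to, length.out = n_bands)
  }
  values <- as.numeric(values)
  if (any(diff(values) <= 0)) stop("wavelengths must be strictly increasing")
  structure(list(values = values, n_bands = length(values)),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm\n",
              x$n_bands, x$values[1], x$values[x$n_bands]))
  invisible(x)
}

#' Spectrum set
#'
#' The pipeline's central exchange type: one reflectance spectrum per seed,
#' with integer class labels and the wavelength grid they were sampled on.
#'
#' @param spectra numeric matrix, one row per seed, one column per band.
#' @param labels integer class labels, one per row of `spectra`.
#' @param grid a [wavelength_grid()] whose band count matches `ncol(spectra)`.
#' @param provenance free-text metadata carried through the pipeline.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, labels, grid = wavelength_grid(),
                         provenance = character()) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  labels <- as.integer(labels)
  if (nrow(spectra) != length(labels))
    stop("row count of spectra must equal label count")
  if (ncol(spectra) != grid$n_bands)
    stop("spectra have ", ncol(spectra), " bands but grid has ", grid$n_bands)
  if (any(!is.finite(spectra)))
    stop("spectra contain non-finite values")
  structure(list(spectra = spectra, labels = labels, grid = grid,
                 provenance = provenance),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d bands, %d classes\n",
              nrow(x$spectra), ncol(x$spectra),
              length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$spectra)

#' Subset a spectrum set by row
#'
#' @param set a [spectrum_set()].
#' @param idx integer or logical row index.
#' @return the subset as a `spectrum_set`.
#' @export
subset_spectra <- function(set, idx) {
  spectrum_set(set$spectra[idx, , drop = FALSE], set$labels[idx],
               set$grid, set$provenance)
}

#' Read and write spectrum tables
#'
#' Flat CSV interchange format: first column `label`, then one column per
#' band named by its wavelength in nm (e.g. `wl_380`).
#'
#' @param set a [spectrum_set()].
#' @param path file path of the CSV table.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns
#'   a `spectrum_set`.
#' @export
write_spectra <- function(set, path) {
  df <- data.frame(label = set$labels, set$spectra)
  names(df) <- c("label", sprintf("wl_%g", set$grid$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "label") stop("first column must be 'label'")
  wl <- as.numeric(sub("^wl_", "", names(df)[-1]))
  if (any(is.na(wl))) stop("band columns must be named wl_<nm>")
  spectrum_set(as.matrix(df[, -1, drop = FALSE]), df$label,
               wavelength_grid(values = wl),
               provenance = paste("read from", path))
}
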