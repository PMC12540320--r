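# Region-of-interest spectrum extraction.
#
# One seed = one rectangle on the calibrated cube = one mean spectrum.
# Coordinates are 0-based and half-open throughout ([start, stop)).

#' ROI rectangle
#'
#' @param line_start,line_stop,sample_start,sample_stop 0-based half-open
#'   pixel bounds.
#' @param label integer class id carried through extraction.
#' @return a one-row data frame; lists of ROIs are data frames with columns
#'   `label`, `line_start`, `line_stop`, `sample_start`, `sample_stop`.
#' @export
roi_rect <- function(line_start, line_stop, sample_start, sample_stop,
                     label = NA_integer_) {
  if (line_stop <= line_start || sample_stop <= sample_start)
    stop("ROI is empty")
  data.frame(label = as.integer(label),
             line_start = as.integer(line_start),
             line_stop = as.integer(line_stop),
             sample_start = as.integer(sample_start),
             sample_stop = as.integer(sample_stop))
}

.check_rois <- function(rois, cube_dim) {
  need <- c("label", "line_start", "line_stop", "sample_start", "sample_stop")
  if (!all(need %in% names(rois))) stop("ROI table missing columns")
  if (nrow(rois) == 0L) stop("no ROIs supplied")
  if (any(rois$line_stop <= rois$line_start) ||
      any(rois$sample_stop <= rois$sample_start))
    stop("empty ROI rectangle")
  if (any(rois$line_start < 0L) || any(rois$sample_start < 0L) ||
      any(rois$line_stop > cube_dim[1]) || any(rois$sample_stop > cube_dim[2]))
    stop("ROI outside cube bounds")
  invisible(rois)
}

#' Extract mean spectra from ROIs
#'
#' Row `i` of the result is the arithmetic mean, per band, over all pixels
#' of ROI `i` on the (calibrated) cube.
#'
#' @param cube a reflectance [hyper_cube()].
#' @param rois ROI table (see [roi_rect()], [grid_rois()], [read_rois()]).
#' @return a [spectrum_set()] with one row per ROI.
#' @export
extract_spectra <- function(cube, rois) {
  .check_rois(rois, dim(cube$data))
  nb <- dim(cube$data)[3]
  out <- matrix(0, nrow(rois), nb)
  for (i in seq_len(nrow(rois))) {
    block <- cube$data[(rois$line_start[i] + 1L):rois$line_stop[i],
                       (rois$sample_start[i] + 1L):rois$sample_stop[i], ,
                       drop = FALSE]
    out[i, ] <- apply(block, 3, mean)
  }
  spectrum_set(out, rois$label, cube$grid,
               provenance = sprintf("extracted from %d ROIs", nrow(rois)))
}

#' Lay a tray grid of ROIs over a cube
#'
#' Produces `rows * cols` equal-size, non-overlapping rectangles in
#' row-major order, matching the geometry [gen_tray_cube()] renders.
#'
#' @param layout a [tray_layout()].
#' @param cube_shape `c(lines, samples)` of the target cube.
#' @return ROI table (labels `NA`; fill from a truth table or by variety).
#' @export
grid_rois <- function(layout, cube_shape) {
  need <- tray_cube_shape(layout)
  if (cube_shape[1] < need[1] || cube_shape[2] < need[2])
    stop("layout does not fit in cube of shape ",
         paste(cube_shape, collapse = "x"))
  el <- layout$seed_extent_px[1]; es <- layout$seed_extent_px[2]
  out <- vector("list", layout$rows * layout$cols)
  i <- 0L
  for (r in seq_len(layout$rows)) {
    for (c in seq_len(layout$cols)) {
      i <- i + 1L
      l0 <- layout$margin_px + (r - 1L) * (el + layout$gap_px)
      s0 <- layout$margin_px + (c - 1L) * (es + layout$gap_px)
      out[[i]] <- roi_rect(l0, l0 + el, s0, s0 + es)
    }
  }
  do.call(rbind, out)
}

#' Read and write ROI tables
#'
#' Plain TSV with columns `label`, `line_start`, `line_stop`,
#' `sample_start`, `sample_stop` (0-based half-open bounds).
#'
#' @param rois ROI table.
#' @param path file path.
#' @return `write_rois` returns `path` invisibly; `read_rois` the table.
#' @export
write_rois <- function(rois, path) {
  utils::write.table(rois, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
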