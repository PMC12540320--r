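# ENVI-style cube I/O and dark/white reflectance calibration.
#
# The only cube format supported is the classic ENVI pair: an ASCII
# "key = value" header next to a headerless little-endian binary whose
# layout is declared by the header's interleave (bsq/bil/bip), data type
# and dimensions.

# ENVI data-type codes supported (code -> bytes, reader/writer mode)
.envi_dtypes <- list(
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Hyperspectral cube
#'
#' A 3-D array of radiance counts or reflectance indexed
#' `(line, sample, band)` with its wavelength grid and storage metadata.
#'
#' @param data 3-D numeric array `(lines, samples, bands)`.
#' @param grid a [wavelength_grid()]; band count must match `dim(data)[3]`.
#' @param interleave storage interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param dtype_code ENVI data-type code (2 = int16, 4 = float32,
#'   5 = float64, 12 = uint16).
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, grid, interleave = "bsq", dtype_code = 4L) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (any(dim(data) == 0L)) stop("empty cube")
  if (dim(data)[3] != grid$n_bands)
    stop("cube has ", dim(data)[3], " bands but grid has ", grid$n_bands)
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  if (!as.character(dtype_code) %in% names(.envi_dtypes))
    stop("unsupported ENVI data type code: ", dtype_code)
  structure(list(data = data, grid = grid, interleave = interleave,
                 dtype_code = as.integer(dtype_code)),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d lines x %d samples x %d bands (%s, type %d)\n",
              d[1], d[2], d[3], x$interleave, x$dtype_code))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

.header_path <- function(path) {
  if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
}

.binary_path <- function(header_path) sub("\\.hdr$", "", header_path)

#' Write an ENVI cube
#'
#' Writes `<path>` (binary, little-endian) and `<path>.hdr` (ASCII header
#' with samples, lines, bands, interleave, data type and the wavelength
#' list).
#'
#' @param cube a [hyper_cube()].
#' @param path output path of the binary file (header gets `.hdr` added).
#' @param interleave storage order; defaults to the cube's own.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = cube$interleave) {
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  dt <- .envi_dtypes[[as.character(cube$dtype_code)]]
  d <- dim(cube$data)  # (lines, samples, bands)
  # reorder to the fastest-varying-first layout of each interleave
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vals <- as.vector(aperm(cube$data, perm))
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    if (cube$dtype_code == 12L && any(vals < 0))
      stop("negative values cannot be stored as uint16")
  } else {
    vals <- as.double(vals)  # writeBin writes the R storage type as-is
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = dt$size, endian = "little")
  hdr <- c(
    "ENVI",
    "description = { seedspec hyper_cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", cube$dtype_code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(format(cube$grid$values, trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(hdr, .header_path(path))
  invisible(path)
}

# Parse an ENVI header into a named list; multi-line { } values are joined.
.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ENVI")
    stop("not an ENVI header: ", header_path)
  out <- list()
  i <- 2L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      while (grepl("\\{", val) && !grepl("\\}", val) && i < n) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      out[[key]] <- val
    }
    i <- i + 1L
  }
  out
}

#' Read an ENVI cube
#'
#' @param header_path path to the `.hdr` file (or to the binary, in which
#'   case `.hdr` is appended).
#' @return a [hyper_cube()].
#' @export
read_envi <- function(header_path) {
  hp <- .header_path(header_path)
  if (!file.exists(hp)) stop("header not found: ", hp)
  h <- .parse_envi_header(hp)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("header missing keys: ", paste(miss, collapse = ", "))
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", interleave)
  if (!as.character(dtype) %in% names(.envi_dtypes))
    stop("unsupported ENVI data type code: ", dtype)
  if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) != 0L)
    stop("only little-endian (byte order = 0) files are supported")
  if (!is.null(h$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
    if (length(wl) != nb)
      stop("header declares ", nb, " bands but ", length(wl), " wavelengths")
    grid <- wavelength_grid(values = wl)
  } else {
    grid <- wavelength_grid(n_bands = nb, from = 1, to = nb)
  }
  dt <- .envi_dtypes[[as.character(dtype)]]
  bin <- .binary_path(hp)
  if (!file.exists(bin)) stop("binary file not found: ", bin)
  expect_bytes <- as.numeric(ns) * nl * nb * dt$size
  if (file.size(bin) != expect_bytes)
    stop(sprintf("binary size %d does not match header (%d bytes expected)",
                 file.size(bin), expect_bytes))
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, dt$what, n = ns * nl * nb, size = dt$size,
                  signed = dt$signed, endian = "little")
  dims <- switch(interleave,
                 bsq = c(ns, nl, nb),
                 bil = c(ns, nb, nl),
                 bip = c(nb, ns, nl))
  arr <- array(vals, dim = dims)
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),
                 bil = c(3, 1, 2),
                 bip = c(3, 2, 1))
  hyper_cube(aperm(arr, perm), grid, interleave = interleave,
             dtype_code = dtype)
}

#' Dark/white reflectance calibration
#'
#' Converts raw radiance counts to relative reflectance using a dark-current
#' frame and a white-reference scan:
#' `reflectance = (raw - dark) / (white - dark)`, elementwise per band.
#' White and dark references may be full cubes matching `raw`, or
#' single-line cubes broadcast across all lines.
#'
#' Bands where `|white - dark|` falls below `eps` times the white dynamic
#' range are set to 0 and counted in the `dead_bands` attribute rather than
#' producing non-finite values.
#'
#' @param raw,white,dark [hyper_cube()]s sharing the band count; `white` and
#'   `dark` may have a single line.
#' @param clamp if `TRUE`, clamp the output into \[0, 1\]; off by default
#'   because specular pixels legitimately exceed 1.
#' @param eps relative denominator guard.
#' @return a reflectance [hyper_cube()] on `raw`'s grid, with an integer
#'   attribute `dead_bands` (per-band count of guarded pixels).
#' @export
#' @examples
#' g <- wavelength_grid(4, 400, 700)
#' raw <- hyper_cube(array(5, c(2, 2, 4)), g)
#' wht <- hyper_cube(array(9, c(2, 2, 4)), g)
#' drk <- hyper_cube(array(1, c(2, 2, 4)), g)
#' calibrate_reflectance(raw, wht, drk)$data[1, 1, 1]  # 0.5
calibrate_reflectance <- function(raw, white, dark, clamp = FALSE,
                                  eps = 1e-6) {
  d <- dim(raw$data)
  for (ref in list(white, dark)) {
    dr <- dim(ref$data)
    if (dr[3] != d[3] || dr[2] != d[2] || !(dr[1] == d[1] || dr[1] == 1L))
      stop("reference cube shape ", paste(dr, collapse = "x"),
           " incompatible with raw ", paste(d, collapse = "x"))
  }
  bc <- function(ref) {
    if (dim(ref$data)[1] == d[1]) ref$data
    else array(rep(ref$data, each = d[1]),
               dim = d)  # broadcast the single line across lines
  }
  w <- bc(white); k <- bc(dark)
  denom <- w - k
  guard <- eps * max(abs(w))
  bad <- abs(denom) < guard
  denom[bad] <- 1
  out <- (raw$data - k) / denom
  out[bad] <- 0
  if (clamp) out <- pmin(pmax(out, 0), 1)
  dead <- apply(bad, 3, sum)
  res <- hyper_cube(out, raw$grid, interleave = raw$interleave,
                    dtype_code = 4L)
  attr(res, "dead_bands") <- as.integer(dead)
  res
}
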