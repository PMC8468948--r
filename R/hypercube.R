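# Hyperspectral cube data model, ENVI / portable I/O, reflectance calibration.
#
# A cube is a (rows x cols x bands) array of nonnegative reals plus a strictly
# increasing wavelength axis in nm and an origin tag: "raw_counts" for sensor
# counts, "reflectance" after white/dark calibration. Spatial coordinates are
# 0-based (row, col) conceptually with row 1 at the image top; all R-side
# indexing is the usual 1-based array indexing.

#' Default VIS/NIR wavelength axis
#'
#' The acquisition grid of the imaging system: 60 bands from 450 to 1040 nm
#' in 10 nm steps.
#'
#' @return numeric vector of 60 band-centre wavelengths (nm).
#' @export
default_wavelengths <- function() seq(450, 1040, by = 10)

#' Construct a hyperspectral cube
#'
#' @param data numeric array (rows x cols x bands), nonnegative.
#' @param wavelengths strictly increasing band-centre wavelengths in nm;
#'   length must equal `dim(data)[3]`.
#' @param origin `"raw_counts"` or `"reflectance"`. Reflectance cubes must
#'   lie in \[0, 1.5\] (headroom above the 0.99 white target for noise).
#' @return an object of class `hypercube`.
#' @export
hyper_cube <- function(data, wavelengths = default_wavelengths(),
                       origin = c("raw_counts", "reflectance")) {
  origin <- match.arg(origin)
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_contract("cube data must be a 3-D array (rows x cols x bands)")
  d <- dim(data)
  if (any(d < 1L)) abort_contract("all cube dimensions must be >= 1")
  if (length(wavelengths) != d[3L])
    abort_contract(sprintf("band dimension (%d) does not match wavelength axis length (%d)",
                           d[3L], length(wavelengths)))
  if (is.unsorted(wavelengths, strictly = TRUE))
    abort_contract("wavelength axis must be strictly increasing")
  if (anyNA(data)) abort_contract("cube data contains missing values")
  if (min(data) < 0) abort_contract("cube data must be nonnegative")
  if (origin == "reflectance" && max(data) > 1.5)
    abort_contract("reflectance cube has values above 1.5")
  structure(list(data = data, wavelengths = as.numeric(wavelengths), origin = origin),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm), origin: %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$origin))
  invisible(x)
}

n_bands <- function(cube) dim(cube$data)[3L]

#' Flatten a cube to a pixel-spectrum matrix
#'
#' Rows are pixels in column-major (R array) order, columns are bands. If a
#' logical mask is supplied only `TRUE` pixels are returned, in the same
#' order.
#'
#' @param cube a `hypercube`.
#' @param mask optional logical matrix with the cube's spatial shape.
#' @return numeric matrix, one spectrum per row.
#' @export
as_spectrum_matrix <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  X <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  if (!is.null(mask)) {
    check_mask_shape(mask, cube)
    X <- X[as.vector(mask), , drop = FALSE]
  }
  X
}

check_mask_shape <- function(mask, cube) {
  if (!is.logical(mask) || !identical(dim(mask), dim(cube$data)[1:2]))
    abort_contract("mask must be a logical matrix matching the cube's spatial shape")
  invisible(TRUE)
}

# ---------------------------------------------------------------- references

#' Bundle white and dark reference measurements
#'
#' White and dark references may be full cubes (the acquisition case) or
#' per-band numeric vectors (spatially flat references, broadcast over the
#' image); they must share the wavelength axis. The calibration target's
#' known reflectance `rho_ref` defaults to the 99% white standard and may be
#' a per-band vector.
#'
#' @param white,dark raw-count `hypercube`s or per-band numeric vectors.
#' @param rho_ref scalar in (0, 1\] or per-band vector; default 0.99.
#' @param wavelengths axis used when both references are plain vectors.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(white, dark, rho_ref = 0.99,
                          wavelengths = default_wavelengths()) {
  wl <- if (inherits(white, "hypercube")) white$wavelengths
        else if (inherits(dark, "hypercube")) dark$wavelengths
        else wavelengths
  for (nm in c("white", "dark")) {
    r <- get(nm)
    if (inherits(r, "hypercube")) {
      if (!isTRUE(all.equal(r$wavelengths, wl)))
        abort_contract("white and dark references must share a wavelength axis")
    } else if (!is.numeric(r) || length(r) != length(wl)) {
      abort_contract(sprintf("%s reference must be a hypercube or a per-band numeric vector", nm))
    }
  }
  if (inherits(white, "hypercube") && inherits(dark, "hypercube") &&
      !identical(dim(white$data)[1:2], dim(dark$data)[1:2]))
    abort_contract("white and dark reference cubes must share spatial shape")
  if (any(rho_ref <= 0) || any(rho_ref > 1) ||
      !(length(rho_ref) %in% c(1L, length(wl))))
    abort_contract("rho_ref must lie in (0, 1], scalar or one value per band")
  structure(list(white = white, dark = dark, rho_ref = rho_ref, wavelengths = wl),
            class = "reference_set")
}

ref_as_array <- function(r, d) {
  if (inherits(r, "hypercube")) {
    if (!identical(dim(r$data)[1:2], d[1:2]))
      abort_contract("reference cube spatial shape does not match the raw cube")
    r$data
  } else {
    aperm(array(rep(r, each = d[1] * d[2]), dim = d), c(1, 2, 3))
  }
}

#' Calibrate raw counts to relative reflectance
#'
#' Converts raw sensor counts to relative reflectance with the standard
#' white/dark correction
#' \deqn{\rho(x,y,\lambda) = \rho_{ref}(\lambda)\,
#'   \frac{R(x,y,\lambda) - R_{dark}(x,y,\lambda)}
#'        {R_{white}(x,y,\lambda) - R_{dark}(x,y,\lambda)}}
#' so a pixel imaging the white standard maps to `rho_ref` and the dark
#' signal maps to 0. Values are clipped to \[0, 1.5\] (negative values can
#' arise from sensor noise when raw < dark); the number of clipped entries is
#' recorded in the `n_clipped` attribute of the result's data.
#'
#' @param raw a raw-counts `hypercube`.
#' @param refs a `reference_set` sharing the cube's axis (and spatial shape,
#'   for full-cube references).
#' @return a reflectance-tagged `hypercube`.
#' @export
calibrate_reflectance <- function(raw, refs) {
  if (!inherits(raw, "hypercube")) abort_contract("raw must be a hypercube")
  if (!inherits(refs, "reference_set")) abort_contract("refs must be a reference_set")
  if (!isTRUE(all.equal(raw$wavelengths, refs$wavelengths)))
    abort_contract("raw cube and references have different wavelength axes")
  d <- dim(raw$data)
  white <- ref_as_array(refs$white, d)
  dark  <- ref_as_array(refs$dark, d)
  denom <- white - dark
  if (any(denom <= 0)) {
    idx <- which(denom <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("calibration undefined: white <= dark at (row %d, col %d, band %d)",
                  idx[1], idx[2], idx[3]), "hsib_calibration_error")
  }
  rho <- if (length(refs$rho_ref) == 1L) refs$rho_ref
         else rep(refs$rho_ref, each = d[1] * d[2])
  out <- rho * (raw$data - dark) / denom
  n_clip <- sum(out < 0) + sum(out > 1.5)
  if (n_clip > 0)
    message(sprintf("calibrate_reflectance: clipped %d value(s) to [0, 1.5]", n_clip))
  out[out < 0] <- 0
  out[out > 1.5] <- 1.5
  res <- hyper_cube(out, raw$wavelengths, origin = "reflectance")
  attr(res$data, "n_clipped") <- n_clip
  res
}

# ----------------------------------------------------------------------- I/O

envi_paths <- function(path) {
  base <- sub("\\.hdr$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"))
}

#' Write a cube to disk
#'
#' Two formats are supported. `"envi"` writes a classic ENVI pair: a text
#' `.hdr` header (samples/lines/bands, interleave, data type, wavelength
#' list) and a flat binary `.dat` payload, band-sequential, little-endian
#' 64-bit floats so that values round-trip exactly. `"portable"` writes a
#' single RDS container holding the data, wavelength axis and origin tag.
#'
#' @param cube a `hypercube`.
#' @param path output path; for ENVI the `.hdr`/`.dat` pair is derived from
#'   it (a trailing `.hdr` is stripped first).
#' @param format `"envi"` or `"portable"`.
#' @return `invisible(path)`.
#' @export
write_cube <- function(cube, path, format = c("envi", "portable")) {
  format <- match.arg(format)
  if (!inherits(cube, "hypercube")) abort_contract("cube must be a hypercube")
  if (!dir.exists(dirname(path)))
    abort(sprintf("cannot write '%s': directory does not exist", path), "hsib_io_error")
  if (format == "portable") {
    saveRDS(list(data = cube$data, wavelengths = cube$wavelengths,
                 origin = cube$origin), path)
    return(invisible(path))
  }
  p <- envi_paths(path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = { hsibruise hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("data origin = %s", cube$origin),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, scientific = FALSE),
                 collapse = ", "), " }"))
  writeLines(hdr, p$hdr)
  # BSQ: samples fastest, then lines, then bands
  v <- as.vector(aperm(cube$data, c(2, 1, 3)))
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # key = value lines; { ... } values may span several lines
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{") && !grepl("\\}", val)) {
      while (i < length(lines) && !grepl("\\}", val)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
    }
    fields[[key]] <- val
    i <- i + 1L
  }
  fields
}

envi_int <- function(fields, key) {
  if (is.null(fields[[key]])) abort_format(sprintf("ENVI header missing '%s'", key))
  v <- suppressWarnings(as.integer(fields[[key]]))
  if (is.na(v)) abort_format(sprintf("ENVI header field '%s' is not an integer", key))
  v
}

#' Read a cube from disk
#'
#' Counterpart of [write_cube()]. ENVI reading supports `bil`, `bip` and
#' `bsq` interleaves and data types 4 (float32) / 5 (float64), little-endian.
#' Wavelengths are taken from the header and sorted ascending (bands
#' reordered accordingly). The origin tag defaults to `"raw_counts"` unless
#' the header declares reflectance.
#'
#' @param path file path (for ENVI, the `.hdr` or its basename).
#' @param format `"auto"` (by extension/content), `"envi"` or `"portable"`.
#' @return a `hypercube`.
#' @export
read_cube <- function(path, format = c("auto", "envi", "portable")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(envi_paths(path)$hdr)) "envi" else "portable"
  }
  if (format == "portable") {
    if (!file.exists(path)) abort(sprintf("no such file: %s", path), "hsib_io_error")
    obj <- readRDS(path)
    if (!is.list(obj) || !all(c("data", "wavelengths", "origin") %in% names(obj)))
      abort_format(sprintf("'%s' is not a portable hypercube container", path))
    return(hyper_cube(obj$data, obj$wavelengths, obj$origin))
  }
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) abort(sprintf("no such file: %s", p$hdr), "hsib_io_error")
  if (!file.exists(p$dat)) abort(sprintf("no such file: %s", p$dat), "hsib_io_error")
  f <- parse_envi_header(p$hdr)
  samples <- envi_int(f, "samples"); lines <- envi_int(f, "lines")
  bands <- envi_int(f, "bands"); dtype <- envi_int(f, "data type")
  interleave <- tolower(f[["interleave"]] %||% "")
  if (!interleave %in% c("bil", "bip", "bsq"))
    abort_format(sprintf("unsupported or missing interleave '%s'", interleave))
  if (!dtype %in% c(4L, 5L))
    abort_format(sprintf("unsupported ENVI data type %d (only 4/5 supported)", dtype))
  wl_raw <- f[["wavelength"]]
  if (is.null(wl_raw)) abort_format("ENVI header missing 'wavelength'")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (anyNA(wl)) abort_format("ENVI header wavelength list is not numeric")
  if (length(wl) != bands)
    abort_format(sprintf("ENVI header declares %d bands but %d wavelengths",
                         bands, length(wl)))
  n <- samples * lines * bands
  size <- if (dtype == 5L) 8L else 4L
  if (file.info(p$dat)$size != n * size)
    abort_corrupt(sprintf("'%s': payload is %d bytes, header implies %d",
                          p$dat, file.info(p$dat)$size, n * size))
  con <- file(p$dat, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = size, endian = "little")
  if (length(v) != n) abort_corrupt(sprintf("'%s': truncated payload", p$dat))
  data <- switch(interleave,
    bsq = aperm(array(v, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3, 2, 1)))
  ord <- order(wl)
  origin <- if (identical(tolower(f[["data origin"]] %||% ""), "reflectance"))
    "reflectance" else "raw_counts"
  hyper_cube(data[, , ord, drop = FALSE], wl[ord], origin)
}
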