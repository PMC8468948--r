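# Fruit-from-background segmentation: per-image PCA, PC1 min-max
# normalisation, greyscale closing, Otsu binarisation, binary opening, and
# largest-connected-component selection. Morphology and labelling are
# delegated to EBImage; components use 4-connectivity throughout.

#' Otsu threshold
#'
#' Histogram-based threshold selection maximising the between-class variance
#' over a 256-bin histogram spanning the input range. Candidate thresholds
#' are the inner bin edges; ties are broken by the lowest qualifying
#' threshold. The returned value partitions the data as `x <= t` versus
#' `x > t`.
#'
#' @param values numeric vector or matrix (NAs dropped); needs >= 2 distinct
#'   finite values.
#' @param n_bins number of histogram bins (default 256).
#' @return the scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.vector(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    abort_degenerate("Otsu threshold undefined for constant input")
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- .bincode(v, breaks, right = TRUE, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- w * centers
  omega0 <- cumsum(w)[-n_bins]          # class {<= edge k}
  m0 <- cumsum(mu)[-n_bins]
  mt <- sum(mu)
  omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mt * omega0[valid] - m0[valid])^2 /
    (omega0[valid] * omega1[valid])
  k <- which.max(sigma_b)               # which.max takes the first (lowest) tie
  breaks[k + 1L]
}

disc_brush <- function(radius) {
  if (radius < 1L) abort_parameter("structuring element radius must be >= 1")
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Binary morphological closing and opening
#'
#' Disc-structuring-element morphology on logical masks: closing
#' (dilation then erosion) fills holes and is extensive and idempotent;
#' opening (erosion then dilation) removes small objects and is
#' anti-extensive and idempotent.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (>= 1).
#' @return logical matrix of the same shape.
#' @export
morph_close <- function(mask, radius) {
  m <- EBImage::closing(mask * 1L, disc_brush(radius))
  matrix(as.logical(m > 0), nrow(mask), ncol(mask))
}

#' @rdname morph_close
#' @export
morph_open <- function(mask, radius) {
  m <- EBImage::opening(mask * 1L, disc_brush(radius))
  matrix(as.logical(m > 0), nrow(mask), ncol(mask))
}

#' Label 4-connected components
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Segment the fruit from background and calyx
#'
#' Runs the background-removal chain on a reflectance cube: a per-image PCA
#' is fitted on all pixel spectra; the PC1 score image (which carries the
#' bulk of the brightness/contrast variance) is min-max normalised to
#' \[0, 1\]; a greyscale closing suppresses dark speckle inside the fruit;
#' Otsu's threshold binarises the closed image; a binary opening removes
#' small residual objects (calyx leaf fragments, noise); finally the largest
#' 4-connected component is kept. Of the two Otsu classes, the fruit is the
#' one with the higher mean NIR reflectance (bands >= 800 nm), since the
#' fruit is reflective and the background dark.
#'
#' @param cube a reflectance `hypercube`.
#' @param close_radius disc radius of the greyscale closing (default 3).
#' @param open_radius disc radius of the binary opening (default 5).
#' @return logical fruit mask (single 4-connected component).
#' @export
segment_fruit <- function(cube, close_radius = 3L, open_radius = 5L) {
  if (!inherits(cube, "hypercube")) abort_contract("cube must be a hypercube")
  if (cube$origin != "reflectance") abort_contract("segment_fruit expects a reflectance cube")
  d <- dim(cube$data)
  X <- as_spectrum_matrix(cube)
  model <- pca_fit(X, n_components = 1L)
  pc1 <- matrix(pca_project_matrix(model, X)[, 1L], d[1], d[2])
  pc1 <- normalize_pc_image(pc1)
  closed <- EBImage::closing(pc1, disc_brush(close_radius))
  closed <- matrix(as.numeric(closed), d[1], d[2])
  thr <- otsu_threshold(closed)
  high <- closed > thr
  # orientation: the true (fruit) class has the higher mean NIR reflectance
  nir <- cube$wavelengths >= 800
  nir_mean <- function(m) {
    if (!any(m)) return(-Inf)
    mean(as_spectrum_matrix(cube, m)[, nir, drop = FALSE])
  }
  bright <- nir_mean(high); dark <- nir_mean(!high)
  fruit_cls <- if (bright >= dark) high else !high
  # a real fruit reflects far more NIR than the dark background; if the two
  # Otsu classes are comparably dark the scene contains no fruit and the
  # threshold merely split sensor noise
  if (max(bright, dark) < 2 * max(min(bright, dark), 1e-6))
    abort("fruit segmentation empty: no NIR-bright object distinct from background",
          "hsib_empty_segmentation_error")
  opened <- morph_open(fruit_cls, open_radius)
  comp <- largest_component(opened)
  if (is.null(comp))
    abort(sprintf("fruit segmentation empty: no component survived opening"),
          "hsib_empty_segmentation_error")
  comp
}
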