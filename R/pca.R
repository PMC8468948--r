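# Principal component analysis on pixel spectra: observations are pixels,
# variables are bands; column centring, no variance scaling. The solver is a
# deterministic thin SVD of the centred data matrix; signs follow the
# convention that each loading's largest-magnitude coefficient is positive,
# so fitted models are reproducible bit-for-bit.

#' Fit a PCA model on a spectrum matrix
#'
#' @param X numeric matrix, rows = observations (pixels), cols = bands.
#' @param n_components number of components to retain,
#'   `1 <= n_components <= min(rows, bands)`.
#' @return an object of class `pca_model` with fields `mean` (per-band
#'   centring vector), `loadings` (`n_components x bands`, orthonormal rows)
#'   and `evr` (explained-variance fraction per component, descending).
#' @export
pca_fit <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1L || n_components > min(n, p))
    abort_parameter("n_components must satisfy 1 <= n_components <= min(rows, bands)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = n_components)
  total <- sum(sv$d^2)
  if (total < 1e-300) abort_degenerate("PCA input has zero total variance")
  L <- t(sv$v)  # n_components x bands
  for (i in seq_len(nrow(L))) {
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  structure(list(mean = mu, loadings = L,
                 evr = (sv$d[seq_len(n_components)]^2) / total,
                 n_components = as.integer(n_components)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components x %d bands; evr: %s\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(sprintf("%.4f", x$evr), collapse = " ")))
  invisible(x)
}

#' Project spectra onto a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param X spectrum matrix with the model's band count.
#' @return score matrix (rows x components).
#' @export
pca_project_matrix <- function(model, X) {
  X <- as_matrix_rows(X)
  if (ncol(X) != ncol(model$loadings))
    abort_contract("band count of X does not match the PCA model")
  sweep(X, 2L, model$mean) %*% t(model$loadings)
}

#' Project a cube to a stack of PC score images
#'
#' Each valid pixel's spectrum is centred by the model mean and projected on
#' every loading; pixels outside the mask are `NA` and excluded from any
#' downstream statistic.
#'
#' @param cube a `hypercube` whose axis length matches the model.
#' @param mask optional logical matrix of valid pixels (`NULL` = all).
#' @param model a `pca_model`.
#' @return an object of class `pc_image_stack`: `scores` (rows x cols x
#'   components array, `NA` outside the mask) and `mask`.
#' @export
pca_project <- function(cube, mask = NULL, model) {
  if (!inherits(cube, "hypercube")) abort_contract("cube must be a hypercube")
  if (n_bands(cube) != ncol(model$loadings))
    abort_contract("cube axis length does not match the PCA model band count")
  d <- dim(cube$data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2]) else check_mask_shape(mask, cube)
  k <- nrow(model$loadings)
  S <- pca_project_matrix(model, as_spectrum_matrix(cube, mask))
  scores <- array(NA_real_, c(d[1], d[2], k))
  flat <- which(as.vector(mask))
  for (j in seq_len(k)) {
    img <- matrix(NA_real_, d[1], d[2])
    img[flat] <- S[, j]
    scores[, , j] <- img
  }
  structure(list(scores = scores, mask = mask), class = "pc_image_stack")
}

#' Min-max normalise a PC score image to \[0, 1\]
#'
#' Linearly rescales the valid (finite) pixels so the minimum maps to 0 and
#' the maximum to 1; invalid pixels stay `NA`.
#'
#' @param img numeric matrix (a single PC score image), possibly with `NA`s.
#' @return matrix of the same shape with valid values in \[0, 1\].
#' @export
normalize_pc_image <- function(img) {
  v <- img[is.finite(img)]
  if (length(unique(v)) < 2L)
    abort_degenerate("cannot normalise a constant (or empty) score image")
  (img - min(v)) / (max(v) - min(v))
}
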