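# Spectral preprocessing shared by segmentation and classification:
# Savitzky-Golay smoothing/derivatives, standard normal variate, mean
# centring with stored training means, and a pluggable cube denoiser.

as_matrix_rows <- function(X) {
  if (is.vector(X)) matrix(X, nrow = 1L) else as.matrix(X)
}

# Least-squares polynomial filter matrix C (n x n) so that Y = X %*% t(C)
# applies the filter to every row. Interior points use the centred window;
# near the edges the window is truncated one-sided and, if that leaves fewer
# than polyorder+1 samples, extended inward until the fit is determined.
sg_filter_matrix <- function(n, window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    while (hi - lo + 1L < polyorder + 1L) {
      if (lo > 1L) lo <- lo - 1L else hi <- hi + 1L
    }
    idx <- lo:hi
    A <- outer(idx - i, 0:polyorder, `^`)
    # fitted poly coefficients a = (A'A)^{-1} A' y; d-th derivative at the
    # evaluation point is d! * a_d
    P <- solve(crossprod(A), t(A))
    C[i, idx] <- factorial(deriv) * P[deriv + 1L, ]
  }
  C
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Applies the classical moving least-squares polynomial filter to each row
#' of a spectrum matrix. With `deriv = 0` this smooths while preserving any
#' polynomial of degree `polyorder` exactly; `deriv = d` returns the d-th
#' derivative of the local fit, in per-band-index units. Edge samples are
#' handled by fitting the polynomial to the truncated one-sided window
#' (extended inward to `polyorder + 1` points when necessary), so the output
#' has the same number of bands as the input.
#'
#' @param X numeric matrix (rows = spectra) or a single spectrum vector.
#' @param window odd window length >= 3.
#' @param polyorder polynomial degree, `< window`.
#' @param deriv derivative order, `<= polyorder`.
#' @return matrix of the same shape as `X`.
#' @export
savitzky_golay <- function(X, window = 5L, polyorder = 2L, deriv = 0L) {
  X <- as_matrix_rows(X)
  n <- ncol(X)
  if (window %% 2L != 1L || window < 3L) abort_parameter("window must be odd and >= 3")
  if (polyorder >= window) abort_parameter("polyorder must be < window")
  if (deriv < 0L || deriv > polyorder) abort_parameter("deriv must satisfy 0 <= deriv <= polyorder")
  if (n < window) abort_parameter("band count must be >= window")
  X %*% t(sg_filter_matrix(n, as.integer(window), as.integer(polyorder), as.integer(deriv)))
}

#' Standard normal variate transform
#'
#' Standardises each spectrum by its own mean and sample (n-1) standard
#' deviation, suppressing multiplicative scatter effects: `snv(a*x + b)`
#' equals `snv(x)` for any `a > 0`. Rows with numerically zero spread (flat
#' spectra, e.g. background pixels) map to all zeros; their count is
#' recorded in the `n_degenerate` attribute.
#'
#' @param X numeric matrix (rows = spectra) or a single spectrum vector.
#' @return matrix of the same shape, each non-degenerate row with mean 0 and
#'   sample standard deviation 1.
#' @export
snv <- function(X) {
  X <- as_matrix_rows(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1L))
  # spread at rounding-noise level relative to the row magnitude counts as
  # flat: dividing by it would only amplify float noise
  degenerate <- s <= 1e-10 * pmax(abs(m), 1e-12)
  s[degenerate] <- 1
  out <- (X - m) / s
  out[degenerate, ] <- 0
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Learn per-band means for mean centring
#'
#' @param X numeric matrix with >= 2 rows.
#' @return a recipe step carrying the column means, to be applied to
#'   training and test data alike via [recipe_apply()].
#' @export
mean_center_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) abort_parameter("mean centring needs at least 2 rows")
  list(type = "mean_center", means = colMeans(X))
}

# ------------------------------------------------------------------ recipes

#' Preprocessing recipes
#'
#' A recipe is an ordered list of steps, each `sg(window, polyorder, deriv)`,
#' `snv`, or `mean_center`. `recipe_fit()` learns any data-dependent state
#' (currently the centring means) on training data; `recipe_apply()` replays
#' the fitted steps on new data with the training statistics. Recipes
#' round-trip through plain lists (`unclass`) so a fitted pipeline is
#' serialisable to JSON/YAML.
#'
#' @param steps list of steps, e.g.
#'   `list(step_sg(3, 2, 1), step_snv(), step_mean_center())`.
#' @return an object of class `preprocess_recipe`.
#' @export
preprocess_recipe <- function(steps) {
  for (s in steps) {
    if (!is.list(s) || is.null(s$type)) abort_parameter("each step must be a named list with a 'type'")
    if (!s$type %in% c("sg", "snv", "mean_center"))
      abort_parameter(sprintf("unknown step type '%s'", s$type))
  }
  structure(list(steps = steps), class = "preprocess_recipe")
}

#' @rdname preprocess_recipe
#' @param window,polyorder,deriv Savitzky-Golay parameters.
#' @export
step_sg <- function(window = 5L, polyorder = 2L, deriv = 0L)
  list(type = "sg", window = window, polyorder = polyorder, deriv = deriv)

#' @rdname preprocess_recipe
#' @export
step_snv <- function() list(type = "snv")

#' @rdname preprocess_recipe
#' @param means per-band means; left `NULL` until fitted.
#' @export
step_mean_center <- function(means = NULL) list(type = "mean_center", means = means)

apply_step <- function(step, X) {
  switch(step$type,
    sg = savitzky_golay(X, step$window, step$polyorder, step$deriv),
    snv = snv(X),
    mean_center = {
      if (is.null(step$means)) abort_contract("mean_center step applied before fitting")
      if (length(step$means) != ncol(X)) abort_contract("mean_center step has wrong band count")
      sweep(X, 2L, step$means)
    })
}

#' @rdname preprocess_recipe
#' @param recipe a `preprocess_recipe`.
#' @param X training spectrum matrix.
#' @export
recipe_fit <- function(recipe, X) {
  X <- as_matrix_rows(X)
  steps <- recipe$steps
  for (i in seq_along(steps)) {
    if (steps[[i]]$type == "mean_center" && is.null(steps[[i]]$means))
      steps[[i]] <- mean_center_fit(X)
    X <- apply_step(steps[[i]], X)
  }
  structure(list(steps = steps), class = "preprocess_recipe")
}

#' @rdname preprocess_recipe
#' @export
recipe_apply <- function(recipe, X) {
  X <- as_matrix_rows(X)
  for (s in recipe$steps) X <- apply_step(s, X)
  X
}

# ----------------------------------------------------------------- denoising

#' Denoise a reflectance cube
#'
#' Pluggable instrumental-noise reduction stage. `"none"` (the default
#' pipeline setting) is the identity; `"gaussian_spatial"` smooths each band
#' image with a normalised Gaussian kernel (circular boundary, so each
#' band's spatial mean is conserved); `"pca_truncate"` reconstructs every
#' pixel spectrum from its top-`k` principal components.
#'
#' @param cube a reflectance-tagged `hypercube`.
#' @param method one of `"none"`, `"gaussian_spatial"`, `"pca_truncate"`.
#' @param sigma Gaussian kernel standard deviation in pixels.
#' @param k number of components kept by `pca_truncate`; must be `< bands`.
#' @return a `hypercube` of the same shape and axis.
#' @export
denoise_cube <- function(cube, method = c("none", "gaussian_spatial", "pca_truncate"),
                         sigma = 1, k = 8L) {
  method <- match.arg(method)
  if (!inherits(cube, "hypercube")) abort_contract("cube must be a hypercube")
  if (cube$origin != "reflectance") abort_contract("denoise_cube expects a reflectance cube")
  if (method == "none") return(cube)
  d <- dim(cube$data)
  if (method == "gaussian_spatial") {
    r <- max(1L, ceiling(3 * sigma))
    g <- outer(dnorm(-r:r, sd = sigma), dnorm(-r:r, sd = sigma))
    g <- g / sum(g)
    out <- cube$data
    for (b in seq_len(d[3]))
      out[, , b] <- EBImage::filter2(cube$data[, , b], g, boundary = "circular")
    out[out < 0] <- 0
    return(hyper_cube(out, cube$wavelengths, "reflectance"))
  }
  if (k >= d[3]) abort_parameter("pca_truncate requires k < band count")
  X <- as_spectrum_matrix(cube)
  model <- pca_fit(X, n_components = k)
  scores <- pca_project_matrix(model, X)
  rec <- scores %*% model$loadings + rep(model$mean, each = nrow(X))
  rec[rec < 0] <- 0
  rec[rec > 1.5] <- 1.5
  hyper_cube(array(rec, d), cube$wavelengths, "reflectance")
}
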