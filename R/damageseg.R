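# Bruise detection inside the fruit mask: pixel spectra are smoothed
# (Savitzky-Golay) and scatter-corrected (SNV), projected onto a damage PCA
# model fitted once on a small training subset, and the selected PC score
# image is Otsu-thresholded; candidate regions are filtered by area,
# circularity and closeness to the fruit boundary before the fruit is
# declared damaged or intact.

#' Damage-PCA configuration
#'
#' @param n_components number of principal components fitted (default 8).
#' @param selected_pc which PC score image is thresholded for damage
#'   (default 6, the component found to delimit bruise contours best on real
#'   persimmon images; for other datasets choose by inspecting the PC
#'   images).
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay parameters applied
#'   to pixel spectra before SNV (default 5-point, 2nd order, smoothing).
#' @param per_day number of training images sampled per day class when
#'   fitting the damage PCA (default 2); `NULL` uses every image offered.
#' @return an object of class `damage_pca_config`.
#' @export
damage_pca_config <- function(n_components = 8L, selected_pc = 6L,
                              sg_window = 5L, sg_polyorder = 2L, sg_deriv = 0L,
                              per_day = 2L) {
  if (selected_pc < 1L || selected_pc > n_components)
    abort_parameter("selected_pc must satisfy 1 <= selected_pc <= n_components")
  structure(list(n_components = as.integer(n_components),
                 selected_pc = as.integer(selected_pc),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 per_day = if (is.null(per_day)) NULL else as.integer(per_day)),
            class = "damage_pca_config")
}

#' Region filter for damage candidates
#'
#' Removes segmentation artifacts: regions smaller than `min_area` pixels
#' (`NULL` = 0.2% of the fruit area), less compact than `min_circularity`
#' (long narrow structures typical of illumination errors near the fruit
#' edge), or with more than `max_boundary_fraction` of their pixels inside a
#' `rim_width`-pixel rim along the fruit boundary.
#'
#' @param min_area minimum region area in pixels, or `NULL` for 0.2% of the
#'   fruit area.
#' @param min_circularity minimum isoperimetric circularity in \[0, 1\].
#' @param max_boundary_fraction maximum tolerated fraction of region pixels
#'   in the boundary rim.
#' @param rim_width rim width in pixels.
#' @return an object of class `region_filter`.
#' @export
region_filter <- function(min_area = NULL, min_circularity = 0.3,
                          max_boundary_fraction = 0.5, rim_width = 3L) {
  if (!is.null(min_area) && min_area < 1) abort_parameter("min_area must be >= 1")
  if (min_circularity < 0 || min_circularity > 1)
    abort_parameter("min_circularity must be in [0, 1]")
  structure(list(min_area = min_area, min_circularity = min_circularity,
                 max_boundary_fraction = max_boundary_fraction,
                 rim_width = as.integer(rim_width)),
            class = "region_filter")
}

# Moore-neighbour boundary trace of a single connected region; returns the
# closed chain length with orthogonal steps counting 1 and diagonal steps
# sqrt(2). Single pixels (and dominoes) have degenerate chains; circularity
# handles them via the cap.
trace_perimeter <- function(mask) {
  n <- sum(mask)
  if (n == 1L) return(0)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # clockwise from W
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  # start: first foreground pixel in row-major scan; its W neighbour is bg
  start <- NULL
  for (i in seq_len(nr + 2L)) {
    j <- which(m[i, ])[1]
    if (!is.na(j)) { start <- c(i, j); break }
  }
  cur <- start
  dir_from <- 1L  # index into dirs of the backtrack (W of start)
  per <- 0
  first_move <- NULL
  max_steps <- 8L * n + 16L  # safety bound; a Moore trace is O(boundary)
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) break
    found <- FALSE
    for (s in seq_len(8L)) {
      k <- ((dir_from - 1L + s - 1L) %% 8L) + 1L
      nb <- cur + dirs[k, ]
      if (m[nb[1], nb[2]]) {
        step <- if (sum(abs(dirs[k, ])) == 2L) sqrt(2) else 1
        per <- per + step
        # next search starts from the neighbour we examined just before k,
        # rotated to point back toward the previous pixel
        dir_from <- ((k - 1L - 2L) %% 8L) + 1L
        if (is.null(first_move)) first_move <- k
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(0)  # isolated pixel (shouldn't reach: n > 1 connected)
    if (all(cur == start)) {
      # Jacob's criterion: stop on re-entering start via the initial move
      nxt_found <- NA
      for (s in seq_len(8L)) {
        k <- ((dir_from - 1L + s - 1L) %% 8L) + 1L
        nb <- cur + dirs[k, ]
        if (m[nb[1], nb[2]]) { nxt_found <- k; break }
      }
      if (identical(nxt_found, first_move)) break
    }
  }
  per
}

#' Isoperimetric circularity of a pixel region
#'
#' `4 * pi * area / perimeter^2`, capped at 1, with the perimeter measured
#' as the length of the Moore-neighbour boundary chain of the region
#' (orthogonal steps 1, diagonal steps `sqrt(2)`). A rasterised disk scores
#' near 1, a one-pixel-wide line near 0; a single pixel is defined as 1.
#'
#' @param mask logical matrix containing one nonempty connected region.
#' @return circularity in \[0, 1\].
#' @export
circularity <- function(mask) {
  a <- sum(mask)
  if (a == 0L) abort_contract("circularity of an empty region is undefined")
  if (a == 1L) return(1)
  p <- trace_perimeter(mask)
  if (p <= 0) return(1)
  min(1, 4 * pi * a / p^2)
}

preprocess_pixels <- function(S, cfg)
  snv(savitzky_golay(S, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv))

#' Fit the damage PCA on a training subset
#'
#' Randomly selects `cfg$per_day` images per day class (seeded), pools their
#' fruit pixels, applies the configured Savitzky-Golay smoothing and SNV to
#' every pixel spectrum, and fits a `cfg$n_components`-component PCA. The
#' fitted model is reused, unchanged, for all subsequent images.
#'
#' @param cubes list of reflectance `hypercube`s.
#' @param masks list of fruit masks aligned with `cubes`.
#' @param days vector of day labels (one per cube) in `{0, 1, 2, 3}`.
#' @param cfg a `damage_pca_config`.
#' @param seed integer; controls the training-image sampling only.
#' @return a `pca_model`.
#' @export
fit_damage_pca <- function(cubes, masks, days, cfg = damage_pca_config(), seed = 1L) {
  if (length(cubes) != length(masks) || length(cubes) != length(days))
    abort_contract("cubes, masks and days must have equal length")
  sel <- integer(0)
  for (d in sort(unique(days))) {
    idx <- which(days == d)
    if (length(idx) == 0L) abort_contract(sprintf("no training cube for day %s", d))
    take <- if (is.null(cfg$per_day)) length(idx) else min(cfg$per_day, length(idx))
    sel <- c(sel, with_seed(seed + as.integer(d),
                            sort(sample(idx, take, replace = FALSE))))
  }
  X <- do.call(rbind, lapply(sel, function(i)
    as_spectrum_matrix(cubes[[i]], masks[[i]])))
  if (nrow(X) < 10L * cfg$n_components)
    abort_insufficient(sprintf("only %d training pixels for %d components",
                               nrow(X), cfg$n_components))
  pca_fit(preprocess_pixels(X, cfg), cfg$n_components)
}

region_stats <- function(lab, fruit_mask, rim) {
  ids <- seq_len(max(lab))
  do.call(rbind, lapply(ids, function(id) {
    reg <- lab == id
    a <- sum(reg)
    ij <- which(reg, arr.ind = TRUE)
    data.frame(id = id, area = a, circularity = circularity(reg),
               centroid_row = mean(ij[, 1]), centroid_col = mean(ij[, 2]),
               boundary_fraction = sum(reg & rim) / a)
  }))
}

#' Detect and delineate damage inside the fruit
#'
#' Preprocesses the fruit pixels (Savitzky-Golay smoothing, SNV), projects
#' them onto the damage PCA model, Otsu-thresholds the selected PC score
#' image over the fruit pixels, takes the minority class as the damage
#' candidate (a bruise is a localised subregion; the PC sign is arbitrary),
#' labels 4-connected candidate regions and removes those failing the
#' region filter. The fruit is `"damaged"` iff at least one region survives;
#' the mean damage spectrum is the mean raw (calibrated, un-preprocessed)
#' reflectance over all surviving damage pixels.
#'
#' @param cube reflectance `hypercube`.
#' @param fruit_mask logical fruit mask from [segment_fruit()].
#' @param model damage `pca_model` from [fit_damage_pca()].
#' @param cfg a `damage_pca_config` (must match the model's preprocessing).
#' @param filt a `region_filter`.
#' @return an object of class `damage_result`: `verdict` ("intact" or
#'   "damaged"), `damage_mask`, `regions` (data frame of candidate region
#'   statistics with a `kept` column), `mean_damage_spectrum` (or `NULL`),
#'   and `degenerate` (TRUE when the fruit had no spectral contrast).
#' @export
segment_damage <- function(cube, fruit_mask, model, cfg = damage_pca_config(),
                           filt = region_filter()) {
  if (!inherits(cube, "hypercube")) abort_contract("cube must be a hypercube")
  check_mask_shape(fruit_mask, cube)
  if (!any(fruit_mask)) abort_contract("fruit mask is empty")
  if (n_bands(cube) != ncol(model$loadings))
    abort_contract("cube band count does not match the damage PCA model")
  d <- dim(cube$data)
  S <- as_spectrum_matrix(cube, fruit_mask)
  scores <- pca_project_matrix(model, preprocess_pixels(S, cfg))[, cfg$selected_pc]
  empty_result <- function(degenerate) {
    structure(list(verdict = "intact",
                   damage_mask = matrix(FALSE, d[1], d[2]),
                   regions = NULL, mean_damage_spectrum = NULL,
                   degenerate = degenerate),
              class = "damage_result")
  }
  rng <- range(scores)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1e-300))
    return(empty_result(degenerate = TRUE))  # no spectral contrast in the fruit
  thr <- tryCatch(otsu_threshold(scores),
                  hsib_degenerate_error = function(e) NULL)
  if (is.null(thr)) return(empty_result(degenerate = TRUE))
  high <- scores > thr
  minority <- if (sum(high) <= sum(!high)) high else !high
  cand <- matrix(FALSE, d[1], d[2])
  cand[which(as.vector(fruit_mask))[minority]] <- TRUE
  lab <- label_components(cand)
  if (max(lab) == 0L) return(empty_result(degenerate = FALSE))
  eroded <- EBImage::erode(fruit_mask * 1L, disc_brush(filt$rim_width)) > 0
  rim <- fruit_mask & !matrix(eroded, d[1], d[2])
  stats <- region_stats(lab, fruit_mask, rim)
  min_area <- filt$min_area %||% max(1, round(0.002 * sum(fruit_mask)))
  stats$kept <- stats$area >= min_area &
    stats$circularity >= filt$min_circularity &
    stats$boundary_fraction <= filt$max_boundary_fraction
  damage_mask <- matrix(lab %in% stats$id[stats$kept], d[1], d[2])
  if (!any(damage_mask)) {
    res <- empty_result(degenerate = FALSE)
    res$regions <- stats
    return(res)
  }
  structure(list(verdict = "damaged", damage_mask = damage_mask,
                 regions = stats,
                 mean_damage_spectrum = colMeans(as_spectrum_matrix(cube, damage_mask)),
                 degenerate = FALSE),
            class = "damage_result")
}

#' @export
print.damage_result <- function(x, ...) {
  cat(sprintf("<damage_result> verdict: %s; damage pixels: %d; regions kept: %d\n",
              x$verdict, sum(x$damage_mask),
              if (is.null(x$regions)) 0L else sum(x$regions$kept)))
  invisible(x)
}
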