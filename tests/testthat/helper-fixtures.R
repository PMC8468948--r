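# Shared fixtures (memoised, built once per test run) and independent
# oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_templates <- function() fixture("templates", make_templates())

# pipeline config for the synthetic scenes: the bruise contrast of the
# generator's low-rank spectra concentrates in the leading components, so
# PC2 is the score image thresholded for damage (chosen once by inspecting
# the PC images, as one would for any new dataset)
synth_config <- function() pipeline_config(pca = damage_pca_config(selected_pc = 2L))

make_scene <- function(seed, day = "intact", noise_sd = 0.01, contrast = 1,
                       templates = NULL) {
  tmpl <- if (!is.null(templates)) templates
          else if (contrast == 1) fx_templates() else make_templates(contrast)
  sp <- hsibruise:::random_scene_spec(seed)
  sp$noise_sd <- noise_sd
  generate_cube(sp, tmpl, day)
}

# damage PCA fitted on 2 training cubes per day (the model-building recipe)
fx_training <- function() fixture("training", {
  cubes <- list(); masks <- list(); days <- integer(0); k <- 0L
  for (d in 0:3) for (i in 1:2) {
    k <- k + 1L
    g <- make_scene(100L + 10L * d + i, day = d)
    cubes[[k]] <- g$cube
    masks[[k]] <- segment_fruit(g$cube)
    days[k] <- d
  }
  list(cubes = cubes, masks = masks, days = days)
})

fx_damage_model <- function() fixture("damage_model", {
  tr <- fx_training()
  fit_damage_pca(tr$cubes, tr$masks, tr$days, synth_config()$pca, seed = 1L)
})

iou <- function(a, b) sum(a & b) / sum(a | b)

# ------------------------------------------------------------- oracles

# Exhaustive-search Otsu: explicit loop over every inner edge of the same
# 256-bin histogram, recomputing class weights and means by brute force.
oracle_otsu <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0L] <- 1L
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    in0 <- bin <= k
    w0 <- mean(in0)
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(centers[bin[in0]]); mu1 <- mean(centers[bin[!in0]])
    sb <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_k <- k }  # strict: ties -> lowest edge
  }
  breaks[best_k + 1L]
}

# Independent boundary-walk perimeter: chain length along EBImage's oriented
# contour of the (single) region.
oracle_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1L))[[1L]]
  if (nrow(oc) < 2L) return(0)
  steps <- rbind(diff(oc), oc[1L, ] - oc[nrow(oc), ])
  sum(sqrt(rowSums(steps^2)))
}

oracle_circularity <- function(mask) {
  a <- sum(mask)
  if (a == 1L) return(1)
  p <- oracle_perimeter(mask)
  if (p <= 0) return(1)
  min(1, 4 * pi * a / p^2)
}

# Per-point least-squares polynomial fit (the brute-force Savitzky-Golay
# oracle), interior points only.
oracle_sg_point <- function(y, i, window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  idx <- (i - h):(i + h)
  fit <- lm(y[idx] ~ poly(idx - i, polyorder, raw = TRUE))
  factorial(deriv) * coef(fit)[[deriv + 1L]]
}

# Brute-force PCA: eigendecomposition of the explicit covariance matrix,
# with the same largest-coefficient-positive sign convention.
oracle_pca <- function(X, k) {
  e <- eigen(cov(X), symmetric = TRUE)
  L <- t(e$vectors[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  list(loadings = L, evr = e$values[seq_len(k)] / sum(e$values))
}
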