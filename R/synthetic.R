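# Synthetic persimmon hypercube generator. A scene is a fruit ellipse with a
# star-shaped calyx patch at its top on a dark background, optionally with a
# circular bruise whose radius grows with days after damage induction.
# Spectral templates are smooth invented curves constrained to reproduce the
# qualitative day-wise orderings observed in real fruit: the intact spectrum
# is highest over 450-660 nm with the damaged spectra decreasing with age,
# the order flips at 670 nm (chlorophyll loss in bruised tissue), and in the
# 970 nm water-absorption valley the freshest bruise is darkest (free water)
# with reflectance recovering as the tissue dries.

#' Spectral templates for the synthetic scenes
#'
#' Builds intact, damaged (days 0-3), calyx and background reflectance
#' curves on the default 60-band axis. `contrast` linearly scales the
#' damaged-vs-intact separation; at `contrast = 0` every damaged spectrum
#' collapses onto the intact one.
#'
#' @param contrast separation scale in (0, 1\] (0 allowed for the collapse
#'   limit).
#' @return an object of class `spectral_templates` with fields
#'   `wavelengths`, `intact`, `damaged` (4 x bands matrix, rows = days 0-3),
#'   `calyx`, `background`, `contrast`.
#' @export
make_templates <- function(contrast = 1) {
  if (contrast < 0 || contrast > 1) abort_parameter("contrast must be in [0, 1]")
  wl <- default_wavelengths()
  base  <- 0.22 + 0.46 / (1 + exp(-(wl - 620) / 45))
  water <- exp(-((wl - 970) / 40)^2)          # 970 nm absorption valley
  chl   <- exp(-((wl - 670) / 12)^2)          # chlorophyll feature, intact skin
  visw  <- 1 / (1 + exp((wl - 672) / 14))     # ~1 in VIS, ~0 in NIR
  intact <- base - 0.12 * chl - 0.06 * water
  damaged <- t(vapply(0:3, function(day) {
    full <- base - (0.07 + 0.03 * day) * visw - (0.20 - 0.03 * day) * water
    intact + contrast * (full - intact)
  }, numeric(length(wl))))
  calyx <- 0.10 + 0.05 * exp(-((wl - 550) / 25)^2) +
    0.18 / (1 + exp(-(wl - 720) / 25)) - 0.03 * water - 0.05 * chl
  background <- rep(0.04, length(wl))
  structure(list(wavelengths = wl, intact = intact, damaged = damaged,
                 calyx = calyx, background = background, contrast = contrast),
            class = "spectral_templates")
}

#' Scene specification for one synthetic cube
#'
#' @param size image size `c(rows, cols)` (default 128 x 128).
#' @param centre fruit ellipse centre `c(row, col)`.
#' @param semi_axes fruit ellipse semi-axes `c(row, col)` in pixels.
#' @param calyx `NULL` for no calyx, else a list with `radius` (mean star
#'   radius), `points` (number of star points) and `amplitude` (radial
#'   modulation, 0-1); the star is centred on the top vertex of the ellipse.
#' @param bruise `NULL` for intact scenes, else a list with `centre`
#'   `c(row, col)` and per-day `radius` vector (days 0-3); radii must be
#'   nondecreasing and each disc must lie inside the fruit ellipse.
#' @param vignette_strength radial illumination falloff at the image corner
#'   (0 = flat illumination; default 0.15).
#' @param noise_sd additive Gaussian sensor noise, reflectance units
#'   (default 0.01).
#' @param seed integer; fully determines the generated cube.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(128L, 128L),
                       centre = c(66, 64),
                       semi_axes = c(42, 38),
                       calyx = list(radius = 14, points = 6, amplitude = 0.45),
                       bruise = list(centre = c(78, 74), radius = c(7, 9, 11, 13)),
                       vignette_strength = 0.15,
                       noise_sd = 0.01,
                       seed = 1L) {
  if (!is.null(bruise)) {
    if (is.unsorted(bruise$radius)) abort_parameter("bruise radii must be nondecreasing over days")
    th <- seq(0, 2 * pi, length.out = 64L)
    for (r in bruise$radius) {
      pr <- bruise$centre[1] + r * sin(th); pc <- bruise$centre[2] + r * cos(th)
      if (any(((pr - centre[1]) / semi_axes[1])^2 +
              ((pc - centre[2]) / semi_axes[2])^2 > 1))
        abort(sprintf("bruise disc (radius %.1f) is not fully inside the fruit ellipse", r),
              "hsib_spec_error")
    }
  }
  structure(list(size = as.integer(size), centre = centre, semi_axes = semi_axes,
                 calyx = calyx, bruise = bruise,
                 vignette_strength = vignette_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

scene_masks <- function(spec, day) {
  nr <- spec$size[1]; nc <- spec$size[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ellipse <- ((rows - spec$centre[1]) / spec$semi_axes[1])^2 +
             ((cols - spec$centre[2]) / spec$semi_axes[2])^2 <= 1
  calyx <- matrix(FALSE, nr, nc)
  if (!is.null(spec$calyx)) {
    top <- c(spec$centre[1] - spec$semi_axes[1], spec$centre[2])
    dr <- rows - top[1]; dc <- cols - top[2]
    rr <- sqrt(dr^2 + dc^2)
    th <- atan2(dc, dr)
    calyx <- rr <= spec$calyx$radius *
      (1 + spec$calyx$amplitude * cos(spec$calyx$points * th))
  }
  bruise <- matrix(FALSE, nr, nc)
  if (!identical(day, "intact")) {
    if (is.null(spec$bruise)) abort("scene has no bruise specification", "hsib_spec_error")
    d <- as.integer(day)
    r <- spec$bruise$radius[d + 1L]
    bruise <- (rows - spec$bruise$centre[1])^2 +
              (cols - spec$bruise$centre[2])^2 <= r^2
  }
  fruit <- ellipse & !calyx
  bruise <- bruise & fruit
  list(fruit = fruit, calyx = calyx, bruise = bruise, ellipse = ellipse)
}

#' Generate one synthetic hypercube with ground truth
#'
#' Renders the scene: each pixel takes its region's template spectrum
#' (background, intact fruit, bruised fruit for the given day, or calyx),
#' multiplied by a radial vignette factor
#' `1 - vignette_strength * (r / r_corner)^2` about the image centre, plus
#' i.i.d. Gaussian noise, clipped below at 0. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a `scene_spec`.
#' @param templates a `spectral_templates`.
#' @param day `"intact"` or a day in `0:3`.
#' @return list with `cube` (reflectance `hypercube`) and `masks`
#'   (logical `fruit`, `calyx`, `bruise`; `fruit` excludes the calyx).
#' @export
generate_cube <- function(spec, templates = make_templates(), day = "intact") {
  if (!identical(day, "intact") && !(as.integer(day) %in% 0:3))
    abort_parameter("day must be \"intact\" or one of 0:3")
  masks <- scene_masks(spec, day)
  nr <- spec$size[1]; nc <- spec$size[2]
  nb <- length(templates$wavelengths)
  region <- matrix(1L, nr, nc)                 # 1 background
  region[masks$fruit] <- 2L                    # 2 intact fruit
  if (any(masks$bruise)) region[masks$bruise] <- 3L
  region[masks$calyx] <- 4L
  tmpl <- rbind(templates$background, templates$intact,
                if (identical(day, "intact")) templates$intact
                else templates$damaged[as.integer(day) + 1L, ],
                templates$calyx)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rmax2 <- ((nr - 1) / 2)^2 + ((nc - 1) / 2)^2
  vig <- 1 - spec$vignette_strength *
    ((rows - (nr + 1) / 2)^2 + (cols - (nc + 1) / 2)^2) / rmax2
  flat <- tmpl[as.vector(region), , drop = FALSE] * as.vector(vig)
  if (spec$noise_sd > 0)
    flat <- flat + with_seed(spec$seed,
      matrix(stats::rnorm(length(flat), sd = spec$noise_sd), nrow(flat), ncol(flat)))
  flat[flat < 0] <- 0
  flat[flat > 1.5] <- 1.5
  cube <- hyper_cube(array(flat, c(nr, nc, nb)), templates$wavelengths, "reflectance")
  list(cube = cube, masks = masks[c("fruit", "calyx", "bruise")])
}

random_scene_spec <- function(seed, size = c(128L, 128L)) {
  s <- min(size) / 128  # geometry scales with resolution
  with_seed(seed, {
    centre <- c(size[1] / 2 + stats::runif(1, -4, 8) * s,
                size[2] / 2 + stats::runif(1, -6, 6) * s)
    semi <- c(stats::runif(1, 37, 44), stats::runif(1, 33, 40)) * s
    # bruise centre at a normalised ellipse radius <= 0.55, below the calyx
    repeat {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.55
      bc <- c(centre[1] + rad * semi[1] * sin(ang), centre[2] + rad * semi[2] * cos(ang))
      if (bc[1] > centre[1] - 0.45 * semi[1]) break  # keep clear of the calyx
    }
    scene_spec(size = size, centre = centre, semi_axes = semi,
               calyx = list(radius = 14 * s, points = 6, amplitude = 0.45),
               bruise = list(centre = bc, radius = pmax(4, c(7, 9, 11, 13) * s)),
               seed = seed)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Writes `n_per_class` cubes for each of the five states (intact and days
#' 0-3 after damage induction) with randomised fruit/bruise geometry, plus
#' ground-truth masks (PNG) and a manifest CSV with columns `path`, `state`,
#' `fruit_mask`, `calyx_mask`, `bruise_mask`, `seed`. Deterministic per
#' seed. With `write = FALSE` nothing touches disk and the cubes and masks
#' are returned in memory (the manifest then carries empty paths).
#'
#' @param n_per_class cubes per state (>= 1).
#' @param out_dir output directory (created if needed) when writing.
#' @param seed dataset seed; per-cube seeds are derived from it.
#' @param templates a `spectral_templates`.
#' @param format cube file format, `"portable"` or `"envi"`.
#' @param size image size.
#' @param write write files (default) or return everything in memory.
#' @return list with `manifest` (data frame) and, when `write = FALSE`,
#'   `scenes` (list of `generate_cube()` results).
#' @export
generate_dataset <- function(n_per_class, out_dir = NULL, seed = 1L,
                             templates = make_templates(),
                             format = c("portable", "envi"),
                             size = c(128L, 128L), write = TRUE) {
  format <- match.arg(format)
  if (n_per_class < 1L) abort_parameter("n_per_class must be >= 1")
  if (write) {
    if (is.null(out_dir)) abort_parameter("out_dir is required when write = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  states <- c("intact", "0", "1", "2", "3")
  rows <- list(); scenes <- list()
  k <- 0L
  for (si in seq_along(states)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      cube_seed <- as.integer(seed) + 1000L * si + i
      spec <- random_scene_spec(cube_seed, size = size)
      day <- if (states[si] == "intact") "intact" else as.integer(states[si])
      scene <- generate_cube(spec, templates, day)
      stem <- sprintf("cube_%s_%03d", states[si], i)
      if (write) {
        ext <- if (format == "portable") ".rds" else ""
        cube_path <- file.path(out_dir, paste0(stem, ext))
        write_cube(scene$cube, cube_path, format = format)
        mask_paths <- vapply(c("fruit", "calyx", "bruise"), function(nm) {
          mp <- file.path(out_dir, sprintf("%s_%s.png", stem, nm))
          write_mask_png(scene$masks[[nm]], mp)
          mp
        }, character(1))
      } else {
        cube_path <- ""
        mask_paths <- c(fruit = "", calyx = "", bruise = "")
        scenes[[k]] <- scene
      }
      rows[[k]] <- data.frame(path = cube_path, state = states[si],
                              fruit_mask = mask_paths[["fruit"]],
                              calyx_mask = mask_paths[["calyx"]],
                              bruise_mask = mask_paths[["bruise"]],
                              seed = cube_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  if (write) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    list(manifest = manifest)
  } else {
    list(manifest = manifest, scenes = scenes)
  }
}

#' Write / read a binary mask as 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @return `invisible(path)` / logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}
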