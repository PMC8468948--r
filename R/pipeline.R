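# End-to-end orchestration: configuration, the detection run (calibrate ->
# denoise -> fruit segmentation -> damage segmentation), the aging run
# (PLS-DA on the mean damage spectra of detected-damaged fruit), overlay
# rendering, and the command-line entry points.

#' Pipeline configuration
#'
#' Bundles every tunable of the detection and aging stages. The effective
#' config of a run is serialised (JSON) next to its outputs so results are
#' reproducible.
#'
#' @param close_radius,open_radius fruit-segmentation structuring-element
#'   radii (pixels).
#' @param denoise_method,denoise_sigma,denoise_k cube denoising stage; the
#'   default is `"none"` (the pipeline's logic does not depend on the
#'   denoiser choice; plug in `"gaussian_spatial"` or `"pca_truncate"` for
#'   noisy sensors).
#' @param pca a `damage_pca_config`.
#' @param filter a `region_filter`.
#' @param age_sg_deriv derivative order of the 3-point Savitzky-Golay step
#'   in the aging recipe (default 1, the conventional first derivative).
#' @param max_lv,cv_folds latent-variable search range and fold count.
#' @param seed default seed for seeded stages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(close_radius = 3L, open_radius = 5L,
                            denoise_method = "none", denoise_sigma = 1,
                            denoise_k = 8L,
                            pca = damage_pca_config(),
                            filter = region_filter(),
                            age_sg_deriv = 1L, max_lv = 15L, cv_folds = 10L,
                            seed = 1L) {
  structure(list(close_radius = as.integer(close_radius),
                 open_radius = as.integer(open_radius),
                 denoise_method = denoise_method,
                 denoise_sigma = denoise_sigma, denoise_k = as.integer(denoise_k),
                 pca = pca, filter = filter,
                 age_sg_deriv = as.integer(age_sg_deriv),
                 max_lv = as.integer(max_lv), cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(cfg) {
  lst <- unclass(cfg)
  lapply(lst, function(el) if (is.list(el)) config_to_list(el) else el)
}

#' Read a pipeline config from YAML or JSON
#'
#' Unspecified fields keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path), "hsib_io_error")
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  args <- list()
  for (nm in c("close_radius", "open_radius", "denoise_method", "denoise_sigma",
               "denoise_k", "age_sg_deriv", "max_lv", "cv_folds", "seed"))
    if (!is.null(lst[[nm]])) args[[nm]] <- lst[[nm]]
  if (!is.null(lst$pca)) args$pca <- do.call(damage_pca_config, lst$pca)
  if (!is.null(lst$filter)) args$filter <- do.call(region_filter, lst$filter)
  do.call(pipeline_config, args)
}

# day -> overlay colour; plain detection (no age) renders in blue
overlay_colors <- function() {
  list("0" = c(1, 0, 1), "1" = c(0, 1, 0), "2" = c(1, 0, 0), "3" = c(0, 0, 1),
       detect = c(0, 0, 1))
}

#' Render a colour-coded damage overlay
#'
#' Greyscale mean-reflectance image of the scene with the damage pixels
#' coloured: blue for plain detection, or the fixed day colour map
#' (0 = magenta, 1 = green, 2 = red, 3 = blue) once an age has been
#' assigned.
#'
#' @param cube reflectance `hypercube`.
#' @param damage_mask logical damage mask.
#' @param day `NULL` (detection only) or a day in `0:3`.
#' @return rows x cols x 3 RGB array in \[0, 1\].
#' @export
render_overlay <- function(cube, damage_mask, day = NULL) {
  grey <- apply(cube$data, c(1, 2), mean)
  rng <- range(grey)
  if (diff(rng) > 0) grey <- (grey - rng[1]) / diff(rng)
  col <- if (is.null(day)) overlay_colors()$detect
         else overlay_colors()[[as.character(day)]]
  img <- array(rep(grey, 3L), c(dim(grey), 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[damage_mask] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

# Normalise heterogeneous inputs (manifest data frame, paths, cubes, or
# zero-argument loader closures) into loaders + labels.
as_cube_loaders <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    if (is.null(x$path)) abort_contract("manifest must have a 'path' column")
    labels <- labels %||% x$state
    loaders <- lapply(x$path, function(p) local({ pp <- p; function() read_cube(pp) }))
    ids <- basename(as.character(x$path))
  } else if (is.character(x)) {
    loaders <- lapply(x, function(p) local({ pp <- p; function() read_cube(pp) }))
    ids <- basename(x)
  } else if (is.list(x)) {
    loaders <- lapply(seq_along(x), function(i) {
      el <- x[[i]]
      if (inherits(el, "hypercube")) local({ e <- el; function() e })
      else if (is.function(el)) el
      else abort_contract("list inputs must be hypercubes or loader functions")
    })
    ids <- names(x) %||% sprintf("cube_%04d", seq_along(x))
    if (is.null(names(x))) ids <- sprintf("cube_%04d", seq_along(x))
  } else abort_contract("unsupported input type for cube collection")
  if (length(loaders) == 0L) abort_parameter("empty input list")
  list(loaders = loaders, labels = labels, ids = ids)
}

#' Fit the damage PCA from a manifest or cube collection
#'
#' Convenience wrapper: loads (or receives) the damaged-state cubes,
#' segments each fruit, and fits the damage PCA on `cfg$pca$per_day`
#' randomly selected images per day.
#'
#' @param x manifest data frame, character paths, or list of cubes/loaders.
#' @param labels day labels per cube (taken from the manifest's `state`
#'   column when omitted); `"intact"` entries are ignored.
#' @param config a `pipeline_config`.
#' @param seed training-image sampling seed.
#' @return a `pca_model`.
#' @export
train_damage_pca <- function(x, labels = NULL, config = pipeline_config(),
                             seed = config$seed) {
  inp <- as_cube_loaders(x, labels)
  keep <- which(inp$labels %in% c("0", "1", "2", "3", 0, 1, 2, 3))
  if (length(keep) == 0L) abort_contract("no damaged-state cubes to train on")
  days <- as.integer(inp$labels[keep])
  # sample per day first so only the selected cubes are ever loaded
  cfg <- config$pca
  sel <- integer(0)
  for (d in sort(unique(days))) {
    idx <- which(days == d)
    take <- if (is.null(cfg$per_day)) length(idx) else min(cfg$per_day, length(idx))
    sel <- c(sel, with_seed(seed + d, sort(sample(idx, take))))
  }
  cubes <- lapply(inp$loaders[keep][sel], function(f) prepare_cube(f(), config))
  masks <- lapply(cubes, segment_fruit,
                  close_radius = config$close_radius, open_radius = config$open_radius)
  all_cfg <- damage_pca_config(n_components = cfg$n_components,
                               selected_pc = cfg$selected_pc,
                               sg_window = cfg$sg_window,
                               sg_polyorder = cfg$sg_polyorder,
                               sg_deriv = cfg$sg_deriv, per_day = NULL)
  fit_damage_pca(cubes, masks, days[sel], all_cfg, seed = seed)
}

prepare_cube <- function(cube, config, refs = NULL) {
  if (cube$origin == "raw_counts") {
    if (is.null(refs)) abort_contract("raw-counts cube given without a reference_set")
    cube <- calibrate_reflectance(cube, refs)
  }
  denoise_cube(cube, method = config$denoise_method,
               sigma = config$denoise_sigma, k = config$denoise_k)
}

#' Run damage detection over a cube collection
#'
#' Per image: (calibrate if raw counts and references are given) -> denoise
#' -> fruit segmentation -> damage segmentation. Per-image failures are
#' logged and skipped; the run fails only if every image fails. When
#' `out_dir` is given, each image's verdict/regions/spectrum JSON, damage
#' mask PNG and blue-coded overlay PNG are written, along with
#' `summary.csv`, a per-state verdict table `by_state.csv`, the effective
#' `config.json` and a `run_manifest.csv` referencing every output file.
#'
#' @param x manifest data frame, character paths, or list of
#'   cubes / loader closures.
#' @param model damage `pca_model` from [train_damage_pca()].
#' @param config a `pipeline_config`.
#' @param labels optional true state per cube (for the summary table).
#' @param refs optional `reference_set` for raw-counts input.
#' @param out_dir optional output directory.
#' @return list with `results` (per image: verdict, regions, spectrum,
#'   damage area) and `summary` (data frame).
#' @export
run_detect <- function(x, model, config = pipeline_config(), labels = NULL,
                       refs = NULL, out_dir = NULL) {
  inp <- as_cube_loaders(x, labels)
  n <- length(inp$loaders)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- vector("list", n)
  rows <- vector("list", n)
  n_fail <- 0L
  out_files <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      cube <- prepare_cube(inp$loaders[[i]](), config, refs)
      fruit <- segment_fruit(cube, config$close_radius, config$open_radius)
      dmg <- segment_damage(cube, fruit, model, config$pca, config$filter)
      list(id = inp$ids[i], verdict = dmg$verdict,
           damage_area = sum(dmg$damage_mask),
           n_regions = if (is.null(dmg$regions)) 0L else sum(dmg$regions$kept),
           degenerate = dmg$degenerate,
           mean_damage_spectrum = dmg$mean_damage_spectrum,
           damage_mask = dmg$damage_mask, fruit_area = sum(fruit),
           regions = dmg$regions, cube = if (!is.null(out_dir)) cube else NULL)
    }, hsib_error = function(e) {
      message(sprintf("detect: skipping image %s: %s", inp$ids[i], conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    if (!is.null(out_dir)) {
      stem <- tools::file_path_sans_ext(res$id)
      jp <- file.path(out_dir, paste0(stem, "_damage.json"))
      jsonlite::write_json(list(id = res$id, verdict = res$verdict,
                                damage_area = res$damage_area,
                                n_regions = res$n_regions,
                                mean_damage_spectrum = res$mean_damage_spectrum,
                                regions = res$regions),
                           jp, auto_unbox = TRUE, digits = NA, null = "null")
      mp <- file.path(out_dir, paste0(stem, "_damage_mask.png"))
      write_mask_png(res$damage_mask, mp)
      op <- file.path(out_dir, paste0(stem, "_overlay.png"))
      png::writePNG(render_overlay(res$cube, res$damage_mask), op)
      out_files <- c(out_files, jp, mp, op)
      res$cube <- NULL
    }
    results[[i]] <- res
    rows[[i]] <- data.frame(id = res$id,
                            label = if (is.null(inp$labels)) NA_character_
                                    else as.character(inp$labels[i]),
                            verdict = res$verdict, n_regions = res$n_regions,
                            damage_area = res$damage_area,
                            fruit_area = res$fruit_area)
  }
  if (n_fail == n) abort(sprintf("all %d images failed detection", n), "hsib_run_error")
  summary <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    sp <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary, sp, row.names = FALSE)
    out_files <- c(out_files, sp)
    if (!is.null(inp$labels)) {
      tab <- as.data.frame.matrix(table(summary$label, summary$verdict))
      tab <- cbind(state = rownames(tab), tab)
      bp <- file.path(out_dir, "by_state.csv")
      utils::write.csv(tab, bp, row.names = FALSE)
      out_files <- c(out_files, bp)
    }
    cp <- file.path(out_dir, "config.json")
    jsonlite::write_json(config_to_list(config), cp, auto_unbox = TRUE, digits = NA)
    out_files <- c(out_files, cp)
    utils::write.csv(data.frame(file = basename(out_files)),
                     file.path(out_dir, "run_manifest.csv"), row.names = FALSE)
  }
  list(results = results, summary = summary)
}

#' Classify the age of detected damage
#'
#' Takes the detection output, keeps only fruit whose true state is a day in
#' 0-3 *and* that were detected as damaged (intact fruit never enter the
#' aging model), makes a seeded stratified 2/3-1/3 calibration/test split of
#' their mean damage spectra, selects the latent-variable count by
#' stratified 10-fold cross-validation on the calibration set, fits the
#' final PLS-DA model, and reports calibration, cross-validation and test
#' confusion matrices. Ground-truth day labels come from the manifest (as
#' in a designed experiment), never from the detector.
#'
#' @param detect_out result of [run_detect()].
#' @param labels true state per detection result (defaults to the summary's
#'   `label` column).
#' @param config a `pipeline_config`.
#' @param seed split + CV seed.
#' @param out_dir optional directory for confusion/prediction CSVs.
#' @return list with `model`, `n_lv`, `cv_error`, `reports` (confusion
#'   reports for calibration/cv/test), `split` (per-sample assignment) and
#'   `predictions` (data frame).
#' @export
run_age <- function(detect_out, labels = NULL, config = pipeline_config(),
                    seed = config$seed, out_dir = NULL) {
  res <- detect_out$results
  ok <- !vapply(res, is.null, logical(1))
  labels <- labels %||% detect_out$summary$label[match(
    vapply(res[ok], `[[`, "", "id"), detect_out$summary$id)]
  if (length(labels) != sum(ok)) abort_contract("labels length does not match results")
  res <- res[ok]
  damaged <- vapply(res, function(r) r$verdict == "damaged", logical(1))
  is_day <- labels %in% c("0", "1", "2", "3")
  use <- which(damaged & is_day)
  if (length(use) == 0L) abort_insufficient("no detected-damaged fruit with day labels")
  y <- as.integer(labels[use])
  X <- do.call(rbind, lapply(res[use], `[[`, "mean_damage_spectrum"))
  ids <- vapply(res[use], `[[`, "", "id")
  counts <- table(factor(y, levels = 0:3))
  if (any(counts < 3L))
    abort_insufficient(sprintf("too few detected-damaged samples for day(s): %s",
                               paste(names(counts)[counts < 3L], collapse = ", ")))
  # stratified 2/3 calibration - 1/3 test split
  test_idx <- integer(0)
  with_seed(seed, for (cls in 0:3) {
    idx <- which(y == cls)
    test_idx <- c(test_idx, sample(idx, round(length(idx) / 3)))
  })
  tr <- setdiff(seq_along(y), test_idx)
  recipe <- default_age_recipe(config$age_sg_deriv)
  max_lv <- min(config$max_lv, length(tr) - 2L, ncol(X))
  cv <- select_lv_by_cv(X[tr, , drop = FALSE], y[tr], max_lv = max_lv,
                        folds = config$cv_folds, seed = seed, recipe = recipe)
  model <- plsda_fit(X[tr, , drop = FALSE], y[tr], n_lv = cv$n_lv, recipe = recipe)
  pred_cal <- plsda_predict(model, X[tr, , drop = FALSE])
  pred_cv <- cv$cv_pred[, cv$n_lv]
  pred_test <- plsda_predict(model, X[test_idx, , drop = FALSE])
  reports <- list(calibration = confusion(y[tr], pred_cal),
                  cv = confusion(y[tr], pred_cv),
                  test = confusion(y[test_idx], pred_test))
  split <- rep("calibration", length(y)); split[test_idx] <- "test"
  predictions <- data.frame(id = ids, day = y, split = split,
                            predicted = NA_integer_)
  predictions$predicted[tr] <- pred_cal
  predictions$predicted[test_idx] <- pred_test
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    conf_df <- do.call(rbind, Map(confusion_as_df, reports, names(reports)))
    utils::write.csv(conf_df, file.path(out_dir, "confusion.csv"), row.names = FALSE)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"), row.names = FALSE)
    acc <- data.frame(split = names(reports),
                      total_pct = vapply(reports, `[[`, 0, "total_pct"),
                      n_lv = cv$n_lv)
    utils::write.csv(acc, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
    writeLines(c(sprintf("PLS-DA damage aging: %d latent variables", cv$n_lv),
                 vapply(names(reports), function(nm)
                   sprintf("%-12s total %% correct: %.1f", nm, reports[[nm]]$total_pct),
                   character(1))),
               file.path(out_dir, "report.txt"))
  }
  list(model = model, n_lv = cv$n_lv, cv_error = cv$cv_error,
       reports = reports, split = split, predictions = predictions)
}

# ------------------------------------------------------------------- CLI

cli_usage <- function() {
  paste(
    "usage: hsibruise <command> [--key value ...]",
    "",
    "commands:",
    "  simulate  --n-per-class N --seed S --out DIR [--format portable|envi]",
    "            [--contrast C] [--size PX]",
    "  train-pca --manifest M --out MODEL.rds [--per-day K] [--seed S] [--config C]",
    "  detect    --manifest M --model MODEL.rds --out DIR [--config C]",
    "  age       --results DIR --manifest M --out DIR [--seed S] [--config C]",
    sep = "\n")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      abort_parameter(sprintf("unexpected argument '%s'", args[i]))
    key <- gsub("-", "_", substring(args[i], 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      abort_parameter(sprintf("missing value for --%s", substring(args[i], 3L)))
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

cli_config <- function(opt) {
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  cfg
}

#' Command-line entry point
#'
#' Implements the `simulate`, `train-pca`, `detect` and `age` subcommands
#' used by the `inst/cli/hsibruise` script. Exposed as a function so the
#' interface is testable in-process.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  need <- function(nm) {
    if (is.null(opt[[nm]])) abort_parameter(sprintf("%s: --%s is required", cmd, gsub("_", "-", nm)))
    opt[[nm]]
  }
  switch(cmd,
    simulate = {
      n <- as.integer(need("n_per_class"))
      seed <- as.integer(opt$seed %||% 1L)
      size <- as.integer(opt$size %||% 128L)
      tmpl <- make_templates(contrast = as.numeric(opt$contrast %||% 1))
      generate_dataset(n, out_dir = need("out"), seed = seed, templates = tmpl,
                       format = opt$format %||% "portable", size = c(size, size))
      message(sprintf("simulate: wrote %d cubes to %s", 5L * n, opt$out))
    },
    `train-pca` = {
      man <- utils::read.csv(need("manifest"), stringsAsFactors = FALSE)
      cfg <- cli_config(opt)
      if (!is.null(opt$per_day)) cfg$pca$per_day <- as.integer(opt$per_day)
      model <- train_damage_pca(man, config = cfg, seed = cfg$seed)
      saveRDS(model, need("out"))
      message(sprintf("train-pca: model written to %s", opt$out))
    },
    detect = {
      man <- utils::read.csv(need("manifest"), stringsAsFactors = FALSE)
      model <- readRDS(need("model"))
      cfg <- cli_config(opt)
      out <- run_detect(man, model, config = cfg, out_dir = need("out"))
      message(sprintf("detect: %d/%d images damaged; summary in %s",
                      sum(out$summary$verdict == "damaged"), nrow(out$summary), opt$out))
    },
    age = {
      res_dir <- need("results")
      man <- utils::read.csv(need("manifest"), stringsAsFactors = FALSE)
      cfg <- cli_config(opt)
      detect_out <- read_detect_results(res_dir)
      labels <- man$state[match(detect_out$summary$id, basename(man$path))]
      out <- run_age(detect_out, labels = labels, config = cfg,
                     seed = cfg$seed, out_dir = need("out"))
      message(sprintf("age: %d LVs; test accuracy %.1f%%; reports in %s",
                      out$n_lv, out$reports$test$total_pct, opt$out))
    },
    abort_parameter(sprintf("unknown command '%s'\n%s", cmd, cli_usage())))
  invisible(0L)
}

#' Re-load a detection run written by [run_detect()]
#'
#' @param dir directory containing `summary.csv` and the per-image
#'   `*_damage.json` files.
#' @return list shaped like the in-memory result of [run_detect()].
#' @export
read_detect_results <- function(dir) {
  sp <- file.path(dir, "summary.csv")
  if (!file.exists(sp)) abort(sprintf("no summary.csv in %s", dir), "hsib_io_error")
  summary <- utils::read.csv(sp, stringsAsFactors = FALSE)
  results <- lapply(seq_len(nrow(summary)), function(i) {
    stem <- tools::file_path_sans_ext(summary$id[i])
    j <- jsonlite::read_json(file.path(dir, paste0(stem, "_damage.json")),
                             simplifyVector = TRUE)
    list(id = summary$id[i], verdict = j$verdict,
         damage_area = j$damage_area, n_regions = j$n_regions,
         mean_damage_spectrum = as.numeric(j$mean_damage_spectrum))
  })
  list(results = results, summary = summary)
}
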