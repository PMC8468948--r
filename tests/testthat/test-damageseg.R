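# Bruise detection: circularity, damage PCA fitting, damage segmentation.

raster_disk <- function(n, r, c0 = n / 2) {
  ij <- as.matrix(expand.grid(1:n, 1:n))
  m <- matrix(FALSE, n, n)
  m[ij[(ij[, 1] - c0)^2 + (ij[, 2] - c0)^2 <= r^2, ]] <- TRUE
  m
}

test_that("circularity: disks high, lines low, single pixel capped at 1", {
  expect_gte(circularity(raster_disk(40, 15, 20)), 0.85)
  line <- matrix(FALSE, 10, 40); line[5, 6:35] <- TRUE
  expect_lt(circularity(line), 0.25)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(circularity(single), 1)
  expect_error(circularity(matrix(FALSE, 3, 3)), class = "hsib_contract_error")
})

test_that("region statistics agree exactly with a brute-force boundary-walk oracle", {
  set.seed(51)
  shapes <- list(raster_disk(30, 9, 15), raster_disk(30, 4.5, 15))
  # random 4-connected blobs grown from a seed pixel
  grow_blob <- function(n_steps) {
    m <- matrix(FALSE, 25, 25); m[13, 13] <- TRUE
    for (step in seq_len(n_steps)) {
      nb <- rbind(m[-1, ], FALSE) | rbind(FALSE, m[-25, ]) |
        cbind(m[, -1], FALSE) | cbind(FALSE, m[, -25])
      edge <- which(nb & !m)
      m[edge[sample.int(length(edge), 1)]] <- TRUE
    }
    m
  }
  for (rep in 1:6) shapes <- c(shapes, list(grow_blob(120)))
  for (m in shapes) {
    expect_equal(hsibruise:::trace_perimeter(m), oracle_perimeter(m), tolerance = 1e-12)
    expect_equal(circularity(m), oracle_circularity(m), tolerance = 1e-12)
  }
})

test_that("damage PCA fitting is deterministic and invariant to dataset duplication", {
  tr <- fx_training()
  cfg <- synth_config()$pca
  m1 <- fit_damage_pca(tr$cubes, tr$masks, tr$days, cfg, seed = 9)
  m2 <- fit_damage_pca(tr$cubes, tr$masks, tr$days, cfg, seed = 9)
  expect_identical(m1, m2)
  cfg_all <- damage_pca_config(selected_pc = 2, per_day = NULL)
  ma <- fit_damage_pca(tr$cubes, tr$masks, tr$days, cfg_all, seed = 1)
  md <- fit_damage_pca(c(tr$cubes, tr$cubes), c(tr$masks, tr$masks),
                       c(tr$days, tr$days), cfg_all, seed = 1)
  expect_equal(md$loadings, ma$loadings, tolerance = 1e-10)
  expect_true(all(diff(ma$evr) <= 1e-12))
  # a model needing more components than bands is rejected
  expect_error(fit_damage_pca(tr$cubes[1:2], tr$masks[1:2], c(0, 0),
                              damage_pca_config(n_components = 70, selected_pc = 2,
                                                per_day = NULL), 1),
               class = "hsib_parameter_error")
  # too few training pixels for the component count
  tiny <- tr$masks[[1]] & matrix(seq_len(length(tr$masks[[1]])) %% 300 == 0,
                                 nrow(tr$masks[[1]]))
  expect_error(fit_damage_pca(tr$cubes[1], list(tiny), 0,
                              damage_pca_config(selected_pc = 2, per_day = NULL), 1),
               class = "hsib_insufficient_error")
})

test_that("noiseless training spectra are low-rank: eight components explain ~everything", {
  cubes <- list(); masks <- list(); days <- integer(0); k <- 0
  for (d in 0:3) {
    k <- k + 1
    g <- make_scene(300 + d, day = d, noise_sd = 0)
    cubes[[k]] <- g$cube; masks[[k]] <- segment_fruit(g$cube); days[k] <- d
  }
  m <- fit_damage_pca(cubes, masks, days, damage_pca_config(per_day = 1), seed = 1)
  expect_gte(sum(m$evr), 0.999)
})

test_that("damage verdicts follow ground truth and the mask stays inside the fruit", {
  model <- fx_damage_model()
  cfg <- synth_config()
  gi <- make_scene(52, day = "intact")
  fmi <- segment_fruit(gi$cube)
  ri <- segment_damage(gi$cube, fmi, model, cfg$pca, cfg$filter)
  expect_identical(ri$verdict, "intact")
  expect_false(any(ri$damage_mask))
  expect_null(ri$mean_damage_spectrum)
  g3 <- make_scene(53, day = 3)
  fm3 <- segment_fruit(g3$cube)
  r3 <- segment_damage(g3$cube, fm3, model, cfg$pca, cfg$filter)
  expect_identical(r3$verdict, "damaged")
  expect_gte(iou(r3$damage_mask, g3$masks$bruise), 0.5)
  expect_true(all(fm3[r3$damage_mask]))  # damage subset of fruit
  expect_length(r3$mean_damage_spectrum, 60L)
  # verdict "damaged" iff the mask is nonempty, and regions carry stats
  expect_identical(r3$verdict == "damaged", any(r3$damage_mask))
  expect_true(all(c("area", "circularity", "centroid_row", "boundary_fraction")
                  %in% names(r3$regions)))
})

test_that("a spectrally flat fruit yields an intact verdict with a degenerate flag", {
  model <- fx_damage_model()
  cfg <- synth_config()
  flat <- hyper_cube(array(0.5, c(64, 64, 60)), default_wavelengths(), "reflectance")
  fm <- raster_disk(64, 25, 32)
  r <- segment_damage(flat, fm, model, cfg$pca, cfg$filter)
  expect_identical(r$verdict, "intact")
  expect_true(r$degenerate)
  expect_error(segment_damage(flat, matrix(FALSE, 64, 64), model, cfg$pca, cfg$filter),
               class = "hsib_contract_error")
})

test_that("detection rate rises with bruise contrast and with days since damage", {
  model <- fx_damage_model()
  cfg <- synth_config()
  detect_rate <- function(contrast, day, n = 6, base = 600) {
    tmpl <- make_templates(contrast)
    hits <- 0
    for (i in seq_len(n)) {
      g <- make_scene(base + 31 * i, day = day, templates = tmpl)
      fm <- segment_fruit(g$cube)
      r <- segment_damage(g$cube, fm, model, cfg$pca, cfg$filter)
      hits <- hits + (r$verdict == "damaged")
    }
    hits / n
  }
  rates <- vapply(c(0.08, 0.4, 1), detect_rate, numeric(1), day = 1)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], rates[3])
  expect_lte(detect_rate(1, day = 0, base = 700), detect_rate(1, day = 3, base = 700))
})
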