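# Cube data model, ENVI/portable round trips, reflectance calibration.

small_cube <- function(seed = 1, nr = 8, nc = 8, nb = 60, origin = "reflectance") {
  set.seed(seed)
  hyper_cube(array(runif(nr * nc * nb, 0, 1), c(nr, nc, nb)),
             default_wavelengths()[seq_len(nb)] - 450 + 450, origin = origin)
}

test_that("cube constructor enforces its invariants", {
  expect_error(hyper_cube(matrix(1, 3, 3)), class = "hsib_contract_error")
  expect_error(hyper_cube(array(1, c(4, 4, 5)), wavelengths = 1:4),
               class = "hsib_contract_error")
  expect_error(hyper_cube(array(1, c(4, 4, 3)), wavelengths = c(500, 450, 600)),
               class = "hsib_contract_error")
  expect_error(hyper_cube(array(-1, c(4, 4, 3)), wavelengths = 1:3),
               class = "hsib_contract_error")
  expect_error(hyper_cube(array(2, c(4, 4, 3)), wavelengths = 1:3,
                          origin = "reflectance"),
               class = "hsib_contract_error")
  expect_s3_class(hyper_cube(array(0.5, c(1, 1, 60))), "hypercube")
})

test_that("cubes round-trip through both file formats bit-for-bit", {
  dir <- withr::local_tempdir()
  cube <- small_cube()
  for (fmt in c("envi", "portable")) {
    path <- file.path(dir, paste0("c_", fmt, if (fmt == "portable") ".rds" else ""))
    write_cube(cube, path, format = fmt)
    back <- read_cube(path, format = fmt)
    expect_identical(back$data, cube$data, info = fmt)
    expect_identical(back$wavelengths, cube$wavelengths, info = fmt)
    expect_identical(back$origin, cube$origin, info = fmt)
  }
  # and a synthetic generator cube (the pipeline's real currency)
  g <- make_scene(7, day = 1)
  p <- file.path(dir, "synth")
  write_cube(g$cube, p, format = "envi")
  expect_identical(read_cube(p)$data, g$cube$data)
})

test_that("ENVI header declares one wavelength entry per band", {
  dir <- withr::local_tempdir()
  cube <- small_cube(nb = 60)
  write_cube(cube, file.path(dir, "c"), format = "envi")
  hdr <- paste(readLines(file.path(dir, "c.hdr")), collapse = " ")
  wl <- sub(".*wavelength = \\{([^}]*)\\}.*", "\\1", hdr)
  expect_length(strsplit(wl, ",")[[1]], 60L)
  expect_match(hdr, "data origin = reflectance")
})

test_that("bil and bip interleaves are read back correctly", {
  # independently lay out a tiny cube in each interleave with explicit loops
  dir <- withr::local_tempdir()
  set.seed(2)
  a <- array(runif(3 * 4 * 2), c(3, 4, 2))  # rows x cols x bands
  for (il in c("bil", "bip")) {
    v <- numeric(0)
    if (il == "bil") {
      for (r in 1:3) for (b in 1:2) for (cc in 1:4) v <- c(v, a[r, cc, b])
    } else {
      for (r in 1:3) for (cc in 1:4) for (b in 1:2) v <- c(v, a[r, cc, b])
    }
    base <- file.path(dir, il)
    writeLines(c("ENVI", "samples = 4", "lines = 3", "bands = 2",
                 "data type = 5", sprintf("interleave = %s", il),
                 "byte order = 0", "wavelength = { 450, 460 }"),
               paste0(base, ".hdr"))
    con <- file(paste0(base, ".dat"), "wb")
    writeBin(v, con, size = 8, endian = "little")
    close(con)
    expect_equal(read_cube(base)$data, a, info = il)
  }
})

test_that("corrupt or contradictory ENVI files are rejected", {
  dir <- withr::local_tempdir()
  cube <- small_cube(nb = 59)
  base <- file.path(dir, "c")
  write_cube(cube, base, format = "envi")
  # header claims 60 bands / 60 wavelengths but payload has 59
  hdr <- readLines(paste0(base, ".hdr"))
  hdr <- sub("^bands = 59", "bands = 60", hdr)
  hdr <- sub("(wavelength = \\{ .*)\\}", "\\1, 1040 }", hdr)
  writeLines(hdr, paste0(base, ".hdr"))
  expect_error(read_cube(base), class = "hsib_corrupt_error")
  # missing interleave
  writeLines(c("ENVI", "samples = 4", "lines = 3", "bands = 2",
               "data type = 5", "wavelength = { 450, 460 }"),
             paste0(base, ".hdr"))
  expect_error(read_cube(base), class = "hsib_format_error")
  # wavelength count inconsistent with bands
  writeLines(c("ENVI", "samples = 4", "lines = 3", "bands = 2",
               "data type = 5", "interleave = bsq",
               "wavelength = { 450 }"),
             paste0(base, ".hdr"))
  expect_error(read_cube(base), class = "hsib_format_error")
})

test_that("calibration maps dark to 0, white to rho_ref, and is exact on hand arithmetic", {
  wl <- default_wavelengths()
  d <- c(6, 6, 60)
  white <- hyper_cube(array(900, d), wl)
  dark <- hyper_cube(array(100, d), wl)
  refs <- reference_set(white, dark)
  out_w <- calibrate_reflectance(white, refs)
  out_d <- calibrate_reflectance(dark, refs)
  expect_identical(unique(as.vector(out_w$data)), 0.99)
  expect_identical(unique(as.vector(out_d$data)), 0)
  expect_identical(out_w$origin, "reflectance")
  raw <- hyper_cube(array(500, d), wl)
  expect_equal(unique(as.vector(calibrate_reflectance(raw, refs)$data)),
               0.495, tolerance = 1e-12)
})

test_that("scalar-per-band references broadcast like full reference cubes", {
  wl <- default_wavelengths()
  set.seed(4)
  wv <- runif(60, 800, 1000); dv <- runif(60, 50, 150)
  raw <- hyper_cube(array(runif(5 * 5 * 60, 100, 900), c(5, 5, 60)), wl)
  full <- reference_set(hyper_cube(aperm(array(wv, c(60, 5, 5)), c(2, 3, 1)), wl),
                        hyper_cube(aperm(array(dv, c(60, 5, 5)), c(2, 3, 1)), wl))
  flat <- reference_set(wv, dv)
  expect_equal(calibrate_reflectance(raw, full)$data,
               calibrate_reflectance(raw, flat)$data, tolerance = 1e-14)
})

test_that("negative post-calibration values are clipped to zero and counted", {
  wl <- default_wavelengths()
  d <- c(4, 4, 60)
  refs <- reference_set(rep(900, 60), rep(100, 60))
  raw <- hyper_cube(array(50, d), wl)  # below dark everywhere
  expect_message(out <- calibrate_reflectance(raw, refs), "clipped")
  expect_true(all(out$data == 0))
  expect_identical(attr(out$data, "n_clipped"), as.integer(prod(d)))
})

test_that("calibration is monotone and validates its inputs", {
  wl <- default_wavelengths()
  refs <- reference_set(rep(900, 60), rep(100, 60))
  set.seed(5)
  r2 <- array(runif(4 * 4 * 60, 100, 800), c(4, 4, 60))
  r1 <- r2 + 20
  c1 <- calibrate_reflectance(hyper_cube(r1, wl), refs)
  c2 <- calibrate_reflectance(hyper_cube(r2, wl), refs)
  expect_true(all(c1$data >= c2$data))
  # white <= dark somewhere -> calibration-undefined naming the coordinate
  wv <- rep(900, 60); wv[5] <- 50
  expect_error(calibrate_reflectance(hyper_cube(r2, wl), reference_set(wv, rep(100, 60))),
               regexp = "band 5", class = "hsib_calibration_error")
  # axis mismatch
  refs59 <- reference_set(rep(900, 59), rep(100, 59), wavelengths = wl[1:59])
  expect_error(calibrate_reflectance(hyper_cube(r2, wl), refs59),
               class = "hsib_contract_error")
})
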