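# NIPALS PLS-DA: fitting, prediction, CV latent-variable selection,
# confusion reporting.

# toy problem with collinear class means on one noisy axis
toy_data <- function(n_per = 8, noise = 0, seed = 61) {
  set.seed(seed)
  y <- rep(0:3, each = n_per)
  X <- cbind(y + rnorm(length(y), sd = noise),
             matrix(rnorm(length(y) * 4, sd = 0.01), length(y)))
  list(X = X, y = y)
}

# separable toy with orthogonal class centroids (argmax decoding of linear
# scores cannot resolve interior classes of collinear centroids, so the
# separable reference problem uses one axis per class)
sep_data <- function(n_per = 8, noise = 0, seed = 61) {
  set.seed(seed)
  y <- rep(0:3, each = n_per)
  X <- diag(4)[y + 1, ] + matrix(rnorm(length(y) * 4, sd = noise), length(y))
  list(X = X, y = y)
}

plain_recipe <- function() preprocess_recipe(list(step_mean_center()))

test_that("a perfectly separable toy problem is fit exactly", {
  d <- sep_data()
  m <- plsda_fit(d$X, d$y, n_lv = 3, recipe = plain_recipe())
  expect_identical(plsda_predict(m, d$X), d$y)
})

test_that("full-LV PLS2 predictions coincide with ordinary least squares", {
  set.seed(62)
  for (rep in 1:4) {
    n <- 30; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(0:3, n, replace = TRUE)
    while (length(unique(y)) < 4) y <- sample(0:3, n, replace = TRUE)
    m <- plsda_fit(X, y, n_lv = p, recipe = plain_recipe())
    Xc <- scale(X, scale = FALSE)
    Y <- outer(y, 0:3, `==`) * 1
    Yc <- scale(Y, scale = FALSE)
    B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
    scores_pls <- Xc %*% m$coef + rep(m$y_means, each = n)
    scores_ols <- Xc %*% B_ols + rep(colMeans(Y), each = n)
    expect_equal(scores_pls, scores_ols, tolerance = 1e-8, ignore_attr = TRUE)
    expect_identical(plsda_predict(m, X), (0:3)[apply(scores_ols, 1, which.max)])
  }
})

test_that("fitting is invariant to row permutation", {
  d <- toy_data(noise = 0.3, seed = 63)
  m1 <- plsda_fit(d$X, d$y, n_lv = 3, recipe = plain_recipe())
  set.seed(64)
  perm <- sample(length(d$y))
  m2 <- plsda_fit(d$X[perm, ], d$y[perm], n_lv = 3, recipe = plain_recipe())
  expect_equal(m1$coef, m2$coef, tolerance = 1e-10)
})

test_that("prediction reuses training statistics, handles centroids and degenerate input", {
  d <- toy_data(noise = 0.1, seed = 65)
  m <- plsda_fit(d$X, d$y, n_lv = 2, recipe = plain_recipe())
  expect_identical(plsda_predict(m, d$X), plsda_predict(m, d$X))
  # class-0 centroid classifies as 0
  centroid <- colMeans(d$X[d$y == 0, , drop = FALSE])
  expect_identical(plsda_predict(m, centroid), 0L)
  # all-zero spectrum through the default (SG/SNV) recipe: valid label, no error
  g <- fx_training()
  spectra <- do.call(rbind, lapply(seq_along(g$cubes), function(i)
    colMeans(as_spectrum_matrix(g$cubes[[i]], g$masks[[i]]))))
  md <- plsda_fit(spectra, g$days, n_lv = 3)
  p0 <- plsda_predict(md, rep(0, 60))
  expect_true(p0 %in% 0:3)
  expect_error(plsda_predict(md, rep(0, 59)), class = "hsib_contract_error")
  expect_error(plsda_fit(d$X, d$y, n_lv = 40, recipe = plain_recipe()),
               class = "hsib_parameter_error")
  expect_error(plsda_fit(d$X, rep(0:2, length.out = length(d$y)), n_lv = 2,
                         recipe = plain_recipe()),
               class = "hsib_contract_error")
})

test_that("SNV in the recipe makes predictions invariant to positive affine scaling", {
  g <- fx_training()
  spectra <- do.call(rbind, lapply(seq_along(g$cubes), function(i)
    colMeans(as_spectrum_matrix(g$cubes[[i]], g$masks[[i]]))))
  m <- plsda_fit(spectra, g$days, n_lv = 3)
  expect_identical(plsda_predict(m, 1.7 * spectra + 0.05), plsda_predict(m, spectra))
})

test_that("CV selection matches a brute-force re-computation and is seed-stable", {
  d <- toy_data(n_per = 12, noise = 0.6, seed = 66)
  sel <- select_lv_by_cv(d$X, d$y, max_lv = 4, folds = 4, seed = 5,
                         recipe = plain_recipe())
  sel2 <- select_lv_by_cv(d$X, d$y, max_lv = 4, folds = 4, seed = 5,
                          recipe = plain_recipe())
  expect_identical(sel, sel2)
  # brute force: refit each fold at each LV count independently
  cv_err <- numeric(4)
  for (a in 1:4) {
    wrong <- 0
    for (f in 1:4) {
      tr <- sel$folds != f
      mf <- plsda_fit(d$X[tr, ], d$y[tr], n_lv = a, recipe = plain_recipe())
      wrong <- wrong + sum(plsda_predict(mf, d$X[!tr, , drop = FALSE]) != d$y[!tr])
    }
    cv_err[a] <- wrong / length(d$y)
  }
  expect_equal(sel$cv_error, cv_err)
  expect_identical(sel$n_lv, which.min(cv_err))
  expect_true(all(sel$cv_error[sel$n_lv] <= sel$cv_error))
  # separable data -> zero CV error at the selected LV
  ds <- sep_data(n_per = 12, noise = 0.02, seed = 67)
  sels <- select_lv_by_cv(ds$X, ds$y, max_lv = 3, folds = 4, seed = 5,
                          recipe = plain_recipe())
  expect_identical(sels$cv_error[sels$n_lv], 0)
  # too-small classes reduce the fold count with a warning
  dsm <- toy_data(n_per = 4, noise = 0.3, seed = 68)
  expect_warning(select_lv_by_cv(dsm$X, dsm$y, max_lv = 2, folds = 10,
                                 seed = 1, recipe = plain_recipe()),
                 "reducing folds")
})

test_that("confusion reports count and percentage correctly", {
  r <- confusion(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_identical(r$counts, diag(1L, 4L) |>
                     `dimnames<-`(list(true = 0:3, predicted = 0:3)))
  expect_identical(r$total_pct, 100)
  r2 <- confusion(c(0, 0, 1), c(0, 1, 1))
  expect_equal(r2$per_class_pct[["0"]], 50)
  expect_equal(r2$per_class_pct[["1"]], 100)
  expect_equal(r2$total_pct, 200 / 3)
  # percentages recomputed independently from the count matrix agree exactly
  set.seed(68)
  tr <- sample(0:3, 60, replace = TRUE); pr <- sample(0:3, 60, replace = TRUE)
  r3 <- confusion(tr, pr)
  expect_equal(unname(r3$per_class_pct),
               vapply(0:3, function(k) 100 * mean(pr[tr == k] == k), numeric(1)))
  expect_equal(r3$total_pct, 100 * mean(tr == pr))
  expect_true(all(rowSums(r3$counts) == table(factor(tr, levels = 0:3))))
  expect_error(confusion(c(0, 5), c(0, 1)), class = "hsib_contract_error")
})
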