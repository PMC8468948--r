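# PLS-DA damage-age classifier: partial least squares regression (PLS2,
# NIPALS) of dummy-coded day indicators on preprocessed mean damage spectra,
# argmax decoding, and cross-validated latent-variable selection. The whole
# fit is deterministic: NIPALS is initialised from the maximum-variance
# indicator column and the preprocessing recipe carries its training means.

default_age_recipe <- function(sg_deriv = 1L)
  preprocess_recipe(list(step_sg(3L, 2L, sg_deriv), step_snv(), step_mean_center()))

# NIPALS PLS2 on column-centred X and Y. Returns weights W, X-loadings P,
# Y-loadings Q (p x a, p x a, m x a) with nested components, so regression
# coefficients for any 1..a components can be formed afterwards.
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-12, maxit = 500L) {
  p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, m, ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2L, stats::var))]
    if (sum(u^2) < 1e-30) break
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-30) break
      w <- w / nw
      tt <- X %*% w
      st <- sum(tt^2)
      if (st < 1e-30) break
      q <- crossprod(Y, tt) / st
      u_new <- Y %*% q / sum(q^2)
      delta <- sum((u_new - u)^2) / max(sum(u_new^2), 1e-30)
      u <- u_new
      if (delta < tol) break
    }
    tt <- X %*% w
    st <- sum(tt^2)
    if (st < 1e-30) break
    pp <- crossprod(X, tt) / st
    qq <- crossprod(Y, tt) / st
    X <- X - tt %*% t(pp)
    Y <- Y - tt %*% t(qq)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq
    a_done <- a
  }
  list(W = W[, seq_len(a_done), drop = FALSE],
       P = P[, seq_len(a_done), drop = FALSE],
       Q = Q[, seq_len(a_done), drop = FALSE],
       ncomp = a_done)
}

pls_coefficients <- function(fit, n_lv) {
  n_lv <- min(n_lv, fit$ncomp)
  W <- fit$W[, seq_len(n_lv), drop = FALSE]
  P <- fit$P[, seq_len(n_lv), drop = FALSE]
  Q <- fit$Q[, seq_len(n_lv), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a PLS-DA model of damage age
#'
#' Dummy-codes the day labels as four indicator columns, preprocesses the
#' spectra with the supplied recipe (default: 3-point 2nd-order
#' Savitzky-Golay derivative, SNV, mean centring with learned means), and
#' fits a PLS2 regression by NIPALS with `n_lv` latent variables. Class
#' decoding is the argmax of the predicted indicators, ties going to the
#' lowest day.
#'
#' @param X spectrum matrix, one row per fruit (mean damage spectrum).
#' @param y day labels in `levels`; every level must be present.
#' @param n_lv number of latent variables,
#'   `1 <= n_lv <= min(rows - 1, bands)`.
#' @param recipe unfitted `preprocess_recipe`; refit on `X`.
#' @param levels ordered class labels (default `0:3`, days after damage).
#' @return an object of class `plsda_model`.
#' @export
plsda_fit <- function(X, y, n_lv, recipe = default_age_recipe(), levels = 0:3) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) abort_contract("X and y must have equal lengths")
  if (!all(y %in% levels)) abort_contract("labels outside the class set")
  if (!all(levels %in% y)) abort_contract("every class must be present in the training set")
  if (n_lv < 1L || n_lv > min(nrow(X) - 1L, ncol(X)))
    abort_parameter("n_lv must satisfy 1 <= n_lv <= min(rows - 1, bands)")
  fitted_recipe <- recipe_fit(recipe, X)
  Xp <- recipe_apply(fitted_recipe, X)
  Y <- outer(y, levels, `==`) * 1
  ym <- colMeans(Y)
  fit <- nipals_pls2(Xp, sweep(Y, 2L, ym), ncomp = n_lv)
  structure(list(recipe = fitted_recipe, n_lv = as.integer(n_lv),
                 fit = fit, coef = pls_coefficients(fit, n_lv),
                 y_means = ym, levels = levels),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variables, %d bands, classes {%s}\n",
              x$n_lv, nrow(x$coef), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict damage age for new spectra
#'
#' @param model a `plsda_model`.
#' @param X spectrum matrix with the model's band count.
#' @param n_lv optionally predict with fewer latent variables than the
#'   model was fitted with (used by cross-validation).
#' @return integer vector of predicted day labels.
#' @export
plsda_predict <- function(model, X, n_lv = NULL) {
  X <- as_matrix_rows(X)
  if (ncol(X) != nrow(model$coef)) abort_contract("band count does not match the model")
  B <- if (is.null(n_lv) || n_lv == model$n_lv) model$coef
       else pls_coefficients(model$fit, n_lv)
  scores <- recipe_apply(model$recipe, X) %*% B +
    rep(model$y_means, each = nrow(X))
  model$levels[apply(scores, 1L, which.max)]  # which.max: ties -> lowest day
}

stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Select the number of latent variables by cross-validation
#'
#' Stratified, seeded k-fold cross-validation on the training set: for every
#' candidate count `1..max_lv` the pooled misclassification rate is
#' computed, and the count with the minimum rate is returned (ties go to the
#' fewest latent variables). If the smallest class has fewer members than
#' `folds`, the fold count is reduced with a warning.
#'
#' @param X,y training spectra and day labels.
#' @param max_lv largest candidate latent-variable count.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param recipe unfitted preprocessing recipe (refit inside each fold).
#' @param levels class labels.
#' @return list with `n_lv` (selected count), `cv_error` (error-rate curve
#'   over candidates), `folds` (fold assignment) and `cv_pred`
#'   (rows x candidates matrix of held-out predictions).
#' @export
select_lv_by_cv <- function(X, y, max_lv, folds = 10L, seed = 1L,
                            recipe = default_age_recipe(), levels = 0:3) {
  X <- as.matrix(X); y <- as.integer(y)
  if (folds < 2L) abort_parameter("folds must be >= 2")
  if (max_lv < 1L || max_lv > min(nrow(X) - 2L, ncol(X)))
    abort_parameter("max_lv out of bounds for this training set")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)", folds, min_class))
    folds <- min_class
  }
  assign <- stratified_folds(y, folds, seed)
  cv_pred <- matrix(NA_integer_, nrow(X), max_lv)
  for (f in seq_len(folds)) {
    tr <- assign != f
    model <- plsda_fit(X[tr, , drop = FALSE], y[tr], n_lv = max_lv,
                       recipe = recipe, levels = levels)
    for (a in seq_len(max_lv))
      cv_pred[!tr, a] <- plsda_predict(model, X[!tr, , drop = FALSE], n_lv = a)
  }
  cv_error <- colMeans(cv_pred != y)
  n_lv <- which.min(cv_error)  # first minimum = fewest LVs on ties
  list(n_lv = n_lv, cv_error = cv_error, folds = assign, cv_pred = cv_pred)
}

#' Confusion matrix report
#'
#' Counts and percent-correct summaries for a set of predictions, laid out
#' with true classes as rows.
#'
#' @param true,predicted equal-length label vectors.
#' @param levels class labels (default days `0:3`).
#' @return an object of class `confusion_report`: `counts` (4x4 matrix),
#'   `per_class_pct` (diagonal percentage per true class) and `total_pct`.
#' @export
confusion <- function(true, predicted, levels = 0:3) {
  if (length(true) != length(predicted)) abort_contract("length mismatch")
  if (!all(true %in% levels) || !all(predicted %in% levels))
    abort_contract("labels outside the class set")
  counts <- table(factor(true, levels = levels),
                  factor(predicted, levels = levels))
  counts <- matrix(as.integer(counts), length(levels), length(levels),
                   dimnames = list(true = levels, predicted = levels))
  rs <- rowSums(counts)
  per_class <- ifelse(rs > 0, 100 * diag(counts) / rs, NA_real_)
  structure(list(counts = counts, per_class_pct = per_class,
                 total_pct = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> (rows = true day, cols = predicted day)\n")
  print(x$counts)
  cat(sprintf("per-class %% correct: %s\n",
              paste(sprintf("%.1f", x$per_class_pct), collapse = " ")))
  cat(sprintf("total %% correct: %.1f\n", x$total_pct))
  invisible(x)
}

confusion_as_df <- function(x, split) {
  df <- as.data.frame(x$counts)
  names(df) <- c("true", "predicted", "count")
  df$split <- split
  df
}
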