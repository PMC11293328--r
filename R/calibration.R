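#' Ridge regression with unpenalized intercept
#'
#' Solves the penalized least-squares normal equations
#' `(Z'Z + lambda I) beta = Z'y` on column-standardized features `Z` (train
#' statistics), with the intercept left unpenalized, so `lambda = 0` on
#' full-rank data reduces to ordinary least squares and `lambda -> Inf`
#' shrinks all slopes to zero leaving the intercept at `mean(y)`. The penalty
#' acts on the summed (not mean) squared error: duplicating every row while
#' doubling `lambda` leaves the fitted prediction function unchanged.
#'
#' @param features Features tibble or numeric matrix.
#' @param y Numeric response.
#' @param lambda Ridge penalty (>= 0); default 1 on standardized features.
#' @return An `ir_ridge` list: `coefficients` (on the original feature
#'   scale), `intercept`, `lambda`, standardization statistics.
#' @export
fit_ridge <- function(features, y, lambda = 1) {
  X <- feature_matrix(features)
  if (length(y) != nrow(X)) abort("response length must match rows")
  if (anyNA(y) || !all(is.finite(y))) abort("response must be finite")
  if (nrow(X) < 2) abort("need at least two samples")
  check_scalar_number(lambda, "lambda", min = 0)
  mu <- colMeans(X)
  sg <- col_sd_pop(X)
  sg[sg == 0 | is.na(sg)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  yc <- y - mean(y)
  p <- ncol(Z)
  G <- crossprod(Z) + diag(lambda, p)
  b <- solve(G, crossprod(Z, yc))
  beta <- as.numeric(b) / sg
  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      intercept = mean(y) - sum(beta * mu),
      lambda = lambda, feature_names = colnames(X)
    ),
    class = "ir_ridge"
  )
}

#' @export
predict.ir_ridge <- function(object, features, ...) {
  X <- feature_matrix(features)
  as.numeric(X[, object$feature_names, drop = FALSE] %*%
    object$coefficients) + object$intercept
}

# k-fold ridge cross-validation shared by all calibration entry points.
# R2 is out-of-sample: 1 - SSE/SST with SST about the test-fold mean.
ridge_cv <- function(X, y, ids, k, lambda, seed, target) {
  n <- length(y)
  if (k > n) abort("more folds than samples")
  if (sd(y) == 0) abort("constant target: R^2 undefined")
  fold <- with_seed(derive_seed(seed, paste0("calib_", target)), {
    sample(rep_len(seq_len(k), n))
  })
  rows <- list()
  preds <- list()
  for (i in seq_len(k)) {
    tr <- fold != i
    fit <- fit_ridge(X[tr, , drop = FALSE], y[tr], lambda = lambda)
    ph <- predict(fit, X[!tr, , drop = FALSE])
    yt <- y[!tr]
    sse <- sum((yt - ph)^2)
    sst <- sum((yt - mean(yt))^2)
    rows[[i]] <- tibble(
      fold = i, r_squared = 1 - sse / sst,
      rmse = sqrt(mean((yt - ph)^2)), n_test = length(yt)
    )
    preds[[i]] <- tibble(
      sample_id = ids[!tr], fold = i, truth = yt, predicted = ph
    )
  }
  per_fold <- bind_rows(rows)
  structure(
    list(
      target = target, per_fold = per_fold,
      r_squared_mean = mean(per_fold$r_squared),
      r_squared_sd = sd(per_fold$r_squared),
      rmse_mean = mean(per_fold$rmse), rmse_sd = sd(per_fold$rmse),
      predictions = bind_rows(preds), lambda = lambda, k = k, seed = seed
    ),
    class = "ir_calibration"
  )
}

#' @export
print.ir_calibration <- function(x, ...) {
  cat(sprintf(
    "<ir_calibration> %s: R^2 = %.3f +/- %.3f, RMSE = %.4g +/- %.2g (%d-fold CV)\n",
    x$target, x$r_squared_mean, x$r_squared_sd, x$rmse_mean, x$rmse_sd, x$k
  ))
  invisible(x)
}

#' Quantify a clinical analyte from fingerprints
#'
#' Ridge-regression calibration of one analyte concentration against the
#' preprocessed spectra (both sample sets pooled), evaluated by test-fold
#' R-squared and RMSE in a k-fold cross-validation; test-set predictions are
#' retained for plotting. Samples with a missing concentration are excluded.
#'
#' @param spectra Preprocessed spectra tibble.
#' @param clinical Clinical table with `sample_id` and the analyte column
#'   (alternatively a tibble `sample_id` + `value`).
#' @param analyte Column name of the target analyte.
#' @param k Folds. @param lambda Ridge penalty. @param seed Fold-split seed.
#' @return An `ir_calibration` object.
#' @export
quantify_analyte <- function(spectra, clinical, analyte, k = 10, lambda = 1,
                             seed = 1L) {
  check_spectra(spectra)
  cl <- as_tibble(clinical)
  if (!analyte %in% names(cl)) abort(sprintf("no column `%s`", analyte))
  df <- inner_join(spectra["sample_id"],
    cl[, c("sample_id", analyte)],
    by = "sample_id"
  )
  keep <- !is.na(df[[analyte]])
  if (sum(keep) < k) abort("fewer non-missing concentrations than folds")
  ids <- df$sample_id[keep]
  X <- spectra_matrix(spectra)[ids, , drop = FALSE]
  ridge_cv(X, df[[analyte]][keep], ids, k, lambda, seed, target = analyte)
}

#' Quantify a ratio of two analytes from fingerprints
#'
#' Calibrates the elementwise ratio of two analyte concentrations (e.g.
#' triglycerides / HDL cholesterol, a cardiovascular risk marker) with the
#' same pipeline as [quantify_analyte()].
#'
#' @inheritParams quantify_analyte
#' @param numerator,denominator Analyte column names.
#' @export
quantify_ratio <- function(spectra, clinical, numerator, denominator,
                           k = 10, lambda = 1, seed = 1L) {
  cl <- as_tibble(clinical)
  for (a in c(numerator, denominator)) {
    if (!a %in% names(cl)) abort(sprintf("no column `%s`", a))
  }
  den <- cl[[denominator]]
  if (any(!is.na(den) & den <= 0)) abort("denominator must be positive")
  tgt <- paste0(numerator, "/", denominator)
  cl[[tgt]] <- cl[[numerator]] / den
  out <- quantify_analyte(spectra, cl, tgt, k = k, lambda = lambda, seed = seed)
  out
}

#' Per-wavenumber Pearson correlation map
#'
#' Pearson correlation between an analyte concentration and the absorbance at
#' each retained wavenumber -- the univariate view of where an analyte lives
#' in the fingerprint. Zero-variance spectral columns are flagged undefined
#' (`NA`) rather than forced to zero.
#'
#' @inheritParams quantify_analyte
#' @return A `correlation_map` tibble: `wavenumber`, `r`, `undefined`.
#' @export
wavenumber_correlation <- function(spectra, clinical, analyte) {
  check_spectra(spectra)
  cl <- as_tibble(clinical)
  if (!analyte %in% names(cl)) abort(sprintf("no column `%s`", analyte))
  df <- inner_join(spectra["sample_id"], cl[, c("sample_id", analyte)],
    by = "sample_id"
  )
  keep <- !is.na(df[[analyte]])
  if (sum(keep) < 3) abort("need at least three samples")
  y <- df[[analyte]][keep]
  if (sd(y) == 0) abort("constant concentration: correlation undefined")
  A <- spectra_matrix(spectra)[df$sample_id[keep], , drop = FALSE]
  sds <- apply(A, 2, sd)
  r <- rep(NA_real_, ncol(A))
  ok <- sds > 0
  r[ok] <- as.numeric(cor(A[, ok, drop = FALSE], y))
  out <- tibble(
    wavenumber = spectra_grid(spectra), r = r, undefined = !ok
  )
  structure(out,
    class = c("correlation_map", class(out)),
    analyte = analyte, n = sum(keep)
  )
}

#' Anthropometric models from fingerprints
#'
#' How strongly do sex, age and BMI imprint on the plasma fingerprint? Sex is
#' classified with an L2-logistic model (cross-validated ROC/AUC); age and
#' BMI are calibrated by ridge regression exactly as analytes are. Setting
#' `subset = "healthy_only"` restricts to samples negative for all four
#' conditions, isolating anthropometric signal from disease signal.
#'
#' @param spectra Preprocessed spectra tibble.
#' @param clinical Clinical table (`sample_id`, `sex`, `age`, `bmi`,
#'   `individual_id`).
#' @param labels Labels tibble; required for `subset = "healthy_only"`.
#' @param subset `"all"` or `"healthy_only"`.
#' @param k Folds. @param c_reg,lambda Regularization. @param seed Seed.
#' @return List with `sex` (an `ir_binary_experiment`), `age` and `bmi`
#'   (`ir_calibration` objects), and `n`.
#' @export
anthropometric_models <- function(spectra, clinical, labels = NULL,
                                  subset = c("all", "healthy_only"),
                                  k = 10, c_reg = 1, lambda = 1, seed = 1L) {
  subset <- match.arg(subset)
  cl <- as_tibble(clinical)
  if (subset == "healthy_only") {
    if (is.null(labels)) abort("`labels` needed for the healthy-only subset")
    lab <- as_tibble(labels)
    healthy_ids <- lab$sample_id[!is.na(lab$healthy) & lab$healthy]
    cl <- cl[cl$sample_id %in% healthy_ids, ]
  }
  cl <- cl[cl$sample_id %in% spectra$sample_id, ]
  if (nrow(cl) == 0) abort("empty subset")
  if (length(unique(cl$sex)) < 2) abort("subset contains a single sex")
  sp <- subset_rows(spectra, cl$sample_id)
  plan <- make_cv_folds(cl, k = k, seed = seed, regime = paste0("cv_", subset))
  sex_exp <- run_binary_experiment(
    sp, tibble(sample_id = cl$sample_id, outcome = cl$sex == "male"),
    plan,
    c_reg = c_reg
  )
  age_cal <- quantify_analyte(sp, cl, "age", k = k, lambda = lambda, seed = seed)
  bmi_cal <- quantify_analyte(sp, cl, "bmi", k = k, lambda = lambda, seed = seed)
  list(sex = sex_exp, age = age_cal, bmi = bmi_cal, n = nrow(cl), subset = subset)
}
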