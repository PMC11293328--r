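#' Tidy and glance methods
#'
#' Broom-style summaries of the package's fitted objects:
#' * `tidy.ir_chain()` / `tidy.ir_independent()` -- one row per (label,
#'   feature) coefficient, chain-link label features included;
#' * `tidy.ir_ml_experiment()` -- per-fold multilabel metrics in long form;
#'   `glance()` gives the across-fold mean ± SD in one row;
#' * `tidy.ir_binary_experiment()` -- per-fold AUCs; `glance()` the summary;
#' * `tidy.ir_calibration()` -- per-fold R² and RMSE; `glance()` the summary;
#' * `tidy.chance_benchmark()` -- sampled value, analytic expectation and
#'   Monte-Carlo SE per metric.
#'
#' @param x A fitted irpheno object.
#' @param ... Unused.
#' @return A tibble.
#' @name irpheno-tidiers
NULL

#' @rdname irpheno-tidiers
#' @method tidy ir_chain
#' @export
tidy.ir_chain <- function(x, ...) {
  bind_rows(imap(x$models, function(m, lab) {
    tibble(
      label = lab,
      term = c("(Intercept)", names(m$coefficients)),
      estimate = c(m$intercept, unname(m$coefficients))
    )
  }))
}

#' @rdname irpheno-tidiers
#' @method tidy ir_independent
#' @export
tidy.ir_independent <- tidy.ir_chain

#' @rdname irpheno-tidiers
#' @method tidy ir_logit
#' @export
tidy.ir_logit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname irpheno-tidiers
#' @method tidy ir_ridge
#' @export
tidy.ir_ridge <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname irpheno-tidiers
#' @method tidy ir_ml_experiment
#' @export
tidy.ir_ml_experiment <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold,
    cols = c(
      "exact_match_ratio", "hamming_score",
      "one_minus_hamming_loss"
    ),
    names_to = "metric", values_to = "value"
  )
}

#' @rdname irpheno-tidiers
#' @method glance ir_ml_experiment
#' @export
glance.ir_ml_experiment <- function(x, ...) {
  out <- tidyr::pivot_wider(x$summary,
    names_from = "metric",
    values_from = c("mean", "sd")
  )
  mutate(out, regime = x$regime, model = x$model)
}

#' @rdname irpheno-tidiers
#' @method tidy ir_binary_experiment
#' @export
tidy.ir_binary_experiment <- function(x, ...) {
  x$per_fold
}

#' @rdname irpheno-tidiers
#' @method glance ir_binary_experiment
#' @export
glance.ir_binary_experiment <- function(x, ...) {
  tibble(
    auc_mean = x$auc_mean, auc_sd = x$auc_sd,
    n_folds = nrow(x$per_fold), regime = x$regime
  )
}

#' @rdname irpheno-tidiers
#' @method tidy ir_calibration
#' @export
tidy.ir_calibration <- function(x, ...) {
  x$per_fold
}

#' @rdname irpheno-tidiers
#' @method glance ir_calibration
#' @export
glance.ir_calibration <- function(x, ...) {
  tibble(
    target = x$target,
    r_squared_mean = x$r_squared_mean, r_squared_sd = x$r_squared_sd,
    rmse_mean = x$rmse_mean, rmse_sd = x$rmse_sd,
    n_folds = x$k, lambda = x$lambda
  )
}

#' @rdname irpheno-tidiers
#' @method tidy chance_benchmark
#' @export
tidy.chance_benchmark <- function(x, ...) {
  metrics <- names(x$sampled)
  tibble(
    metric = metrics,
    sampled = as.numeric(x$sampled[1, ]),
    expected = as.numeric(x$expected[1, ]),
    mc_se = as.numeric(x$mc_se[1, ])
  )
}
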