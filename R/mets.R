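#' Unit conversion constants for lipid criteria
#'
#' The MetS criteria are stated in mg/dL while the clinical table stores
#' cholesterol fractions in mmol/L (triglycerides are already mg/dL).
#' Cholesterol: 1 mmol/L = 38.67 mg/dL; triglycerides: 1 mmol/L = 88.57
#' mg/dL.
#'
#' @format Named numeric vector with elements `cholesterol` and
#'   `triglycerides` (mg/dL per mmol/L).
#' @export
mgdl_per_mmol <- c(cholesterol = 38.67, triglycerides = 88.57)

#' Score the five harmonized metabolic-syndrome risk factors
#'
#' Applies the harmonized IDF / AHA-NHLBI criteria to each clinical record:
#' (1) waist circumference >= 94 cm (males) / >= 80 cm (females);
#' (2) systolic >= 130 mmHg or diastolic >= 85 mmHg or antihypertensive
#' treatment; (3) fasting glucose >= 100 mg/dL or antidiabetic medication;
#' (4) HDL cholesterol < 40 mg/dL (males) / < 50 mg/dL (females) or fibrate
#' treatment; (5) triglycerides >= 150 mg/dL or fibrate treatment. A record
#' missing any determining field is flagged `any_missing` and its count and
#' MetS status are `NA`; such samples are excluded downstream.
#'
#' @param clinical Clinical table (`sample_id`, `sex`, `waist`, `sbp`, `dbp`,
#'   `fasting_glucose` mg/dL, `hdl` mmol/L, `triglycerides` mg/dL, medication
#'   flags).
#' @return A `risk_profile` tibble: `sample_id`, the five logical factors
#'   (`rf_waist`, `rf_bp`, `rf_glucose`, `rf_hdl`, `rf_tg`), `count` (0-5),
#'   `any_missing`, and `mets` (`count >= 3`).
#' @export
count_risk_factors <- function(clinical) {
  cl <- as_tibble(clinical)
  male <- cl$sex == "male"
  hdl_mgdl <- cl$hdl * mgdl_per_mmol[["cholesterol"]]

  waist <- ifelse(male, cl$waist >= 94, cl$waist >= 80)
  bp <- cl$sbp >= 130 | cl$dbp >= 85 | cl$med_antihypertensive
  glu <- cl$fasting_glucose >= 100 | cl$med_antidiabetic
  hdl <- ifelse(male, hdl_mgdl < 40, hdl_mgdl < 50) | cl$med_fibrates
  tg <- cl$triglycerides >= 150 | cl$med_fibrates

  # medication overrides can decide a factor even when the measurement is NA
  bp[is.na(bp) & cl$med_antihypertensive] <- TRUE
  glu[is.na(glu) & cl$med_antidiabetic] <- TRUE
  hdl[is.na(hdl) & cl$med_fibrates] <- TRUE
  tg[is.na(tg) & cl$med_fibrates] <- TRUE

  any_missing <- is.na(waist) | is.na(bp) | is.na(glu) | is.na(hdl) | is.na(tg)
  count <- waist + bp + glu + hdl + tg
  count[any_missing] <- NA_integer_
  out <- tibble(
    sample_id = cl$sample_id,
    rf_waist = waist, rf_bp = bp, rf_glucose = glu, rf_hdl = hdl, rf_tg = tg,
    count = as.integer(count), any_missing = any_missing,
    mets = count >= 3
  )
  structure(out, class = c("risk_profile", class(out)))
}

#' Metabolic syndrome status from a risk profile
#'
#' MetS is present when at least three of the five harmonized risk factors
#' are present; one or two factors qualify as pre-MetS.
#'
#' @param profile A `risk_profile` tibble from [count_risk_factors()].
#' @return Logical vector (`NA` where `any_missing`).
#' @export
mets_status <- function(profile) {
  profile$count >= 3
}

#' Cohorts contrasting k concurrent risk factors against none
#'
#' Builds, for k = 1..5, the case group of samples with exactly k risk
#' factors and the shared control group with none, for graded binary
#' classification of metabolic burden. Samples with missing factors appear in
#' no cohort; empty case strata are skipped with a warning.
#'
#' @param profile A `risk_profile` tibble.
#' @return Named list (`k1`..`k5`) of lists with `cases` and `controls`
#'   sample-id vectors.
#' @export
k_vs_zero_cohorts <- function(profile) {
  p <- profile[!is.na(profile$count), ]
  controls <- p$sample_id[p$count == 0]
  if (length(controls) == 0) abort("no zero-risk-factor controls")
  out <- list()
  for (k in 1:5) {
    cases <- p$sample_id[p$count == k]
    if (length(cases) == 0) {
      warn(sprintf("no samples with exactly %d risk factors; stratum skipped", k))
      next
    }
    out[[paste0("k", k)]] <- list(cases = cases, controls = controls)
  }
  out
}

#' Incident-MetS forecasting cohort
#'
#' From individuals with linked baseline and follow-up records (MetS status
#' determinable at both), keeps those MetS-negative at baseline and splits
#' them into cases (MetS-positive at follow-up) and controls (MetS-free at
#' both visits). Baseline-positive individuals and individuals without a
#' follow-up are excluded entirely, so
#' `|cases| + |controls| = |baseline-negative with follow-up|`.
#'
#' @param baseline,followup `risk_profile` tibbles for the two visits.
#' @param clinical Clinical table linking `sample_id` to `individual_id` and
#'   `visit`.
#' @return A `forecast_cohort`: `cases`, `controls` (baseline sample ids),
#'   `outcome` tibble (`sample_id`, `individual_id`, `outcome`), counts.
#' @export
incident_mets_cohort <- function(baseline, followup, clinical) {
  cl <- as_tibble(clinical)
  link <- cl[, c("sample_id", "individual_id", "visit")]
  b <- inner_join(baseline, link[link$visit == 1, ], by = "sample_id")
  f <- inner_join(followup, link[link$visit == 2, ], by = "sample_id")
  both <- inner_join(
    b[!is.na(b$mets), c("individual_id", "sample_id", "mets")],
    f[!is.na(f$mets), c("individual_id", "mets")],
    by = "individual_id", suffix = c("_baseline", "_followup")
  )
  if (nrow(both) == 0) abort("no linked individuals with both visits")
  neg <- both[!both$mets_baseline, ]
  cases <- neg$sample_id[neg$mets_followup]
  controls <- neg$sample_id[!neg$mets_followup]
  structure(
    list(
      cases = cases, controls = controls,
      outcome = tibble(
        sample_id = neg$sample_id, individual_id = neg$individual_id,
        outcome = neg$mets_followup
      ),
      n_baseline_negative = nrow(neg), n_cases = length(cases),
      n_controls = length(controls)
    ),
    class = "forecast_cohort"
  )
}

#' @export
print.forecast_cohort <- function(x, ...) {
  cat(sprintf(
    "<forecast_cohort> %d converters vs %d non-converters (of %d baseline-negative)\n",
    x$n_cases, x$n_controls, x$n_baseline_negative
  ))
  invisible(x)
}

#' Forecast incident MetS from baseline fingerprints
#'
#' 10-fold cross-validated binary classification of future MetS onset:
#' features are exclusively the baseline-visit preprocessed spectra of the
#' forecast cohort; outcomes come from the follow-up records. No follow-up
#' spectrum ever enters the feature matrix.
#'
#' @param cohort A `forecast_cohort`.
#' @param baseline_spectra Preprocessed spectra tibble containing the
#'   baseline samples.
#' @param k Folds. @param c_reg Regularization. @param seed Fold seed.
#' @param stratify Stratify folds by outcome (default `FALSE`).
#' @return An `ir_binary_experiment`.
#' @export
forecast_experiment <- function(cohort, baseline_spectra, k = 10, c_reg = 1,
                                seed = 1L, stratify = FALSE) {
  if (length(cohort$cases) == 0 || length(cohort$controls) == 0) {
    abort("forecast cohort needs both converters and non-converters")
  }
  ids <- cohort$outcome$sample_id
  missing_sp <- setdiff(ids, baseline_spectra$sample_id)
  if (length(missing_sp)) {
    abort(sprintf("%d cohort samples lack baseline spectra", length(missing_sp)))
  }
  samples <- tibble(
    sample_id = ids, individual_id = cohort$outcome$individual_id,
    outcome = cohort$outcome$outcome
  )
  plan <- make_cv_folds(samples,
    k = k, seed = seed,
    strata = if (stratify) "outcome" else NULL, regime = "cv_baseline"
  )
  run_binary_experiment(
    subset_rows(baseline_spectra, ids),
    samples[, c("sample_id", "outcome")], plan,
    c_reg = c_reg
  )
}
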