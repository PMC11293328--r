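base_record <- function(...) {
  out <- tibble::tibble(
    sample_id = "x", sex = "male", waist = 80, sbp = 115, dbp = 70,
    fasting_glucose = 90, hdl = 1.5, triglycerides = 100,
    med_antihypertensive = FALSE, med_antidiabetic = FALSE, med_fibrates = FALSE
  )
  dplyr::mutate(out, ...)
}

test_that("each harmonized risk factor fires at its printed cut-off", {
  # male waist boundary at 94 cm
  p <- count_risk_factors(base_record(waist = 95))
  expect_true(p$rf_waist)
  expect_equal(p$count, 1L)
  expect_false(count_risk_factors(base_record(waist = 93.9))$rf_waist)
  # female waist boundary at 80 cm
  expect_true(count_risk_factors(base_record(sex = "female", waist = 80))$rf_waist)
  # blood pressure disjunction incl. treatment override
  expect_true(count_risk_factors(base_record(sbp = 130))$rf_bp)
  expect_true(count_risk_factors(base_record(dbp = 85))$rf_bp)
  expect_true(count_risk_factors(base_record(med_antihypertensive = TRUE))$rf_bp)
  expect_false(count_risk_factors(base_record(sbp = 129, dbp = 84))$rf_bp)
  # fasting glucose at 100 mg/dL or antidiabetic medication
  expect_true(count_risk_factors(base_record(fasting_glucose = 100))$rf_glucose)
  expect_true(count_risk_factors(base_record(med_antidiabetic = TRUE))$rf_glucose)
  # HDL, sex-specific in mg/dL: female < 50 -> 49 mg/dL = 1.267 mmol/L fires
  expect_true(count_risk_factors(
    base_record(sex = "female", hdl = 49 / 38.67)
  )$rf_hdl)
  expect_false(count_risk_factors(
    base_record(sex = "male", hdl = 49 / 38.67)
  )$rf_hdl)
  expect_true(count_risk_factors(base_record(med_fibrates = TRUE))$rf_hdl)
  # triglycerides at 150 mg/dL or fibrates
  expect_true(count_risk_factors(base_record(triglycerides = 150))$rf_tg)
  expect_true(count_risk_factors(base_record(med_fibrates = TRUE))$rf_tg)
})

test_that("missing determining fields exclude a record from scoring", {
  p <- count_risk_factors(base_record(waist = NA))
  expect_true(p$any_missing)
  expect_true(is.na(p$count))
  expect_true(is.na(p$mets))
  # a medication override decides its factor even with a missing measurement
  p2 <- count_risk_factors(base_record(sbp = NA, med_antihypertensive = TRUE))
  expect_true(p2$rf_bp)
  expect_false(p2$any_missing)
})

test_that("MetS requires at least three factors; one or two are pre-MetS", {
  three <- count_risk_factors(base_record(waist = 100, sbp = 135, triglycerides = 160))
  expect_equal(three$count, 3L)
  expect_true(mets_status(three))
  two <- count_risk_factors(base_record(waist = 100, sbp = 135))
  expect_equal(two$count, 2L)
  expect_false(mets_status(two))
  expect_false(mets_status(count_risk_factors(base_record())))
})

test_that("risk scoring matches the independent rule-table oracle", {
  rec <- random_clinical_records(10000, seed = 314)
  prof <- count_risk_factors(rec)
  oracle <- vapply(
    seq_len(nrow(rec)),
    function(i) oracle_risk_count(rec[i, ]), integer(1)
  )
  expect_equal(prof$count, oracle)
  expect_equal(is.na(prof$count), is.na(oracle))
  expect_equal(prof$mets, oracle >= 3)
})

test_that("adding a risk factor never lowers the count or clears MetS", {
  rec <- random_clinical_records(300, seed = 55, na_rate = 0)
  before <- count_risk_factors(rec)
  worse <- dplyr::mutate(rec,
    waist = waist + 40, sbp = sbp + 40,
    triglycerides = triglycerides + 200
  )
  after <- count_risk_factors(worse)
  expect_true(all(after$count >= before$count))
  expect_false(any(before$mets & !after$mets))
})

test_that("k-vs-0 cohorts partition by exact factor count", {
  co <- small_cohort()
  prof <- count_risk_factors(co$clinical)
  cohorts <- suppressWarnings(k_vs_zero_cohorts(prof))
  for (k in seq_along(cohorts)) {
    kk <- as.integer(sub("k", "", names(cohorts)[k]))
    counts <- prof$count[match(cohorts[[k]]$cases, prof$sample_id)]
    expect_true(all(counts == kk))
    zero <- prof$count[match(cohorts[[k]]$controls, prof$sample_id)]
    expect_true(all(zero == 0))
  }
  # missing-profile samples never appear
  excluded <- prof$sample_id[is.na(prof$count)]
  all_ids <- unlist(lapply(cohorts, function(x) c(x$cases, x$controls)))
  expect_length(intersect(excluded, all_ids), 0)
  # a sample with count 2 appears only in the k = 2 cohort
  two <- prof$sample_id[!is.na(prof$count) & prof$count == 2][1]
  hits <- vapply(cohorts, function(x) two %in% x$cases, TRUE)
  expect_equal(sum(hits), 1L)
  expect_true(hits[["k2"]])
})

test_that("incident cohort construction satisfies the partition identity", {
  co <- small_cohort()
  cl <- co$clinical
  p1 <- count_risk_factors(cl[cl$visit == 1, ])
  p2 <- count_risk_factors(cl[cl$visit == 2, ])
  fc <- incident_mets_cohort(p1, p2, cl)
  expect_equal(fc$n_cases + fc$n_controls, fc$n_baseline_negative)
  expect_length(intersect(fc$cases, fc$controls), 0)
  # all members are baseline MetS-negative with a scored follow-up
  ids <- c(fc$cases, fc$controls)
  expect_true(all(p1$mets[match(ids, p1$sample_id)] == FALSE))
  inds <- cl$individual_id[match(ids, cl$sample_id)]
  i2 <- cl$individual_id[cl$visit == 2]
  expect_true(all(inds %in% i2))
  # baseline-positive individuals are excluded entirely
  pos_inds <- cl$individual_id[match(
    p1$sample_id[!is.na(p1$mets) & p1$mets], cl$sample_id
  )]
  expect_length(intersect(inds, pos_inds), 0)
  # visit-1-only individuals (no follow-up) are excluded
  no_fu <- setdiff(cl$individual_id[cl$visit == 1], i2)
  expect_length(intersect(inds, no_fu), 0)
})

test_that("generated converters enrich the incident cases", {
  co <- small_cohort()
  cl <- co$clinical
  fc <- incident_mets_cohort(
    count_risk_factors(cl[cl$visit == 1, ]),
    count_risk_factors(cl[cl$visit == 2, ]),
    cl
  )
  case_inds <- cl$individual_id[match(fc$cases, cl$sample_id)]
  ctrl_inds <- cl$individual_id[match(fc$controls, cl$sample_id)]
  conv <- co$truth$converters
  expect_gt(mean(case_inds %in% conv), mean(ctrl_inds %in% conv))
})

test_that("forecasting uses baseline features only and detects the signal", {
  co <- small_cohort()
  pp <- small_fingerprints()
  cl <- co$clinical
  fc <- incident_mets_cohort(
    count_risk_factors(cl[cl$visit == 1, ]),
    count_risk_factors(cl[cl$visit == 2, ]),
    cl
  )
  fe <- forecast_experiment(fc, pp, k = 5, seed = 1)
  expect_gt(fe$auc_mean, 0.55)
  # every feature row used comes from visit 1
  expect_true(all(fc$outcome$sample_id %in% cl$sample_id[cl$visit == 1]))
  # spectra restricted to visit-2 rows must be rejected
  pp2 <- pp[pp$sample_id %in% cl$sample_id[cl$visit == 2], ]
  expect_error(forecast_experiment(fc, pp2, k = 5), "lack baseline spectra")
})

test_that("removing the conversion signal collapses forecast accuracy", {
  # converters chosen at random and no between-visit latent drift: the only
  # residual forecastable information is proximity to the risk-factor
  # thresholds at baseline (intrinsic to threshold-crossing dynamics)
  co0 <- simulate_cohort(sim_config(
    n_set1 = 320, n_set2 = 320, n_overlap = 320, seed = 77,
    forecast_signal = 0, visit_drift_sd = 0, missing_rate = 0
  ))
  pp0 <- preprocess_spectra(co0$spectra, co0$water)$spectra
  cl0 <- co0$clinical
  fc0 <- incident_mets_cohort(
    count_risk_factors(cl0[cl0$visit == 1, ]),
    count_risk_factors(cl0[cl0$visit == 2, ]),
    cl0
  )
  fe0 <- forecast_experiment(fc0, pp0, k = 5, seed = 2)
  co1 <- small_cohort()
  cl1 <- co1$clinical
  fc1 <- incident_mets_cohort(
    count_risk_factors(cl1[cl1$visit == 1, ]),
    count_risk_factors(cl1[cl1$visit == 2, ]),
    cl1
  )
  fe1 <- forecast_experiment(fc1, small_fingerprints(), k = 5, seed = 2)
  expect_lt(fe0$auc_mean, fe1$auc_mean)
  expect_lt(fe0$auc_mean, 0.75)

  # permuting the outcomes is the exact chance floor
  perm <- fc0
  perm$outcome$outcome <- withr::with_seed(3, sample(perm$outcome$outcome))
  perm$cases <- perm$outcome$sample_id[perm$outcome$outcome]
  perm$controls <- perm$outcome$sample_id[!perm$outcome$outcome]
  fep <- forecast_experiment(perm, pp0, k = 5, seed = 2)
  expect_lt(abs(fep$auc_mean - 0.5), 0.15)
})
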