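test_that("population structure respects set sizes and overlap bookkeeping", {
  cfg <- sim_config(n_set1 = 120, n_set2 = 80, n_overlap = 50, seed = 9)
  pop <- make_population(cfg)
  expect_equal(nrow(pop$individuals), 120 + 80 - 50)
  cl <- pop$clinical
  expect_equal(sum(cl$visit == 1), 120)
  expect_equal(sum(cl$visit == 2), 80)
  ind1 <- unique(cl$individual_id[cl$visit == 1])
  ind2 <- unique(cl$individual_id[cl$visit == 2])
  expect_equal(length(intersect(ind1, ind2)), 50)
  expect_equal(length(union(ind1, ind2)), 150)
  expect_false(anyDuplicated(cl$sample_id) > 0)
  # each (individual, visit) pair unique
  expect_false(anyDuplicated(cl[, c("individual_id", "visit")]) > 0)
  # ages within the configured range at baseline
  expect_true(all(pop$individuals$age_baseline >= 32 &
    pop$individuals$age_baseline <= 88))
})

test_that("disjoint sets and study-scale unique-individual count", {
  pop0 <- make_population(sim_config(n_set1 = 30, n_set2 = 20, n_overlap = 0, seed = 2))
  expect_equal(nrow(pop0$individuals), 50)
  # the study-design default: 3044 + 2140 - 2015 = 3169 unique individuals
  cfg <- sim_config()
  expect_equal(cfg$n_set1 + cfg$n_set2 - cfg$n_overlap, 3169)
})

test_that("generation is deterministic given the seed", {
  a <- simulate_cohort(sim_config(n_set1 = 40, n_set2 = 25, n_overlap = 10, seed = 7))
  b <- simulate_cohort(sim_config(n_set1 = 40, n_set2 = 25, n_overlap = 10, seed = 7))
  expect_equal(a$clinical, b$clinical)
  expect_equal(a$spectra, b$spectra)
  expect_equal(a$labels, b$labels)
  c2 <- simulate_cohort(sim_config(n_set1 = 40, n_set2 = 25, n_overlap = 10, seed = 8))
  expect_false(isTRUE(all.equal(a$clinical$fasting_glucose, c2$clinical$fasting_glucose)))
})

test_that("clinical records satisfy their physiological invariants", {
  cl <- small_cohort()$truth$concentrations
  expect_true(all(cl[, c(
    "fasting_glucose", "hba1c", "total_cholesterol", "ldl",
    "hdl", "triglycerides", "creatinine", "albumin", "leukocytes",
    "erythrocytes", "platelets", "glucose_2h"
  )] > 0))
  expect_true(all(cl$hematocrit > 0 & cl$hematocrit < 1))
  expect_true(all(cl$total_cholesterol >= cl$hdl))
})

test_that("phenotype assignment follows the clinical threshold rules", {
  base <- tibble::tibble(
    sample_id = "x", total_cholesterol = 4.5, hdl = 1.5, sbp = 120, dbp = 70,
    fasting_glucose = 90, glucose_2h = 110,
    med_antihypertensive = FALSE, med_antidiabetic = FALSE
  )
  all_neg <- assign_phenotypes(base)
  expect_true(all_neg$healthy)
  expect_false(any(unlist(all_neg[, c("dyslipidemia", "hypertension", "prediabetes", "t2d")])))

  # non-HDL 5.0 mmol/L exceeds the 4.1 cut-off
  dys <- assign_phenotypes(dplyr::mutate(base, total_cholesterol = 6, hdl = 1))
  expect_true(dys$dyslipidemia)
  expect_false(dys$healthy)

  # diastolic alone reaches the and/or disjunction boundary
  hyp <- assign_phenotypes(dplyr::mutate(base, sbp = 139, dbp = 90))
  expect_true(hyp$hypertension)
  # one below both cut-offs is negative
  expect_false(assign_phenotypes(dplyr::mutate(base, sbp = 139, dbp = 89))$hypertension)
  # medication overrides the reading
  expect_true(assign_phenotypes(dplyr::mutate(base, med_antihypertensive = TRUE))$hypertension)

  # glycemic staging: prediabetic band vs diabetic thresholds
  expect_true(assign_phenotypes(dplyr::mutate(base, fasting_glucose = 110))$prediabetes)
  expect_true(assign_phenotypes(dplyr::mutate(base, fasting_glucose = 126))$t2d)
  expect_true(assign_phenotypes(dplyr::mutate(base, glucose_2h = 140))$prediabetes)
  t2d <- assign_phenotypes(dplyr::mutate(base, glucose_2h = 200))
  expect_true(t2d$t2d)
  expect_false(t2d$prediabetes)

  # missing determining field -> unknown with NA labels
  unk <- assign_phenotypes(dplyr::mutate(base, hdl = NA))
  expect_true(unk$unknown)
  expect_true(is.na(unk$dyslipidemia))
})

test_that("every generated label vector is feasible", {
  lab <- known_labels(small_cohort())
  m <- as.matrix(lab[, phenotype_labels()])
  expect_false(any(m[, "prediabetes"] & m[, "t2d"]))
  derived_healthy <- !(m[, "dyslipidemia"] | m[, "hypertension"] |
    m[, "prediabetes"] | m[, "t2d"])
  expect_equal(unname(m[, "healthy"]), unname(derived_healthy))
  expect_true(all(rowSums(m) >= 1))
})

test_that("the Beer-Lambert forward model is linear and zero-preserving", {
  grid <- seq(950, 3050, by = 2)
  lib <- band_library()
  conc <- tibble::tibble(
    sample_id = c("a", "b"),
    fasting_glucose = c(0, 100), albumin = c(0, 45)
  )
  sp <- synthesize_spectra(conc, lib, grid)
  expect_equal(unname(spectra_matrix(sp)["a", ]), rep(0, length(grid)))
  sp2 <- synthesize_spectra(dplyr::mutate(conc,
    fasting_glucose = fasting_glucose * 2, albumin = albumin * 2
  ), lib, grid)
  expect_equal(spectra_matrix(sp2)["b", ], 2 * spectra_matrix(sp)["b", ])

  # glucose-only spectrum peaks inside the glucose window
  glu <- synthesize_spectra(
    tibble::tibble(sample_id = "g", fasting_glucose = 100), lib, grid
  )
  peak <- grid[which.max(spectra_matrix(glu)[1, ])]
  expect_gte(peak, 1000)
  expect_lte(peak, 1180)

  expect_error(
    synthesize_spectra(tibble::tibble(sample_id = "x", unobtanium = 1), lib, grid),
    "absent from band library"
  )
})

test_that("stronger lipid effect raises non-HDL among dyslipidemia positives", {
  lo <- make_population(sim_config(
    n_set1 = 400, n_set2 = 0, n_overlap = 0, seed = 31,
    effect_sizes = c(lipid = 1), missing_rate = 0
  ))
  hi <- make_population(sim_config(
    n_set1 = 400, n_set2 = 0, n_overlap = 0, seed = 31,
    effect_sizes = c(lipid = 1.5), missing_rate = 0
  ))
  non_hdl_pos <- function(pop) {
    lab <- assign_phenotypes(pop$clinical)
    x <- pop$clinical$total_cholesterol - pop$clinical$hdl
    mean(x[which(lab$dyslipidemia)])
  }
  expect_gt(non_hdl_pos(hi), non_hdl_pos(lo))
})

test_that("written cohorts round-trip through the readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_set1 = 25, n_set2 = 15, n_overlap = 10, seed = 13))
  paths <- write_cohort(co, dir)
  sp1 <- read_spectra_csv(file.path(dir, "spectra_set1.csv"))
  sp2 <- read_spectra_csv(file.path(dir, "spectra_set2.csv"))
  expect_equal(nrow(sp1), 25)
  expect_equal(nrow(sp2), 15)
  orig1 <- co$spectra[match(sp1$sample_id, co$spectra$sample_id), ]
  expect_equal(spectra_matrix(sp1), spectra_matrix(orig1), tolerance = 1e-12)
  cl <- read_clinical_csv(file.path(dir, "clinical.csv"))
  expect_equal(cl$fasting_glucose, co$clinical$fasting_glucose, tolerance = 1e-12)
  lab <- read_labels_csv(file.path(dir, "labels.csv"))
  expect_equal(lab$healthy, co$labels$healthy)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  # ground truth lists every sample exactly once
  expect_setequal(names(gt$water_deficit), co$clinical$sample_id)
  expect_equal(length(gt$water_deficit), nrow(co$clinical))
})
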