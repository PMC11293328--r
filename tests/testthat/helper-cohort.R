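# memoized fixtures: built once per test run, shared across files

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small two-visit cohort for unit tests
small_cohort <- function() {
  memo("small", simulate_cohort(
    sim_config(n_set1 = 220, n_set2 = 160, n_overlap = 110, seed = 42)
  ))
}

# its preprocessed fingerprints
small_fingerprints <- function() {
  memo("small_pp", preprocess_spectra(small_cohort()$spectra, small_cohort()$water)$spectra)
}

# study-scale cohort for the end-to-end acceptance checks
accept_cohort <- function() {
  memo("accept", simulate_cohort(
    sim_config(n_set1 = 2000, n_set2 = 1400, n_overlap = 1000, seed = 1)
  ))
}

accept_fingerprints <- function() {
  memo("accept_pp", preprocess_spectra(accept_cohort()$spectra, accept_cohort()$water)$spectra)
}

analyte_features <- function(cohort, ids = NULL) {
  ana <- cohort$clinical[, c(
    "sample_id", "fasting_glucose", "hba1c", "total_cholesterol", "ldl",
    "hdl", "triglycerides", "creatinine", "albumin", "leukocytes",
    "erythrocytes", "hematocrit", "platelets"
  )]
  if (!is.null(ids)) ana <- ana[match(ids, ana$sample_id), ]
  ana[stats::complete.cases(ana), ]
}

# labels restricted to known (non-unknown) samples, aligned to given ids
known_labels <- function(cohort, ids = NULL) {
  lab <- cohort$labels[!cohort$labels$unknown, ]
  if (!is.null(ids)) lab <- lab[lab$sample_id %in% ids, ]
  lab
}

# a small deterministic spectra tibble on an arbitrary grid
toy_spectra <- function(m, ids = paste0("s", seq_len(nrow(m))), grid = NULL) {
  if (!is.null(grid)) colnames(m) <- as.character(grid)
  as_spectra(m, sample_id = ids)
}

# independent set-arithmetic oracle for the three multilabel metrics
oracle_multilabel <- function(Y, Yhat) {
  n <- nrow(Y)
  emr <- 0
  hs <- 0
  hl <- 0
  for (i in seq_len(n)) {
    yi <- which(Y[i, ])
    pi <- which(Yhat[i, ])
    emr <- emr + as.integer(setequal(yi, pi) && all(Y[i, ] == Yhat[i, ]))
    u <- union(yi, pi)
    hs <- hs + if (length(u) == 0) 1 else length(intersect(yi, pi)) / length(u)
    hl <- hl + sum(Y[i, ] != Yhat[i, ])
  }
  c(emr = emr / n, hs = hs / n, one_minus_hl = 1 - hl / (n * ncol(Y)))
}

# O(n^2) pairwise-concordance oracle for the AUC (ties count 1/2)
oracle_auc <- function(y, s) {
  pos <- s[y]
  neg <- s[!y]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independent rule-table oracle for the harmonized MetS risk factors
oracle_risk_count <- function(row) {
  male <- row$sex == "male"
  hdl_mgdl <- row$hdl * 38.67
  f <- c(
    if (male) row$waist >= 94 else row$waist >= 80,
    row$sbp >= 130 || row$dbp >= 85 || row$med_antihypertensive,
    row$fasting_glucose >= 100 || row$med_antidiabetic,
    (if (male) hdl_mgdl < 40 else hdl_mgdl < 50) || row$med_fibrates,
    row$triglycerides >= 150 || row$med_fibrates
  )
  # medication overrides rescue NA measurements
  if (is.na(f[2]) && isTRUE(row$med_antihypertensive)) f[2] <- TRUE
  if (is.na(f[3]) && isTRUE(row$med_antidiabetic)) f[3] <- TRUE
  if (is.na(f[4]) && isTRUE(row$med_fibrates)) f[4] <- TRUE
  if (is.na(f[5]) && isTRUE(row$med_fibrates)) f[5] <- TRUE
  if (anyNA(f)) NA_integer_ else sum(f)
}

random_clinical_records <- function(n, seed, na_rate = 0.05) {
  withr::with_seed(seed, {
    tibble::tibble(
      sample_id = paste0("r", seq_len(n)),
      sex = sample(c("male", "female"), n, TRUE),
      waist = ifelse(runif(n) < na_rate, NA, runif(n, 60, 130)),
      sbp = ifelse(runif(n) < na_rate, NA, runif(n, 90, 200)),
      dbp = ifelse(runif(n) < na_rate, NA, runif(n, 50, 120)),
      fasting_glucose = ifelse(runif(n) < na_rate, NA, runif(n, 60, 250)),
      hdl = ifelse(runif(n) < na_rate, NA, runif(n, 0.5, 3)),
      triglycerides = ifelse(runif(n) < na_rate, NA, runif(n, 40, 400)),
      med_antihypertensive = runif(n) < 0.2,
      med_antidiabetic = runif(n) < 0.1,
      med_fibrates = runif(n) < 0.1
    )
  })
}
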