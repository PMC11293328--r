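#' Configuration for the synthetic two-visit cohort
#'
#' Defines the population structure (two partially overlapping sample sets,
#' mirroring a baseline and a follow-up donation), the effect sizes tying
#' latent metabolic burdens to clinical analytes, the Beer-Lambert forward
#' model settings, and the between-visit batch effects. Defaults reproduce the
#' study-scale design: 3044 baseline samples, 2140 follow-up samples, 2015
#' individuals donating at both visits, ages 32-88, ~3% of samples with a
#' missing phenotype-determining field, and ~17% of baseline-MetS-negative
#' individuals converting to MetS by the follow-up.
#'
#' @param n_set1,n_set2 Samples in sets 1 (visit 1) and 2 (visit 2).
#' @param n_overlap Individuals donating at both visits
#'   (`n_overlap <= min(n_set1, n_set2)`).
#' @param seed Integer seed; every random draw in [simulate_cohort()] derives
#'   from it.
#' @param age_range Baseline age range in years.
#' @param effect_sizes Named multipliers on the latent-burden -> analyte/blood
#'   pressure couplings (`lipid`, `glycemic`, `vascular`, `adiposity`, `sex`).
#'   1 = default magnitude, 0 switches the pathway off.
#' @param noise_sd Spectral (per-channel) Gaussian noise, AU.
#' @param path_length Per-visit optical path-length factors (length 2);
#'   visit 2 defaults to a 6% longer effective path, a cuvette batch effect.
#' @param storage_drift Visit-2 additive baseline distortion amplitude, AU.
#' @param batch_sd SD of the per-analyte visit-2 multiplicative log-scale
#'   drift (assay/storage batch effect).
#' @param visit_drift_sd SD of the individual latent-burden random walk
#'   between visits.
#' @param water_deficit_range Range of the per-sample water deficit
#'   coefficient `d` in the forward model `A = L(sum c eps + baseline) - d W + noise`.
#' @param baseline_scale Multiplier on the smooth instrumental baseline
#'   (0 disables it).
#' @param missing_rate Fraction of samples with one phenotype-determining
#'   field blanked in the released clinical table.
#' @param convert_fraction Fraction of baseline-MetS-negative overlap
#'   individuals that develop MetS by visit 2.
#' @param forecast_signal Strength of the link between baseline latent burden
#'   and conversion (0 = converters chosen at random, so baseline spectra
#'   carry no forecasting information).
#' @param followup_years Time between visits (enters only the ageing of
#'   participants, not any classifier).
#' @param grid Wavenumber axis of the synthesized raw spectra.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_set1 = 3044, n_set2 = 2140, n_overlap = 2015,
                       seed = 1L,
                       age_range = c(32, 88),
                       effect_sizes = c(
                         lipid = 1, glycemic = 1, vascular = 1,
                         adiposity = 1, sex = 1
                       ),
                       noise_sd = 5e-4,
                       path_length = c(1, 1.06),
                       storage_drift = 0.006,
                       batch_sd = 0.03,
                       visit_drift_sd = 0.18,
                       water_deficit_range = c(0, 0.25),
                       baseline_scale = 1,
                       missing_rate = 0.03,
                       convert_fraction = 0.168,
                       forecast_signal = 1,
                       followup_years = 6.5,
                       grid = seq(950, 3050, by = 2)) {
  for (nm in c("n_set1", "n_set2", "n_overlap")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      abort(sprintf("`%s` must be a non-negative integer", nm))
    }
  }
  if (n_overlap > min(n_set1, n_set2)) {
    abort("`n_overlap` cannot exceed min(n_set1, n_set2)")
  }
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  for (nm in c("missing_rate", "convert_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) abort(sprintf("`%s` must be in [0, 1]", nm))
  }
  if (length(water_deficit_range) != 2 || diff(water_deficit_range) < 0) {
    abort("`water_deficit_range` must be an increasing length-2 range")
  }
  es <- c(lipid = 1, glycemic = 1, vascular = 1, adiposity = 1, sex = 1)
  es[names(effect_sizes)] <- effect_sizes
  structure(
    list(
      n_set1 = as.integer(n_set1), n_set2 = as.integer(n_set2),
      n_overlap = as.integer(n_overlap), seed = as.integer(seed),
      age_range = age_range, effect_sizes = es, noise_sd = noise_sd,
      path_length = path_length, storage_drift = storage_drift,
      batch_sd = batch_sd, visit_drift_sd = visit_drift_sd,
      water_deficit_range = water_deficit_range,
      baseline_scale = baseline_scale, missing_rate = missing_rate,
      convert_fraction = convert_fraction, forecast_signal = forecast_signal,
      followup_years = followup_years, grid = grid
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> set1 = %d, set2 = %d, overlap = %d (unique individuals = %d), seed = %d\n",
    x$n_set1, x$n_set2, x$n_overlap, x$n_set1 + x$n_set2 - x$n_overlap, x$seed
  ))
  invisible(x)
}

#' Names of the five modeled phenotypes
#'
#' @return Character vector in the default chain order: dyslipidemia,
#'   hypertension, prediabetes, t2d, healthy.
#' @export
phenotype_labels <- function() {
  c("dyslipidemia", "hypertension", "prediabetes", "t2d", "healthy")
}

#' The clinically feasible phenotype label combinations
#'
#' Enumerates all 2^5 binary vectors over the five phenotype labels and keeps
#' those satisfying the feasibility constraints: a diabetic individual cannot
#' simultaneously be prediabetic, and `healthy` holds exactly when all four
#' conditions are absent. Exactly 12 combinations survive.
#'
#' @return A tibble with one logical column per phenotype, 12 rows.
#' @examples
#' nrow(phenotype_combinations()) # 12
#' @export
phenotype_combinations <- function() {
  labs <- phenotype_labels()
  grid <- tidyr::expand_grid(
    dyslipidemia = c(FALSE, TRUE), hypertension = c(FALSE, TRUE),
    prediabetes = c(FALSE, TRUE), t2d = c(FALSE, TRUE),
    healthy = c(FALSE, TRUE)
  )
  ok <- !(grid$prediabetes & grid$t2d) &
    (grid$healthy == !(grid$dyslipidemia | grid$hypertension |
      grid$prediabetes | grid$t2d))
  out <- grid[ok, labs]
  as_tibble(out)
}

#' Clinical phenotype decision thresholds
#'
#' Cut-offs used to derive the five phenotype labels from a clinical record:
#' dyslipidemia when non-HDL cholesterol (total minus HDL) exceeds 4.1 mmol/L;
#' hypertension at >= 140 mmHg systolic and/or >= 90 mmHg diastolic or use of
#' antihypertensive medication; glycemic staging in the WHO style, with type 2
#' diabetes at fasting glucose >= 126 mg/dL or 2-h glucose >= 200 mg/dL or
#' antidiabetic medication, and prediabetes (impaired fasting glucose and/or
#' impaired glucose tolerance) at fasting 110-125 mg/dL or 2-h 140-199 mg/dL.
#'
#' @param non_hdl mmol/L. @param sbp,dbp mmHg.
#' @param fasting_t2d,g2h_t2d,fasting_pre,g2h_pre mg/dL.
#' @return Named list of thresholds.
#' @export
phenotype_thresholds <- function(non_hdl = 4.1, sbp = 140, dbp = 90,
                                 fasting_t2d = 126, g2h_t2d = 200,
                                 fasting_pre = 110, g2h_pre = 140) {
  as.list(environment())
}

#' Derive phenotype labels from clinical records
#'
#' Applies the threshold rules of [phenotype_thresholds()] row-wise. A record
#' missing any field that determines a label is flagged `unknown = TRUE` and
#' gets `NA` labels; such samples are excluded from downstream analyses.
#' `healthy` is the conjunction of all four conditions being absent, so every
#' emitted non-unknown label vector is one of the 12 feasible combinations.
#'
#' @param clinical Tibble with columns `sample_id`, `total_cholesterol`,
#'   `hdl` (mmol/L), `sbp`, `dbp` (mmHg), `fasting_glucose`, `glucose_2h`
#'   (mg/dL) and the logical medication flags `med_antihypertensive`,
#'   `med_antidiabetic`.
#' @param thresholds See [phenotype_thresholds()].
#' @return Tibble: `sample_id`, five logical label columns, `unknown`.
#' @export
assign_phenotypes <- function(clinical, thresholds = phenotype_thresholds()) {
  cl <- as_tibble(clinical)
  need <- c(
    "sample_id", "total_cholesterol", "hdl", "sbp", "dbp",
    "fasting_glucose", "glucose_2h", "med_antihypertensive", "med_antidiabetic"
  )
  miss <- setdiff(need, names(cl))
  if (length(miss)) abort(paste("clinical table lacks columns:", toString(miss)))
  th <- thresholds

  non_hdl <- cl$total_cholesterol - cl$hdl
  dys <- non_hdl > th$non_hdl
  hyp <- cl$sbp >= th$sbp | cl$dbp >= th$dbp | cl$med_antihypertensive
  t2d <- cl$fasting_glucose >= th$fasting_t2d | cl$glucose_2h >= th$g2h_t2d |
    cl$med_antidiabetic
  pre <- !t2d & ((cl$fasting_glucose >= th$fasting_pre &
    cl$fasting_glucose < th$fasting_t2d) |
    (cl$glucose_2h >= th$g2h_pre & cl$glucose_2h < th$g2h_t2d))

  unknown <- is.na(dys) | is.na(hyp) | is.na(t2d) | is.na(pre)
  dys[unknown] <- NA
  hyp[unknown] <- NA
  t2d[unknown] <- NA
  pre[unknown] <- NA
  healthy <- !(dys | hyp | pre | t2d)

  tibble(
    sample_id = cl$sample_id,
    dyslipidemia = dys, hypertension = hyp, prediabetes = pre,
    t2d = t2d, healthy = healthy, unknown = unknown
  )
}

# analyte names of the 12-analyte clinical panel
analyte_names <- function() {
  c(
    "fasting_glucose", "hba1c", "total_cholesterol", "ldl", "hdl",
    "triglycerides", "creatinine", "albumin", "leukocytes", "erythrocytes",
    "hematocrit", "platelets"
  )
}

#' Generate the synthetic two-visit population
#'
#' Draws individuals (sex, baseline age and BMI, four correlated latent
#' metabolic burdens -- lipid, glycemic, vascular, adiposity -- plus stable
#' per-analyte multipliers), then produces one clinical record per donation.
#' Analyte concentrations are log-normal with sex/age/BMI linear predictors on
#' the log scale, so they are positive and realistically right-skewed. Visit-2
#' records evolve from the same individual's latents through a random drift, a
#' per-analyte batch shift, and -- for the configured fraction of converters --
#' a coordinated rise of all four burdens that produces incident metabolic
#' syndrome. Everything is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `individuals` (one row per person), `clinical` (released
#'   table, with missingness applied), `clinical_true` (complete ground-truth
#'   concentrations), and `converters` (individual ids destined to develop
#'   MetS by visit 2).
#' @export
make_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "population"), make_population_(config))
}

make_population_ <- function(cfg) {
  n1 <- cfg$n_set1
  n2 <- cfg$n_set2
  nov <- cfg$n_overlap
  n_ind <- n1 + n2 - nov
  es <- cfg$effect_sizes

  id <- sprintf("I%05d", seq_len(n_ind))
  # first `nov` individuals attend both visits, then visit-1-only, visit-2-only
  visits <- c(
    rep(list(c(1L, 2L)), nov),
    rep(list(1L), n1 - nov),
    rep(list(2L), n2 - nov)
  )

  sexM <- rbinom(n_ind, 1, 0.49)
  age0 <- runif(n_ind, cfg$age_range[1], cfg$age_range[2])
  bmi0 <- exp(rnorm(n_ind, log(26.5), 0.15))

  # correlated latent burdens: lipid, glycemic, vascular, adiposity
  S <- matrix(0.3, 4, 4)
  diag(S) <- 1
  U <- matrix(rnorm(n_ind * 4), n_ind, 4) %*% chol(S)
  colnames(U) <- c("lip", "gly", "vasc", "adi")

  # stable per-analyte multipliers (individual biochemical idiosyncrasy)
  ana <- analyte_names()
  E <- matrix(rnorm(n_ind * length(ana), 0, 0.05), n_ind,
    dimnames = list(NULL, ana)
  )

  individuals <- tibble(
    individual_id = id, sex = ifelse(sexM == 1, "male", "female"),
    age_baseline = age0, bmi_baseline = bmi0,
    visits = visits
  )

  # visit-2 latent evolution
  drift <- matrix(rnorm(n_ind * 4, 0, cfg$visit_drift_sd), n_ind, 4)
  batch_shift <- setNames(rnorm(length(ana), 0, cfg$batch_sd), ana)

  record_for <- function(idx, visit, U_v, bmi_v) {
    m <- length(idx)
    age <- age0[idx] + (visit - 1) * cfg$followup_years
    z_age <- (age - 60) / 14
    z_bmi <- (bmi_v - 26.5) / 4
    sx <- sexM[idx]
    lip <- es["lipid"] * U_v[, "lip"]
    gly <- es["glycemic"] * U_v[, "gly"]
    vas <- es["vascular"] * U_v[, "vasc"]
    adi <- es["adiposity"] * U_v[, "adi"]
    sfx <- es["sex"]
    bshift <- if (visit == 2) batch_shift else batch_shift * 0
    ln <- function(name, mu, sdm) {
      exp(mu + E[idx, name] + bshift[[name]] + rnorm(m, 0, sdm))
    }

    med_aht <- rbinom(m, 1, plogis(-2.1 + 1.6 * vas + 0.6 * z_age)) == 1
    med_adm <- rbinom(m, 1, plogis(-4.5 + 3.0 * gly)) == 1
    med_fib <- rbinom(m, 1, plogis(-3.6 + 0.9 * lip)) == 1

    fasting <- ln("fasting_glucose", log(97) + 0.16 * gly + 0.05 * z_age + 0.04 * z_bmi, 0.02)
    g2h <- fasting * exp(0.15 + 0.22 * gly + rnorm(m, 0, 0.05))
    # glucose-lowering treatment suppresses measured glucose; HbA1c keeps the memory
    fasting <- fasting * exp(-0.10 * med_adm)
    g2h <- g2h * exp(-0.10 * med_adm)
    # glycation memory: HbA1c tracks chronic exposure, rising disproportionately
    # at diabetic-range burdens while lagging acute (prediabetic) elevations
    hba1c <- ln("hba1c", log(5.5) + 0.05 * gly + 0.12 * pmax(gly - 0.8, 0) + 0.05 * z_age, 0.02)
    hdl <- ln("hdl", log(1.58) - sfx * 0.20 * sx - 0.11 * lip - 0.09 * adi - 0.06 * z_bmi, 0.08)
    non_hdl <- ln("total_cholesterol", log(3.95) + 0.20 * lip + 0.05 * z_age + 0.05 * adi + 0.04 * z_bmi, 0.05)
    total_chol <- hdl + non_hdl
    ldl <- pmin(non_hdl * 0.72 * exp(rnorm(m, 0, 0.05)), 0.95 * non_hdl)
    tg <- ln("triglycerides", log(118) + 0.25 * lip + 0.13 * adi + 0.08 * vas + 0.15 * z_bmi + sfx * 0.08 * sx, 0.20)
    creat <- ln("creatinine", log(0.85) + sfx * 0.30 * sx + 0.26 * vas + 0.06 * z_age, 0.05)
    alb <- ln("albumin", log(45) - 0.05 * vas - 0.035 * z_age - sfx * 0.045 * sx, 0.025)
    leuk <- ln("leukocytes", log(6.1) + 0.05 * adi + 0.10 * z_bmi, 0.20)
    ery <- ln("erythrocytes", log(4.55) + sfx * 0.12 * sx, 0.05)
    hct <- pmin(pmax(ery * 0.088 * exp(rnorm(m, 0, 0.02)), 0.15), 0.65)
    plt <- ln("platelets", log(250) - 0.05 * z_age, 0.18)

    sbp <- 124 + 16 * vas + 5 * z_age + 4 * z_bmi + rnorm(m, 0, 5)
    dbp <- 77 + 10 * vas + 2.5 * z_bmi + rnorm(m, 0, 4)
    waist <- 81 + 13 * sfx * sx + 2.3 * (bmi_v - 26.5) + 2.5 * adi + rnorm(m, 0, 4.5)


    tibble(
      sample_id = sprintf("%s_V%d", id[idx], visit),
      individual_id = id[idx], visit = as.integer(visit),
      sex = ifelse(sx == 1, "male", "female"),
      age = age, bmi = bmi_v, waist = waist, sbp = sbp, dbp = dbp,
      med_antihypertensive = med_aht, med_antidiabetic = med_adm,
      med_fibrates = med_fib,
      fasting_glucose = fasting, hba1c = hba1c,
      total_cholesterol = total_chol, ldl = ldl, hdl = hdl,
      triglycerides = tg, creatinine = creat, albumin = alb,
      leukocytes = leuk, erythrocytes = ery, hematocrit = hct,
      platelets = plt, glucose_2h = g2h
    )
  }

  in_set1 <- which(vapply(visits, function(v) 1L %in% v, TRUE))
  in_set2 <- which(vapply(visits, function(v) 2L %in% v, TRUE))
  rec1 <- record_for(in_set1, 1L, U[in_set1, , drop = FALSE], bmi0[in_set1])

  # converters: baseline-MetS-negative overlap individuals with the highest
  # (noisy) mean latent burden develop MetS by visit 2
  overlap_idx <- seq_len(nov)
  converters <- character(0)
  conv <- rep(FALSE, n_ind)
  if (nov > 0 && cfg$convert_fraction > 0) {
    base1 <- rec1[match(id[overlap_idx], rec1$individual_id), ]
    prof <- count_risk_factors(base1)
    neg <- overlap_idx[!is.na(prof$mets) & !prof$mets]
    if (length(neg) > 0) {
      score <- cfg$forecast_signal * rowMeans(U[neg, , drop = FALSE]) +
        rnorm(length(neg), 0, 0.5)
      n_conv <- round(cfg$convert_fraction * length(neg))
      conv[neg[order(score, decreasing = TRUE)[seq_len(n_conv)]]] <- TRUE
      converters <- id[conv]
    }
  }

  U2 <- U + drift + 0.85 * conv
  bmi2 <- bmi0 * exp(rnorm(n_ind, 0, 0.03)) + 1.4 * conv
  clinical_true <- rec1
  if (length(in_set2) > 0) {
    rec2 <- record_for(in_set2, 2L, U2[in_set2, , drop = FALSE], bmi2[in_set2])
    clinical_true <- bind_rows(rec1, rec2)
  }

  # released table: blank one phenotype-determining field in a few samples
  clinical <- clinical_true
  if (cfg$missing_rate > 0) {
    n_all <- nrow(clinical)
    hit <- which(runif(n_all) < cfg$missing_rate)
    fields <- c(
      "total_cholesterol", "hdl", "sbp", "dbp", "fasting_glucose",
      "glucose_2h", "waist", "triglycerides"
    )
    pick <- sample(fields, length(hit), replace = TRUE)
    for (k in seq_along(hit)) clinical[[pick[k]]][hit[k]] <- NA_real_
  }

  list(
    individuals = individuals, clinical = clinical,
    clinical_true = clinical_true, converters = converters
  )
}

#' Synthesize plasma absorbance spectra from concentrations
#'
#' Beer-Lambert forward model: for each sample,
#' `A(v) = L * (sum_m c_m eps_m(v) + baseline(v)) - d * W(v) + noise`, where
#' `eps_m` is the analyte's Gaussian-band absorptivity profile from the
#' [band_library()], `L` a path-length factor, `d` the sample's water-deficit
#' coefficient, and `W` the pure-water reference. The model is linear in the
#' concentrations; with zero concentrations, baseline, deficit and noise the
#' spectrum is identically zero.
#'
#' @param concentrations Tibble: `sample_id` plus one numeric column per
#'   analyte. Every analyte column must exist in `library`.
#' @param library A [band_library()].
#' @param grid Wavenumber axis.
#' @param path_length Scalar or per-sample vector of path-length factors.
#' @param deficit Scalar or per-sample water-deficit coefficients `d`.
#' @param water Water reference spectra tibble on `grid`; required when any
#'   `deficit != 0`.
#' @param baseline Either `NULL` (none) or a numeric vector on `grid` (per
#'   sample it is scaled by `baseline_jitter` draws when `seed` given).
#' @param noise_sd Per-channel Gaussian noise SD, AU.
#' @param seed Seed for the noise draws (`NULL` = no noise RNG touched when
#'   `noise_sd = 0`).
#' @return A spectra tibble on `grid`.
#' @export
synthesize_spectra <- function(concentrations, library = band_library(),
                               grid = seq(950, 3050, by = 2),
                               path_length = 1, deficit = 0, water = NULL,
                               baseline = NULL, noise_sd = 0, seed = NULL) {
  conc <- as_tibble(concentrations)
  if (names(conc)[1] != "sample_id") abort("first column must be `sample_id`")
  ana <- setdiff(names(conc), "sample_id")
  missing_lib <- setdiff(ana, names(library))
  if (length(missing_lib)) {
    abort(paste("analytes absent from band library:", toString(missing_lib)))
  }
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be strictly increasing")
  n <- nrow(conc)
  p <- length(grid)
  eps <- vapply(ana, function(a) eval_bands(library[[a]], grid), numeric(p))
  C <- as.matrix(conc[, ana, drop = FALSE])
  if (anyNA(C)) abort("concentrations contain missing values")
  A <- C %*% t(eps) # n x p
  if (!is.null(baseline)) {
    if (length(baseline) != p) abort("`baseline` must match the grid length")
    A <- A + matrix(baseline, n, p, byrow = TRUE)
  }
  A <- A * rep(path_length, length.out = n)
  d <- rep(deficit, length.out = n)
  if (any(d != 0)) {
    if (is.null(water)) abort("`water` reference required when deficit != 0")
    w <- as.numeric(spectra_matrix(water)[1, ])
    if (length(w) != p) abort("water reference not on the same grid")
    A <- A - d %o% w
  }
  if (noise_sd > 0) {
    A <- A + with_seed(seed, matrix(rnorm(n * p, 0, noise_sd), n, p))
  }
  colnames(A) <- format_wavenumber(grid)
  rownames(A) <- conc$sample_id
  as_spectra(A)
}

#' Simulate the full synthetic cohort
#'
#' Runs [make_population()], derives phenotype labels, and synthesizes raw
#' FTIR spectra for every donation (ground-truth concentrations drive the
#' spectra even where the released clinical table has masked values). Batch
#' effects between the two visits -- path-length factor, per-analyte assay
#' drift and a storage baseline distortion -- are included so that
#' sample-set-independent validation is genuinely harder than within-set
#' cross-validation.
#'
#' @param config A [sim_config()].
#' @return An `ir_cohort` list: `clinical`, `labels`, `spectra` (raw, all
#'   samples), `water` (reference spectrum), `individuals`, `truth` (complete
#'   concentrations, per-sample water deficit `d`, converter ids, band
#'   library), and `config`.
#' @examples
#' co <- simulate_cohort(sim_config(n_set1 = 40, n_set2 = 30, n_overlap = 20, seed = 7))
#' nrow(co$clinical) # 70
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pop <- make_population(config)
  labels <- assign_phenotypes(pop$clinical)
  grid <- config$grid
  water <- water_reference_spectrum(grid)
  lib <- band_library()

  truth_conc <- pop$clinical_true[, c("sample_id", analyte_names())]
  n <- nrow(truth_conc)
  sp <- with_seed(derive_seed(config$seed, "spectra"), {
    d <- runif(n, config$water_deficit_range[1], config$water_deficit_range[2])
    visit <- pop$clinical_true$visit
    L <- config$path_length[visit]
    base_shape <- config$baseline_scale *
      (0.010 + 0.020 * exp(-((grid - 1250) / 600)^2 / 2))
    storage <- config$storage_drift * exp(-((grid - 1460) / 300)^2 / 2)
    A0 <- spectra_matrix(synthesize_spectra(truth_conc, lib, grid))
    jitter <- 1 + 0.15 * rnorm(n)
    A <- (A0 + jitter %o% base_shape) * L +
      (visit == 2) %o% storage -
      d %o% as.numeric(spectra_matrix(water)[1, ])
    if (config$noise_sd > 0) {
      A <- A + matrix(rnorm(n * length(grid), 0, config$noise_sd), n)
    }
    rownames(A) <- truth_conc$sample_id
    list(spectra = as_spectra(A), deficit = tibble(
      sample_id = truth_conc$sample_id, deficit = d
    ))
  })

  structure(
    list(
      clinical = pop$clinical, labels = labels, spectra = sp$spectra,
      water = water, individuals = pop$individuals,
      truth = list(
        concentrations = pop$clinical_true, deficit = sp$deficit,
        converters = pop$converters, library = lib
      ),
      config = config
    ),
    class = "ir_cohort"
  )
}

#' @export
print.ir_cohort <- function(x, ...) {
  cat(sprintf(
    "<ir_cohort> %d samples (%d visit 1, %d visit 2), %d individuals, %d-point grid\n",
    nrow(x$clinical), sum(x$clinical$visit == 1), sum(x$clinical$visit == 2),
    nrow(x$individuals), length(spectra_grid(x$spectra))
  ))
  invisible(x)
}

#' Samples belonging to one sample set of a cohort
#'
#' Sample set 1 comprises the visit-1 donations, sample set 2 the visit-2
#' donations.
#'
#' @param cohort An `ir_cohort`.
#' @param set 1 or 2.
#' @return Character vector of sample ids.
#' @export
cohort_set <- function(cohort, set) {
  cohort$clinical$sample_id[cohort$clinical$visit == set]
}
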