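#' Stratified k-fold cross-validation plan within one sample set
#'
#' Partitions the samples of one set into k disjoint test folds of near-equal
#' size (differing by at most one). When a stratification column is supplied,
#' strata with at least k members are split evenly across folds (rare strata
#' are pooled), which reduces fold-to-fold variance. Within one sample set
#' each individual contributes a single sample, and the plan asserts that no
#' individual appears in both the train and test side of any fold.
#'
#' @param samples Tibble with `sample_id`, `individual_id` and optionally the
#'   stratification column.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @param strata Optional name of a column to stratify on (e.g. the label
#'   combination).
#' @param regime Regime tag stored in the plan.
#' @return A `fold_plan`: list with `regime`, `k`, `seed` and `folds`, a list
#'   of `list(train =, test =)` sample-id vectors.
#' @export
make_cv_folds <- function(samples, k = 10, seed = 1L, strata = NULL,
                          regime = "cv") {
  s <- as_tibble(samples)
  if (!all(c("sample_id", "individual_id") %in% names(s))) {
    abort("`samples` needs `sample_id` and `individual_id` columns")
  }
  n <- nrow(s)
  if (k > n) abort("more folds than samples")
  fold <- with_seed(derive_seed(seed, "cv_folds"), {
    if (is.null(strata)) {
      grp <- rep("all", n)
    } else {
      grp <- as.character(s[[strata]])
      grp[is.na(grp)] <- ".na"
      small <- names(which(table(grp) < k))
      grp[grp %in% small] <- ".pooled"
    }
    f <- integer(n)
    counter <- 0L
    for (g in unique(grp)) {
      idx <- which(grp == g)
      idx <- idx[sample.int(length(idx))]
      # rotating assignment keeps overall fold sizes within 1 of each other
      f[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- (counter + length(idx)) %% k
    }
    f
  })
  folds <- lapply(seq_len(k), function(i) {
    list(train = s$sample_id[fold != i], test = s$sample_id[fold == i])
  })
  plan <- structure(
    list(
      regime = regime, k = k, seed = seed, folds = folds,
      individual = setNames(s$individual_id, s$sample_id)
    ),
    class = "fold_plan"
  )
  assert_no_leakage(plan)
  plan
}

#' Sample-set-independent validation plan
#'
#' Trains on visit-1 samples, tests on visit-2 samples of individuals never
#' seen in training. The individuals overlapping both sets are partitioned
#' into k disjoint hold-out groups of near-equal size; iteration i tests on
#' the set-2 samples of group i and trains on all set-1 samples except those
#' of group-i individuals. Every fold is therefore free of subject leakage,
#' and the k test groups cover the whole overlapping pool.
#'
#' @param set1,set2 Tibbles (`sample_id`, `individual_id`) for the training
#'   and testing sample sets.
#' @param k Number of hold-out iterations.
#' @param seed Seed for the partition of the overlap individuals.
#' @return A `fold_plan` with regime `"set_independent"`.
#' @export
make_independent_plan <- function(set1, set2, k = 10, seed = 1L) {
  s1 <- as_tibble(set1)
  s2 <- as_tibble(set2)
  overlap <- intersect(unique(s1$individual_id), unique(s2$individual_id))
  if (length(overlap) == 0) abort("no overlapping individuals between the sets")
  if (k > length(overlap)) abort("more folds than overlapping individuals")
  grp <- with_seed(derive_seed(seed, "independent"), {
    setNames(sample(rep_len(seq_len(k), length(overlap))), overlap)
  })
  folds <- lapply(seq_len(k), function(i) {
    held <- overlap[grp == i]
    list(
      train = s1$sample_id[!s1$individual_id %in% held],
      test = s2$sample_id[s2$individual_id %in% held]
    )
  })
  plan <- structure(
    list(
      regime = "set_independent", k = k, seed = seed, folds = folds,
      individual = c(
        setNames(s1$individual_id, s1$sample_id),
        setNames(s2$individual_id, s2$sample_id)
      )[!duplicated(c(s1$sample_id, s2$sample_id))]
    ),
    class = "fold_plan"
  )
  assert_no_leakage(plan)
  plan
}

# the leakage guarantee: no individual on both sides of any fold
assert_no_leakage <- function(plan) {
  for (f in plan$folds) {
    tr <- unique(plan$individual[f$train])
    te <- unique(plan$individual[f$test])
    if (length(intersect(tr, te)) > 0) {
      abort("fold plan leaks individuals between train and test")
    }
  }
  invisible(plan)
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), 1L)
  cat(sprintf(
    "<fold_plan> regime = %s, k = %d, test sizes %d-%d, seed = %d\n",
    x$regime, x$k, min(sizes), max(sizes), x$seed
  ))
  invisible(x)
}

subset_rows <- function(features, ids) {
  if (is.data.frame(features)) {
    idx <- match(ids, features$sample_id)
    if (anyNA(idx)) abort("plan references samples absent from `features`")
    features[idx, , drop = FALSE]
  } else {
    features[ids, , drop = FALSE]
  }
}

#' Run a multilabel experiment over a fold plan
#'
#' For each fold: fit the multilabel model (chained by default, or
#' independent one-vs-rest) on the training samples, predict the test
#' samples, and compute the three multilabel metrics on the test side only.
#' Metrics are aggregated as mean and SD across folds. Features are generic:
#' preprocessed spectra fingerprints or a clinical analyte panel.
#'
#' @param features Features tibble (`sample_id` + numeric columns).
#' @param labels Labels tibble; samples with `NA` labels are dropped from
#'   both sides of every fold.
#' @param plan A `fold_plan`.
#' @param model `"chain"` or `"independent"`.
#' @param order Chain order (default canonical).
#' @param c_reg Inverse regularization strength.
#' @param project Feasibility projection at prediction time.
#' @return An `ir_ml_experiment`: `per_fold` tibble (fold, the three metrics,
#'   n_test), `summary` (mean/sd per metric), plus the configuration.
#' @export
run_multilabel_experiment <- function(features, labels, plan,
                                      model = c("chain", "independent"),
                                      order = NULL, c_reg = 1,
                                      project = FALSE) {
  model <- match.arg(model)
  lab <- as_tibble(labels)
  label_cols <- setdiff(names(lab), c("sample_id", "unknown"))
  known <- lab$sample_id[stats::complete.cases(lab[, label_cols])]
  per_fold <- map(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    tr <- intersect(f$train, known)
    te <- intersect(f$test, known)
    ftr <- subset_rows(features, tr)
    fte <- subset_rows(features, te)
    ytr <- lab[match(tr, lab$sample_id), ]
    yte <- lab[match(te, lab$sample_id), ]
    fitted <- if (model == "chain") {
      fit_chain(ftr, ytr, order = order, c_reg = c_reg)
    } else {
      fit_independent(ftr, ytr, c_reg = c_reg)
    }
    pred <- if (model == "chain") {
      predict(fitted, fte, project = project)
    } else {
      predict(fitted, fte)
    }
    sc <- multilabel_score(
      label_matrix(yte, label_cols),
      label_matrix(pred, label_cols)
    )
    mutate(sc, fold = i, .before = 1)
  })
  per_fold <- bind_rows(per_fold)
  metrics <- c("exact_match_ratio", "hamming_score", "one_minus_hamming_loss")
  summary <- tibble(
    metric = metrics,
    mean = map_dbl(metrics, ~ mean(per_fold[[.x]])),
    sd = map_dbl(metrics, ~ sd(per_fold[[.x]]))
  )
  structure(
    list(
      per_fold = per_fold, summary = summary, regime = plan$regime,
      model = model, c_reg = c_reg
    ),
    class = "ir_ml_experiment"
  )
}

#' @export
print.ir_ml_experiment <- function(x, ...) {
  cat(sprintf(
    "<ir_ml_experiment> %s model, regime = %s, %d folds\n",
    x$model, x$regime, nrow(x$per_fold)
  ))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf(
      "  %-24s %.3f +/- %.3f\n", x$summary$metric[i],
      x$summary$mean[i], x$summary$sd[i]
    ))
  }
  invisible(x)
}

#' Run a binary classification experiment over a fold plan
#'
#' One-vs-rest phenotype detection, metabolic-risk-factor cohorts, or any
#' other binary outcome: per fold an L2-logistic classifier is fit on the
#' training samples and the test ROC curve and AUC are computed. Folds whose
#' train or test side lacks one of the classes are skipped with a warning.
#'
#' @param features Features tibble.
#' @param outcome Tibble with `sample_id` and a logical `outcome` column, or
#'   a named logical vector.
#' @param plan A `fold_plan`.
#' @param c_reg Inverse regularization strength.
#' @return An `ir_binary_experiment`: `per_fold` (fold, auc, n_test), `rocs`
#'   (list of `ir_roc`), `auc_mean`, `auc_sd`.
#' @export
run_binary_experiment <- function(features, outcome, plan, c_reg = 1) {
  if (is.data.frame(outcome)) {
    y <- setNames(as.logical(outcome$outcome), outcome$sample_id)
  } else {
    y <- as.logical(outcome)
    names(y) <- names(outcome)
  }
  known <- names(y)[!is.na(y)]
  rows <- list()
  rocs <- list()
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    tr <- intersect(f$train, known)
    te <- intersect(f$test, known)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      warn(sprintf("fold %d skipped: a class is absent", i))
      next
    }
    fit <- fit_binary(subset_rows(features, tr), y[tr], c_reg = c_reg)
    sc <- predict(fit, subset_rows(features, te))
    r <- roc_auc(y[te], sc)
    rows[[length(rows) + 1]] <- tibble(fold = i, auc = r$auc, n_test = length(te))
    rocs[[length(rocs) + 1]] <- r
  }
  if (length(rows) == 0) abort("no usable folds")
  per_fold <- bind_rows(rows)
  structure(
    list(
      per_fold = per_fold, rocs = rocs,
      auc_mean = mean(per_fold$auc), auc_sd = sd(per_fold$auc),
      regime = plan$regime, c_reg = c_reg
    ),
    class = "ir_binary_experiment"
  )
}

#' @export
print.ir_binary_experiment <- function(x, ...) {
  cat(sprintf(
    "<ir_binary_experiment> regime = %s, %d folds, AUC = %.3f +/- %.3f\n",
    x$regime, nrow(x$per_fold), x$auc_mean, x$auc_sd
  ))
  invisible(x)
}

#' Pair-matched case-control cohort construction
#'
#' Matches each case to a control of the same sex and similar age and BMI, to
#' strip anthropometric contributions from a case-control contrast. Matching
#' is greedy nearest-neighbor without replacement on the Euclidean distance
#' over standardized covariates, with sex strata processed in order of
#' control scarcity (fewest controls per case first). Cases with no remaining
#' sex-compatible control are reported unmatched.
#'
#' @param cases,controls Tibbles with `sample_id`, `sex` and the matching
#'   covariates.
#' @param covariates Numeric covariates to match on (standardized over the
#'   pooled input).
#' @param caliper Optional maximum standardized distance for a valid pair.
#' @return A `matched_cohort`: `pairs` tibble (`case_id`, `control_id`,
#'   `distance`), `unmatched` case ids, `covariates`.
#' @export
pair_match <- function(cases, controls, covariates = c("age", "bmi"),
                       caliper = NULL) {
  ca <- as_tibble(cases)
  co <- as_tibble(controls)
  if (nrow(co) == 0) abort("`controls` is empty")
  pooled <- bind_rows(ca[, covariates], co[, covariates])
  mu <- vapply(pooled, mean, 1)
  sg <- vapply(pooled, sd, 1)
  sg[sg == 0 | is.na(sg)] <- 1
  std <- function(df) {
    sweep(sweep(as.matrix(df[, covariates]), 2, mu), 2, sg, `/`)
  }
  Xa <- std(ca)
  Xo <- std(co)
  used <- rep(FALSE, nrow(co))
  pairs <- list()
  unmatched <- character(0)

  scarcity <- vapply(unique(ca$sex), function(s) {
    sum(co$sex == s) / max(sum(ca$sex == s), 1)
  }, 1)
  for (s in names(sort(scarcity))) {
    for (i in which(ca$sex == s)) {
      avail <- which(!used & co$sex == s)
      if (length(avail) == 0) {
        unmatched <- c(unmatched, ca$sample_id[i])
        next
      }
      d <- sqrt(colSums((t(Xo[avail, , drop = FALSE]) - Xa[i, ])^2))
      j <- avail[which.min(d)]
      if (!is.null(caliper) && min(d) > caliper) {
        unmatched <- c(unmatched, ca$sample_id[i])
        next
      }
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- tibble(
        case_id = ca$sample_id[i], control_id = co$sample_id[j],
        distance = min(d)
      )
    }
  }
  if (length(pairs) == 0) abort("no pairs could be formed")
  structure(
    list(
      pairs = bind_rows(pairs), unmatched = unmatched,
      covariates = covariates
    ),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "<matched_cohort> %d pairs (%d unmatched cases), matched on %s + exact sex\n",
    nrow(x$pairs), length(x$unmatched), toString(x$covariates)
  ))
  invisible(x)
}
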