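fake_samples <- function(n, prefix = "s") {
  tibble::tibble(
    sample_id = paste0(prefix, seq_len(n)),
    individual_id = paste0("I", seq_len(n))
  )
}

test_that("cv folds partition the samples into near-equal disjoint tests", {
  s <- fake_samples(100)
  plan <- make_cv_folds(s, k = 10, seed = 1)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_true(all(lengths(tests) == 10))
  expect_setequal(unlist(tests), s$sample_id)
  expect_equal(sum(lengths(tests)), 100)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), s$sample_id)
  }
  # deterministic given seed
  plan2 <- make_cv_folds(s, k = 10, seed = 1)
  expect_equal(plan$folds, plan2$folds)
  expect_error(make_cv_folds(fake_samples(5), k = 10), "more folds")
})

test_that("uneven n still yields fold sizes differing by at most one", {
  plan <- make_cv_folds(fake_samples(103), k = 10, seed = 2)
  sizes <- lengths(lapply(plan$folds, `[[`, "test"))
  expect_lte(diff(range(sizes)), 1)
  # stratified variant keeps the size guarantee
  s <- fake_samples(97)
  s$combo <- sample(rep(c("a", "b", "c"), length.out = 97))
  plan_s <- make_cv_folds(s, k = 7, seed = 3, strata = "combo")
  sizes_s <- lengths(lapply(plan_s$folds, `[[`, "test"))
  expect_lte(diff(range(sizes_s)), 1)
})

test_that("the independent plan holds out overlap individuals correctly", {
  co <- small_cohort()
  cl <- co$clinical
  s1 <- cl[cl$visit == 1, c("sample_id", "individual_id")]
  s2 <- cl[cl$visit == 2, c("sample_id", "individual_id")]
  plan <- make_independent_plan(s1, s2, k = 10, seed = 4)
  overlap <- intersect(s1$individual_id, s2$individual_id)
  test_inds <- lapply(plan$folds, function(f) unique(plan$individual[f$test]))
  # the k test groups partition the overlap pool
  expect_setequal(unlist(test_inds), overlap)
  expect_equal(sum(lengths(test_inds)), length(overlap))
  for (f in plan$folds) {
    # all test samples are visit-2, all train samples visit-1
    expect_true(all(f$test %in% s2$sample_id))
    expect_true(all(f$train %in% s1$sample_id))
    # bookkeeping: train excludes exactly the held-out individuals' set-1 samples
    held <- unique(plan$individual[f$test])
    expect_equal(length(f$train), nrow(s1) - sum(s1$individual_id %in% held))
    expect_length(intersect(plan$individual[f$train], plan$individual[f$test]), 0)
  }
  d1 <- tibble::tibble(sample_id = paste0("a", 1:5), individual_id = paste0("I", 1:5))
  d2 <- tibble::tibble(sample_id = paste0("b", 1:5), individual_id = paste0("J", 1:5))
  expect_error(make_independent_plan(d1, d2, k = 2), "no overlapping individuals")
})

test_that("a 2015-individual overlap splits into groups of 201 or 202", {
  n <- 2500
  s1 <- tibble::tibble(
    sample_id = paste0("a", 1:n),
    individual_id = paste0("I", 1:n)
  )
  s2 <- tibble::tibble(
    sample_id = paste0("b", 1:2015),
    individual_id = paste0("I", 1:2015)
  )
  plan <- make_independent_plan(s1, s2, k = 10, seed = 1)
  sizes <- sort(lengths(lapply(plan$folds, `[[`, "test")))
  expect_true(all(sizes %in% c(201, 202)))
  expect_equal(sum(sizes), 2015)
})

test_that("every plan passes the subject-leakage audit across random configs", {
  withr::with_seed(77, {
    for (i in 1:50) {
      n1 <- sample(30:80, 1)
      n2 <- sample(20:60, 1)
      nov <- sample(5:min(n1, n2), 1)
      ind <- paste0("I", seq_len(n1 + n2 - nov))
      s1 <- tibble::tibble(
        sample_id = paste0("a", 1:n1),
        individual_id = ind[1:n1]
      )
      s2 <- tibble::tibble(
        sample_id = paste0("b", 1:n2),
        individual_id = ind[c(seq_len(nov), n1 + seq_len(n2 - nov))]
      )
      k <- sample(2:5, 1)
      for (plan in list(
        make_cv_folds(s1, k = k, seed = i),
        make_independent_plan(s1, s2, k = min(k, nov), seed = i)
      )) {
        for (f in plan$folds) {
          expect_length(
            intersect(plan$individual[f$train], plan$individual[f$test]), 0
          )
        }
      }
    }
  })
})

test_that("multilabel experiments score only unseen test samples", {
  co <- small_cohort()
  feat <- analyte_features(co, cohort_set(co, 1))
  lab <- co$labels
  cl <- co$clinical[co$clinical$sample_id %in% feat$sample_id, ]
  plan <- make_cv_folds(cl[, c("sample_id", "individual_id")], k = 5, seed = 6)
  ex <- run_multilabel_experiment(feat, lab, plan)
  known <- lab$sample_id[!lab$unknown]
  expected_n <- vapply(
    plan$folds,
    function(f) length(intersect(f$test, known)), 1L
  )
  expect_equal(ex$per_fold$n_samples, expected_n)
  expect_equal(nrow(ex$per_fold), 5)
  expect_true(all(ex$summary$sd >= 0))
})

test_that("perfectly determined labels give exact-match ratio 1", {
  withr::with_seed(11, {
    n <- 120
    x <- rnorm(n)
    feat <- tibble::tibble(sample_id = paste0("s", 1:n), f1 = x, f2 = rnorm(n))
    lab <- tibble::tibble(
      sample_id = feat$sample_id,
      A = x > 1, B = x < -1, C = abs(x) <= 1
    )
    samples <- tibble::tibble(sample_id = feat$sample_id, individual_id = feat$sample_id)
    plan <- make_cv_folds(samples, k = 4, seed = 2)
    ex <- run_multilabel_experiment(feat, lab, plan, c_reg = 1e4)
    expect_gte(mean(ex$per_fold$exact_match_ratio), 0.95)
  })
})

test_that("shuffled labels fall to the chance benchmark", {
  co <- small_cohort()
  feat <- analyte_features(co)
  lab <- known_labels(co, feat$sample_id)
  feat <- feat[match(lab$sample_id, feat$sample_id), ]
  shuffled <- lab
  withr::with_seed(9, {
    idx <- sample(nrow(shuffled))
    shuffled[, phenotype_labels()] <- shuffled[idx, phenotype_labels()]
  })
  samples <- tibble::tibble(sample_id = feat$sample_id, individual_id = feat$sample_id)
  plan <- make_cv_folds(samples, k = 5, seed = 3)
  ex <- run_multilabel_experiment(feat, shuffled, plan)
  bm <- chance_benchmark(lab, n_draws = 2e4, seed = 5)
  # a model trained on shuffled labels can at best learn the label base
  # rates, so it is sandwiched between the stochastic chance level and the
  # best constant prediction
  m <- as.matrix(lab[, phenotype_labels()])
  key <- apply(m, 1, paste, collapse = "")
  p_mode <- max(table(key)) / length(key)
  q <- colMeans(m)
  best_const_hl <- 1 - mean(pmin(q, 1 - q))
  emr <- mean(ex$per_fold$exact_match_ratio)
  expect_gte(emr, bm$expected$exact_match_ratio - 0.05)
  expect_lte(emr, p_mode + 0.05)
  hl <- mean(ex$per_fold$one_minus_hamming_loss)
  expect_gte(hl, bm$expected$one_minus_hamming_loss - 0.05)
  expect_lte(hl, best_const_hl + 0.05)
})

test_that("binary experiments recover separable outcomes and chance nulls", {
  withr::with_seed(14, {
    n <- 150
    x <- rnorm(n)
    feat <- tibble::tibble(sample_id = paste0("s", 1:n), f1 = x, f2 = rnorm(n))
    samples <- tibble::tibble(sample_id = feat$sample_id, individual_id = feat$sample_id)
    plan <- make_cv_folds(samples, k = 5, seed = 1)
    sep <- run_binary_experiment(feat, tibble::tibble(
      sample_id = feat$sample_id, outcome = x > 0
    ), plan)
    expect_gte(sep$auc_mean, 0.95)
    null <- run_binary_experiment(feat, tibble::tibble(
      sample_id = feat$sample_id, outcome = sample(x > 0)
    ), plan)
    expect_lt(abs(null$auc_mean - 0.5), 0.12)
    expect_true(all(sep$per_fold$auc >= 0 & sep$per_fold$auc <= 1))
    expect_gte(sep$auc_sd, 0)
  })
})

test_that("set-independent validation does not beat within-set cross-validation", {
  co <- accept_cohort()
  pp <- accept_fingerprints()
  cl <- co$clinical
  s1 <- cl[cl$visit == 1, c("sample_id", "individual_id")]
  s2 <- cl[cl$visit == 2, c("sample_id", "individual_id")]
  ex_cv <- run_multilabel_experiment(
    pp, co$labels, make_cv_folds(s1, k = 10, seed = 2, regime = "cv_set1")
  )
  ex_ind <- run_multilabel_experiment(
    pp, co$labels, make_independent_plan(s1, s2, k = 10, seed = 2)
  )
  expect_lte(
    mean(ex_ind$per_fold$exact_match_ratio),
    mean(ex_cv$per_fold$exact_match_ratio) + 0.01
  )
})

test_that("pair matching is exact on sex, greedy on distance, without replacement", {
  cases <- tibble::tibble(
    sample_id = c("c1", "c2"), sex = "male", age = c(50, 60), bmi = c(25, 30)
  )
  controls <- tibble::tibble(
    sample_id = c("k1", "k2", "k3"), sex = c("male", "male", "female"),
    age = c(50, 70, 50), bmi = c(25, 35, 25)
  )
  mc <- pair_match(cases, controls)
  expect_equal(nrow(mc$pairs), 2)
  # identical covariates give a zero-distance pair
  expect_equal(mc$pairs$distance[mc$pairs$case_id == "c1"], 0)
  expect_false("k3" %in% mc$pairs$control_id) # sex mismatch never used
  # 2 cases, 1 compatible control -> 1 pair + 1 unmatched
  mc2 <- pair_match(cases, controls[1, ])
  expect_equal(nrow(mc2$pairs), 1)
  expect_length(mc2$unmatched, 1)
  expect_error(pair_match(cases, controls[0, ]), "empty")
})

test_that("matching shrinks the case-control age gap on confounded data", {
  withr::with_seed(123, {
    n <- 150
    cases <- tibble::tibble(
      sample_id = paste0("c", 1:n), sex = sample(c("male", "female"), n, TRUE),
      age = rnorm(n, 65, 8), bmi = rnorm(n, 29, 3)
    )
    controls <- tibble::tibble(
      sample_id = paste0("k", 1:(3 * n)), sex = sample(c("male", "female"), 3 * n, TRUE),
      age = rnorm(3 * n, 50, 10), bmi = rnorm(3 * n, 26, 3)
    )
    mc <- pair_match(cases, controls)
    matched_gap <- abs(
      mean(cases$age[match(mc$pairs$case_id, cases$sample_id)]) -
        mean(controls$age[match(mc$pairs$control_id, controls$sample_id)])
    )
    raw_gap <- abs(mean(cases$age) - mean(controls$age))
    expect_lt(matched_gap, raw_gap)
  })
})
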