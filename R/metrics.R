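#' Multilabel classification metrics
#'
#' The three metrics used to judge multilabel phenotype predictions, each on
#' \code{[0, 1]} with higher = better:
#' * **exact match ratio** -- fraction of samples whose whole predicted label
#'   vector equals the truth: `(1/n) sum_i I(y_i == yhat_i)`; strict, partial
#'   credit is none.
#' * **Hamming score** (Jaccard similarity) -- per sample, the number of
#'   positive labels shared by prediction and truth over the number of labels
#'   positive in either; averaged over samples. True negatives earn nothing;
#'   false positives are penalized.
#' * **1 - Hamming loss** -- one minus the fraction of discordant label cells
#'   over all samples and labels.
#'
#' Inputs may be labels tibbles (logical phenotype columns; `sample_id` /
#' `unknown` columns ignored) or logical matrices of identical shape.
#'
#' @param truth,estimate True and predicted label sets.
#' @return A single number; `multilabel_score()` returns a one-row tibble
#'   with all three plus `n_samples`, `n_labels`.
#' @examples
#' y <- rbind(c(TRUE, FALSE), c(FALSE, TRUE))
#' exact_match_ratio(y, y) # 1
#' hamming_score(rbind(c(TRUE, FALSE)), rbind(c(TRUE, TRUE))) # 0.5
#' @export
exact_match_ratio <- function(truth, estimate) {
  m <- check_pair(truth, estimate)
  mean(rowSums(m$y != m$yhat) == 0)
}

#' @rdname exact_match_ratio
#' @export
hamming_score <- function(truth, estimate) {
  m <- check_pair(truth, estimate)
  inter <- rowSums(m$y & m$yhat)
  union <- rowSums(m$y | m$yhat)
  if (any(union == 0)) {
    warn("samples with no positive label in truth or prediction score 1 by convention")
  }
  mean(ifelse(union == 0, 1, inter / union))
}

#' @rdname exact_match_ratio
#' @export
one_minus_hamming_loss <- function(truth, estimate) {
  m <- check_pair(truth, estimate)
  1 - mean(m$y != m$yhat)
}

#' @rdname exact_match_ratio
#' @export
multilabel_score <- function(truth, estimate) {
  m <- check_pair(truth, estimate)
  tibble(
    exact_match_ratio = exact_match_ratio(m$y, m$yhat),
    hamming_score = suppressWarnings(hamming_score(m$y, m$yhat)),
    one_minus_hamming_loss = one_minus_hamming_loss(m$y, m$yhat),
    n_samples = nrow(m$y), n_labels = ncol(m$y)
  )
}

check_pair <- function(truth, estimate) {
  y <- label_matrix(truth)
  yhat <- label_matrix(estimate)
  if (!all(dim(y) == dim(yhat))) abort("`truth` and `estimate` shapes differ")
  if (nrow(y) == 0) abort("no samples")
  if (anyNA(y) || anyNA(yhat)) abort("labels contain NA; drop unknown samples first")
  list(y = y, yhat = yhat)
}

#' ROC curve and area under the curve
#'
#' Builds the ROC curve over all distinct score thresholds (tied scores
#' grouped into one operating point) and integrates it by the trapezoid rule.
#' The resulting AUC equals the tie-corrected Mann-Whitney concordance
#' probability: the probability that a random positive outscores a random
#' negative, counting ties as 1/2.
#'
#' @param truth Logical (or 0/1) vector.
#' @param score Numeric classifier scores, higher = more positive.
#' @return An `ir_roc` list: `curve` tibble (`threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(truth, score) {
  y <- as.logical(truth)
  if (length(y) != length(score)) abort("length mismatch")
  if (anyNA(y) || anyNA(score)) abort("NA in truth or score")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both classes must be present")
  }
  o <- order(score, decreasing = TRUE)
  ys <- y[o]
  ss <- score[o]
  last <- c(diff(ss) != 0, TRUE) # last index of each tied score group
  tp <- cumsum(ys)[last]
  fp <- cumsum(!ys)[last]
  curve <- tibble(
    threshold = c(Inf, ss[last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc, n_positive = n_pos, n_negative = n_neg),
    class = "ir_roc"
  )
}

#' @export
print.ir_roc <- function(x, ...) {
  cat(sprintf(
    "<ir_roc> AUC = %.3f (%d positives, %d negatives)\n",
    x$auc, x$n_positive, x$n_negative
  ))
  invisible(x)
}

#' Stochastic chance benchmark for multilabel metrics
#'
#' What would the three multilabel metrics be for a "classifier" that knows
#' the population's label-combination distribution but cannot link spectra to
#' individuals? Two independent samples of `n_draws` label vectors are drawn
#' from the empirical distribution over the observed feasible combinations
#' and scored against each other. Alongside the sampled values, analytic
#' expectations are reported: expected exact match ratio `sum_k p_k^2` over
#' combination probabilities, expected Hamming score
#' `sum_k sum_l p_k p_l J(k, l)` (J = Jaccard similarity of the two
#' combinations), and expected 1 - Hamming loss
#' `1 - (1/L) sum_j 2 q_j (1 - q_j)` with `q_j` the label marginals. Monte
#' Carlo standard errors accompany the sampled values.
#'
#' @param labels Labels tibble (or logical matrix) defining the population
#'   distribution; rows with `NA` are dropped.
#' @param n_draws Vectors per sample (default 1e5).
#' @param seed Seed for the draws.
#' @return A `chance_benchmark` list with `sampled` (one-row tibble),
#'   `expected` (one-row tibble), `mc_se`, `n_draws`, `seed`.
#' @export
chance_benchmark <- function(labels, n_draws = 1e5, seed = 1L) {
  y <- label_matrix(labels)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  if (nrow(y) == 0) abort("no complete label rows")
  L <- ncol(y)
  key <- apply(matrix(as.integer(y), nrow(y)), 1, paste, collapse = "")
  tab <- table(key)
  p <- as.numeric(tab) / length(key)
  combos <- do.call(rbind, lapply(names(tab), function(k) {
    as.integer(strsplit(k, "")[[1]]) == 1
  }))
  q <- colSums(combos * p)

  # analytic expectations
  emr_exp <- sum(p^2)
  inter <- combos %*% t(combos)
  union <- outer(rowSums(combos), rowSums(combos), `+`) - inter
  J <- ifelse(union == 0, 1, inter / union)
  hs_exp <- as.numeric(t(p) %*% J %*% p)
  hl_exp <- 1 - mean(2 * q * (1 - q))

  draws <- with_seed(seed, list(
    a = sample.int(nrow(combos), n_draws, replace = TRUE, prob = p),
    b = sample.int(nrow(combos), n_draws, replace = TRUE, prob = p)
  ))
  ya <- combos[draws$a, , drop = FALSE]
  yb <- combos[draws$b, , drop = FALSE]
  sampled <- suppressWarnings(multilabel_score(ya, yb))

  per_emr <- rowSums(ya != yb) == 0
  u <- rowSums(ya | yb)
  per_hs <- ifelse(u == 0, 1, rowSums(ya & yb) / u)
  per_hl <- 1 - rowMeans(ya != yb)
  mc_se <- tibble(
    exact_match_ratio = sd(per_emr) / sqrt(n_draws),
    hamming_score = sd(per_hs) / sqrt(n_draws),
    one_minus_hamming_loss = sd(per_hl) / sqrt(n_draws)
  )

  structure(
    list(
      sampled = sampled[, 1:3],
      expected = tibble(
        exact_match_ratio = emr_exp, hamming_score = hs_exp,
        one_minus_hamming_loss = hl_exp
      ),
      mc_se = mc_se, n_draws = n_draws, seed = seed,
      combination_probabilities = tibble(combination = names(tab), p = p)
    ),
    class = "chance_benchmark"
  )
}

#' @export
print.chance_benchmark <- function(x, ...) {
  cat(sprintf(
    "<chance_benchmark> n_draws = %s, seed = %d\n  sampled : EMR %.4f, Hamming score %.4f, 1-HL %.4f\n  expected: EMR %.4f, Hamming score %.4f, 1-HL %.4f\n",
    format(x$n_draws, big.mark = ","), x$seed,
    x$sampled$exact_match_ratio, x$sampled$hamming_score,
    x$sampled$one_minus_hamming_loss,
    x$expected$exact_match_ratio, x$expected$hamming_score,
    x$expected$one_minus_hamming_loss
  ))
  invisible(x)
}
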