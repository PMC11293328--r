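# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so that seeds are explicit and local.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, salt) {
  if (is.null(seed)) {
    return(NULL)
  }
  s <- sum(utf8ToInt(as.character(salt))) %% 10000L
  (as.integer(seed) %% 2000000000L + s * 1009L) %% 2147483647L
}

check_scalar_number <- function(x, arg, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", arg, min))
  }
  invisible(x)
}

# logical matrix from a labels tibble (or matrix); keeps column order
label_matrix <- function(labels, label_cols = NULL) {
  if (is.matrix(labels)) {
    m <- labels
    storage.mode(m) <- "logical"
    return(m)
  }
  lab <- as_tibble(labels)
  if (is.null(label_cols)) {
    label_cols <- setdiff(names(lab), c("sample_id", "unknown"))
  }
  m <- as.matrix(lab[, label_cols, drop = FALSE])
  storage.mode(m) <- "logical"
  if ("sample_id" %in% names(lab)) rownames(m) <- lab$sample_id
  m
}

# numeric design matrix from a features tibble (sample_id + numeric columns)
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    m <- features
    storage.mode(m) <- "double"
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    return(m)
  }
  df <- as_tibble(features)
  cols <- setdiff(names(df), "sample_id")
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(df)) rownames(m) <- df$sample_id
  if (!all(is.finite(m))) abort("feature matrix contains non-finite values")
  m
}

# population (n-denominator) standard deviation per column: invariant under
# row duplication, which keeps ridge contracts exact
col_sd_pop <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2, mu)^2))
}
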