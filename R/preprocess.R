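#' Water-background correction of absorbance spectra
#'
#' A plasma sample containing less water than the pure-water reference used
#' for absorbance reconstruction shows negative absorption. The correction
#' adds a scaled copy of the water reference to each spectrum,
#' `corrected = raw + c * W`, with the coefficient `c` chosen to minimize the
#' L2 norm of the first derivative of the corrected spectrum inside the
#' biologically silent 2000-2300 cm^-1 window. With first-order finite
#' differences the objective is quadratic in `c` and the minimizer has the
#' closed form `c = -<A', W'> / <W', W'>` over the window, so the recovered
#' coefficient is positive for a water deficit.
#'
#' @param spectra Spectra tibble (one or more rows).
#' @param water One-row spectra tibble on the same grid.
#' @param window Length-2 wavenumber window (closed interval) over which the
#'   derivative is minimized.
#' @return A `water_correction` list: `spectra` (corrected, same shape),
#'   `coefficients` tibble (`sample_id`, `coefficient`, `objective_before`,
#'   `objective_after`).
#' @examples
#' w <- water_reference_spectrum()
#' raw <- as_spectra(-0.3 * spectra_matrix(w), sample_id = "s1")
#' correct_water(raw, w)$coefficients$coefficient # ~0.3
#' @export
correct_water <- function(spectra, water, window = c(2000, 2300)) {
  check_spectra(spectra)
  grid <- spectra_grid(spectra)
  wgrid <- spectra_grid(water)
  if (length(grid) != length(wgrid) || any(grid != wgrid)) {
    abort("`spectra` and `water` must share one wavenumber grid")
  }
  h <- grid_spacing(grid)
  in_win <- which(grid >= window[1] & grid <= window[2])
  if (length(in_win) < 3) abort("derivative window is empty on this grid")

  A <- spectra_matrix(spectra)
  w <- as.numeric(spectra_matrix(water)[1, ])
  # first-order finite differences restricted to the window
  dA <- t(diff(t(A[, in_win, drop = FALSE]))) / h
  dw <- diff(w[in_win]) / h
  ww <- sum(dw * dw)
  if (ww <= .Machine$double.eps) {
    abort("degenerate water reference: zero derivative energy in the window")
  }
  cc <- -as.numeric(dA %*% dw) / ww
  obj_before <- sqrt(rowSums(dA^2))
  dA_after <- dA + cc %o% dw
  obj_after <- sqrt(rowSums(dA_after^2))

  corrected <- A + cc %o% w
  structure(
    list(
      spectra = as_spectra(corrected, sample_id = spectra$sample_id),
      coefficients = tibble(
        sample_id = spectra$sample_id, coefficient = cc,
        objective_before = obj_before, objective_after = obj_after
      ),
      window = window
    ),
    class = "water_correction"
  )
}

#' @export
print.water_correction <- function(x, ...) {
  cat(sprintf(
    "<water_correction> %d spectra, window %g-%g cm^-1, median c = %.4f\n",
    nrow(x$coefficients), x$window[1], x$window[2],
    median(x$coefficients$coefficient)
  ))
  invisible(x)
}

#' Truncate spectra and mask the silent region
#'
#' Restricts spectra to 1000-3000 cm^-1 and removes 1800-2800 cm^-1, where
#' liquid plasma shows no biologically relevant absorbance. Both retained
#' intervals are closed: points at exactly 1800 or 2800 cm^-1 are kept.
#'
#' @param spectra Spectra tibble whose grid covers 1000-3000 cm^-1.
#' @param keep List of closed retained intervals.
#' @return Spectra tibble on the retained grid (order preserved); idempotent.
#' @export
truncate_and_mask <- function(spectra,
                              keep = list(c(1000, 1800), c(2800, 3000))) {
  check_spectra(spectra)
  grid <- spectra_grid(spectra)
  lo <- min(vapply(keep, `[`, 1, 1))
  hi <- max(vapply(keep, `[`, 1, 2))
  if (min(grid) > lo || max(grid) < hi) {
    abort(sprintf("grid does not cover the retained range %g-%g cm^-1", lo, hi))
  }
  retain <- Reduce(`|`, lapply(keep, function(iv) grid >= iv[1] & grid <= iv[2]))
  spectra[, c(TRUE, retain)]
}

#' L2 (Euclidean) normalization of spectra
#'
#' Treats each spectrum as a vector and scales it to unit Euclidean norm,
#' correcting multiplicative differences from total molecular concentration,
#' sample handling and effective path length.
#'
#' @param spectra Spectra tibble.
#' @return Spectra tibble with every row at unit L2 norm.
#' @export
l2_normalize <- function(spectra) {
  check_spectra(spectra)
  A <- spectra_matrix(spectra)
  nrm <- sqrt(rowSums(A^2))
  if (any(nrm <= .Machine$double.eps)) {
    abort("cannot L2-normalize a zero spectrum")
  }
  as_spectra(A / nrm, sample_id = spectra$sample_id)
}

#' Full fingerprint preprocessing pipeline
#'
#' Composition of the three preprocessing steps applied to every spectrum:
#' water-background correction ([correct_water()]), truncation and masking
#' ([truncate_and_mask()]), and -- unless switched off -- L2 normalization
#' ([l2_normalize()]). Row order and sample identities are preserved, and the
#' per-sample water coefficient is recorded.
#'
#' @param spectra Raw spectra tibble.
#' @param water One-row water-reference spectra tibble on the same grid.
#' @param normalize Apply the final L2 normalization (default `TRUE`).
#' @param window Water-correction derivative window.
#' @return An `ir_preprocessed` list: `spectra` (the analysis-ready
#'   fingerprints), `coefficients` (per-sample water correction diagnostics),
#'   `normalized`.
#' @export
preprocess_spectra <- function(spectra, water, normalize = TRUE,
                               window = c(2000, 2300)) {
  wc <- correct_water(spectra, water, window = window)
  out <- truncate_and_mask(wc$spectra)
  if (normalize) out <- l2_normalize(out)
  structure(
    list(spectra = out, coefficients = wc$coefficients, normalized = normalize),
    class = "ir_preprocessed"
  )
}

#' @export
print.ir_preprocessed <- function(x, ...) {
  cat(sprintf(
    "<ir_preprocessed> %d fingerprints on %d retained wavenumbers (%snormalized)\n",
    nrow(x$spectra), length(spectra_grid(x$spectra)),
    if (x$normalized) "L2-" else "not "
  ))
  invisible(x)
}

#' Phenotype differential spectral signature
#'
#' Difference between the mean fingerprint of samples positive for a
#' phenotype and the mean fingerprint of the negative samples, together with
#' the per-wavenumber standard deviation (unbiased, n-1 denominator) of the
#' negative group -- the spectral signature of a phenotype against its
#' complement.
#'
#' @param spectra Preprocessed spectra tibble.
#' @param labels Labels tibble with `sample_id` and the phenotype column;
#'   `NA`-labeled samples are dropped.
#' @param phenotype Name of the label column to contrast.
#' @return A `differential_signature` tibble: `wavenumber`, `delta`,
#'   `negative_sd`, with the phenotype recorded as an attribute.
#' @export
differential_signature <- function(spectra, labels, phenotype) {
  check_spectra(spectra)
  lab <- as_tibble(labels)
  if (!phenotype %in% names(lab)) {
    abort(sprintf("no label column `%s`", phenotype))
  }
  lab <- lab[!is.na(lab[[phenotype]]), c("sample_id", phenotype)]
  df <- inner_join(spectra["sample_id"], lab, by = "sample_id")
  pos_ids <- df$sample_id[df[[phenotype]]]
  neg_ids <- df$sample_id[!df[[phenotype]]]
  if (length(pos_ids) == 0 || length(neg_ids) == 0) {
    abort("both the positive and negative group must be nonempty")
  }
  A <- spectra_matrix(spectra)
  pos <- A[pos_ids, , drop = FALSE]
  neg <- A[neg_ids, , drop = FALSE]
  out <- tibble(
    wavenumber = spectra_grid(spectra),
    delta = unname(colMeans(pos) - colMeans(neg)),
    negative_sd = unname(apply(neg, 2, sd))
  )
  structure(out,
    class = c("differential_signature", class(out)),
    phenotype = phenotype, n_positive = length(pos_ids),
    n_negative = length(neg_ids)
  )
}
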