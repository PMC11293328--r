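#' Gaussian band library for the Beer-Lambert forward model
#'
#' The synthetic cohort generator builds plasma absorbance spectra as a
#' superposition of per-analyte molar absorptivity profiles, each a sum of
#' Gaussian bands placed at the vibrational assignments known for that
#' constituent class: glucose ring modes in 1000-1180 cm^-1, ester C=O
#' stretches of fatty acids in 1725-1750 cm^-1, lipid CH2/CH3 stretches in
#' 2800-2975 cm^-1, carbohydrate C-O stretches in 1100-1275 cm^-1 and the
#' protein amide I/II bands in 1550-1700 cm^-1. Amplitudes are in absorbance
#' units (AU) per unit of the analyte's clinical concentration unit, scaled so
#' a typical plasma composition yields a protein-dominated spectrum of a few
#' tenths of an AU.
#'
#' @param amplitude_scale Global multiplier on all band amplitudes.
#' @return A `band_library` object: a named list with one tibble of bands
#'   (`center`, `sigma`, `amplitude`) per analyte.
#' @seealso [water_reference_spectrum()], [synthesize_spectra()]
#' @export
band_library <- function(amplitude_scale = 1) {
  bands <- function(center, sigma, amplitude) {
    tibble(center = center, sigma = sigma, amplitude = amplitude * amplitude_scale)
  }
  lib <- list(
    # glucose ~95 mg/dL typical -> peak ~0.055 AU
    fasting_glucose = bands(
      c(1035, 1080, 1107, 1150), c(14, 16, 12, 15),
      c(4.8, 8.7, 5.1, 3.9) * 1e-4
    ),
    # HbA1c (%) - glycation carbohydrate signature plus protein backbone
    hba1c = bands(
      c(1045, 1085, 1552, 1656), c(15, 15, 22, 24),
      c(2.0, 2.2, 1.2, 1.4) * 1e-3
    ),
    # cholesterol-bearing lipoproteins: ester C=O + CH stretches
    total_cholesterol = bands(
      c(1740, 2852, 2930), c(10, 14, 16),
      c(1.8, 2.2, 2.6) * 1e-3
    ),
    ldl = bands(
      c(1738, 1170, 2851, 2928, 2960), c(10, 20, 13, 15, 11),
      c(6.0, 2.2, 6.5, 8.0, 4.0) * 1e-3
    ),
    hdl = bands(
      c(1742, 2854, 2934, 1654), c(10, 13, 15, 22),
      c(5.0, 5.5, 6.5, 3.5) * 1e-3
    ),
    # triglycerides ~120 mg/dL; strong ester + C-O-C carbohydrate-region bands
    triglycerides = bands(
      c(1744, 1160, 1240, 2853, 2925, 2958), c(9, 22, 20, 13, 16, 11),
      c(2.6, 0.9, 0.7, 2.0, 2.6, 1.3) * 1e-4
    ),
    # creatinine ~0.9 mg/dL
    creatinine = bands(
      c(1305, 1610, 1695), c(14, 16, 12),
      c(3.0, 3.8, 2.0) * 1e-2
    ),
    # albumin ~45 g/L dominates amide I/II
    albumin = bands(
      c(1656, 1552, 1310, 2935), c(26, 24, 30, 30),
      c(7.0, 4.6, 1.0, 1.4) * 1e-3
    ),
    # cell-count surrogates: weak plasma signatures
    leukocytes = bands(c(1650, 1085), c(25, 20), c(1.2, 0.8) * 1e-4),
    erythrocytes = bands(c(1582, 2870, 1655), c(18, 20, 24), c(10, 7, 8) * 1e-4),
    hematocrit = bands(c(1584, 2872, 1657), c(18, 20, 24), c(11, 7.5, 9) * 1e-3),
    platelets = bands(c(1648, 1240), c(24, 22), c(0.9, 0.5) * 1e-5)
  )
  structure(lib, class = "band_library")
}

#' @export
print.band_library <- function(x, ...) {
  cat("<band_library> ", length(x), " analytes, ",
    sum(vapply(x, nrow, 1L)), " Gaussian bands\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate a set of Gaussian bands on a wavenumber grid
#'
#' @param bands Tibble with `center`, `sigma`, `amplitude` columns.
#' @param grid Numeric wavenumber axis (cm^-1).
#' @return Numeric vector: absorptivity per unit concentration at each grid
#'   point.
#' @export
eval_bands <- function(bands, grid) {
  out <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-((grid - bands$center[i]) / bands$sigma[i])^2 / 2)
  }
  out
}

#' Pure-water reference spectrum
#'
#' A smooth stand-in for the mid-IR absorbance of liquid water on the
#' measurement grid: the HOH bending band near 1640 cm^-1, the weak
#' association (combination) band near 2130 cm^-1 -- which gives the
#' water-correction objective its leverage inside the 2000-2300 cm^-1
#' window -- and the low-frequency wing of the OH stretch rising towards
#' 3050 cm^-1.
#'
#' @param grid Wavenumber axis (cm^-1); default the generator's 950-3050 grid
#'   at 2 cm^-1.
#' @return A one-row spectra tibble with `sample_id = "water_reference"`.
#' @export
water_reference_spectrum <- function(grid = seq(950, 3050, by = 2)) {
  w <- 0.05 +
    1.00 * exp(-((grid - 1640) / 60)^2 / 2) +
    0.10 * exp(-((grid - 2130) / 130)^2 / 2) +
    2.00 * exp(-((grid - 3380) / 210)^2 / 2)
  m <- matrix(w, nrow = 1, dimnames = list("water_reference", format_wavenumber(grid)))
  as_spectra(m)
}
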