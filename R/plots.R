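#' @method autoplot ir_roc
#' @export
autoplot.ir_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_path(color = "#1f6fb4", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot differential_signature
#' @export
autoplot.differential_signature <- function(object, ...) {
  ph <- attr(object, "phenotype")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = -.data$negative_sd, ymax = .data$negative_sd),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_hline(yintercept = 0, color = "grey50", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta), color = "#1f6fb4") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression(Wavenumber ~ (cm^-1)),
      y = "Mean difference (positive - negative)",
      title = sprintf("Differential spectral signature: %s", ph),
      subtitle = "Shaded band: SD of the negative group"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot correlation_map
#' @export
autoplot.correlation_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey50", linewidth = 0.3) +
    ggplot2::geom_line(color = "#b2182b") +
    ggplot2::scale_x_reverse() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(
      x = expression(Wavenumber ~ (cm^-1)), y = "Pearson r",
      title = sprintf("Spectral correlation map: %s", attr(object, "analyte"))
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot ir_calibration
#' @export
autoplot.ir_calibration <- function(object, ...) {
  ggplot2::ggplot(
    object$predictions,
    ggplot2::aes(x = .data$truth, y = .data$predicted)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "#b2182b") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, color = "#1f6fb4") +
    ggplot2::labs(
      x = "Clinically determined", y = "Predicted from fingerprint",
      title = sprintf(
        "%s: R² = %.2f ± %.2f, RMSE = %.3g ± %.2g",
        object$target, object$r_squared_mean, object$r_squared_sd,
        object$rmse_mean, object$rmse_sd
      )
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot ir_ml_experiment
#' @export
autoplot.ir_ml_experiment <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$metric, y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "#1f6fb4", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "Score",
      title = sprintf("Multilabel performance (%s, %s)", object$model, object$regime)
    ) +
    ggplot2::theme_minimal()
}

#' Plot preprocessed fingerprints
#'
#' Overlays (a subset of) preprocessed spectra; the masked 1800-2800 cm^-1
#' region appears as a gap.
#'
#' @param spectra Spectra tibble.
#' @param n_max Maximum number of spectra drawn.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, n_max = 50) {
  check_spectra(spectra)
  sp <- spectra[seq_len(min(nrow(spectra), n_max)), ]
  long <- tidyr::pivot_longer(sp, -"sample_id",
    names_to = "wavenumber", values_to = "absorbance"
  )
  long$wavenumber <- as.numeric(long$wavenumber)
  # break the line across the masked region
  long$segment <- ifelse(long$wavenumber <= 1800, "fingerprint", "CH stretch")
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$wavenumber, y = .data$absorbance,
      group = interaction(.data$sample_id, .data$segment)
    )
  ) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3, color = "#1f6fb4") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (AU)",
      title = "Preprocessed plasma fingerprints"
    ) +
    ggplot2::theme_minimal()
}
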