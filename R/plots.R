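#' Stacked quantile-segment plot of per-variable distributions
#'
#' Displays, for each variable, its 0-0.2-0.4-0.6-0.8-1 quantile segments
#' across datasets as a stacked bar, filled where the variable's mean
#' differs significantly from zero -- the standard display for distributions
#' of standardized regression weights, permutation importances or
#' per-dataset correlations.
#'
#' @param summary Tibble from [summarize_distribution()] (optionally with a
#'   `target` column for facetting).
#' @param ref Optional horizontal reference line (e.g. `1/36`, the
#'   equal-importance expectation for normalised importances).
#' @return A ggplot object.
#' @export
plot_quantile_segments <- function(summary, ref = NULL) {
  qs <- c("q0", "q20", "q40", "q60", "q80", "q100")
  long <- purrr::map_dfr(seq_len(5), function(i) {
    dplyr::mutate(
      summary[setdiff(names(summary), qs)],
      segment = qs[i],
      lo = summary[[qs[i]]],
      hi = summary[[qs[i + 1]]]
    )
  })
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$variable, ymin = .data$lo, ymax = .data$hi,
    alpha = .data$segment, fill = .data$significant
  )) +
    ggplot2::geom_linerange(linewidth = 3) +
    ggplot2::scale_alpha_manual(
      values = stats::setNames(seq(0.35, 1, length.out = 5), qs[1:5]),
      guide = "none"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey60"), na.value = "grey80"
    ) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if ("target" %in% names(summary)) {
    p <- p + ggplot2::facet_wrap(~target, ncol = 1, scales = "free_y")
  }
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = ref, colour = "red")
  }
  p
}

#' @describeIn ridge_fit Bar plot of standardized ridge weights.
#' @param object Fitted model.
#' @exportS3Method ggplot2::autoplot
autoplot.cyclemg_ridge <- function(object, ...) {
  d <- tidy(object)
  d$variable <- factor(d$variable, levels = d$variable)
  ggplot2::ggplot(d, ggplot2::aes(.data$variable, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "standardized weight",
      title = sprintf("Ridge weights (lambda = %g)", object$lambda)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn forest_fit Bar plot of permutation importances with the
#'   equal-importance reference line.
#' @param object Fitted model.
#' @exportS3Method ggplot2::autoplot
autoplot.cyclemg_forest <- function(object, ...) {
  d <- tidy(object)
  d$importance <- d$importance / sum(d$importance)
  d$variable <- factor(d$variable, levels = d$variable)
  ggplot2::ggplot(d, ggplot2::aes(.data$variable, .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 / nrow(d), colour = "red") +
    ggplot2::labs(x = NULL, y = "normalised OOB permutation importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot simulated physiological trajectories
#'
#' Latent load, lactate and oxygen-uptake curves with the sparse sampled
#' observations overlaid.
#'
#' @param truth A `metabolic_truth` from [simulate_metabolics()].
#' @return A ggplot object.
#' @export
plot_physio <- function(truth) {
  stopifnot(inherits(truth, "metabolic_truth"))
  latent <- truth$latent |>
    tidyr::pivot_longer(c("lactate", "vo2"), names_to = "kind")
  obs <- dplyr::bind_rows(
    dplyr::mutate(truth$lactate, kind = "lactate"),
    dplyr::mutate(truth$vo2, kind = "vo2")
  )
  ggplot2::ggplot(latent, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs, size = 0.6) +
    ggplot2::facet_wrap(~kind, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)",
      y = "lactate (mmol/L) / oxygen uptake (L/min)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the shrinkage-selection curve
#'
#' Raw and smoothed mean cross-validated R^2 against the integer shrinkage
#' grid, with the selected value marked.
#'
#' @param selection Result of [select_shrinkage()].
#' @return A ggplot object.
#' @export
plot_shrinkage_curve <- function(selection) {
  d <- selection$curve
  ggplot2::ggplot(d, ggplot2::aes(.data$lambda)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r2_raw), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$r2_smooth), colour = "red") +
    ggplot2::geom_vline(xintercept = selection$lambda, linetype = 2) +
    ggplot2::labs(
      x = expression(lambda), y = expression(mean ~ CV ~ R^2)
    ) +
    ggplot2::theme_minimal()
}
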