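#' Plot cohort repurposing percentages
#'
#' Diverging bars per cohort: on-label percentages extend left of zero and
#' off-label percentages right, faceted by evidence group and association,
#' the conventional display for additive on/off-label repurposing
#' summaries.
#'
#' @param object A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- object |>
    filter(.data$evidence_group %in% c("approved", "trials")) |>
    mutate(signed_pct = if_else(.data$label_scope == "on_label",
                                -.data$pct, .data$pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_pct, y = .data$cohort,
                                   fill = .data$label_scope)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$association),
                        ggplot2::vars(.data$evidence_group)) +
    ggplot2::scale_x_continuous(labels = function(x) abs(x)) +
    ggplot2::labs(
      x = "% of patients (on-label left, off-label right)", y = NULL,
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a TMB concordance scatter
#'
#' Per-sample TMB from the two platforms on log-friendly axes with the
#' high-TMB threshold marked; discordant samples (high on one side only)
#' are highlighted.
#'
#' @param object A `tmb_concordance` from [tmb_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmb_concordance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tmb_a, y = .data$tmb_b,
                                   colour = .data$discordant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = paste("TMB,", object$label_a),
      y = paste("TMB,", object$label_b),
      colour = "threshold-discordant",
      subtitle = sprintf("R = %.3f (%s), n = %d",
                         object$correlation_r, object$method, object$n_samples)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the platform comparison
#'
#' Percentage of patients with at least one actionable call per platform,
#' one line per evidence scope (approved only versus approved plus
#' trials), faceted by association.
#'
#' @param comparison Output of [platform_comparison()].
#' @return A ggplot object.
#' @export
plot_platform_comparison <- function(comparison) {
  df <- comparison |>
    mutate(platform = factor(.data$platform,
                             levels = c("WGS", "WES", "CPANEL", "HGP")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$platform, y = .data$pct,
                                   group = .data$evidence,
                                   colour = .data$evidence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$association)) +
    ggplot2::labs(x = NULL, y = "% patients with actionable call",
                  colour = "evidence scope") +
    ggplot2::theme_minimal()
}
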