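#' Scatter plot of the patient embedding
#'
#' The stage-2 embedding coloured by pattern, noise in grey — the package's
#' counterpart of the published patient-cluster scatter.
#'
#' @param fit A `pattern_discovery` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pattern_discovery <- function(fit, ...) {
  d <- fit$embedding
  d$pattern <- factor(ifelse(fit$assignment$pattern == NOISE_LABEL, "noise",
                             as.character(fit$assignment$pattern)))
  ggplot2::ggplot(d, ggplot2::aes(.data$u1, .data$u2, colour = .data$pattern)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(setNames(scales_hue(nlevels(d$pattern) - ("noise" %in% d$pattern)),
                          setdiff(levels(d$pattern), "noise")),
                 noise = "grey70")) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = "pattern") +
    ggplot2::theme_minimal()
}

# default ggplot hue palette without pulling in scales
scales_hue <- function(n) {
  if (n <= 0) return(character(0))
  hues <- seq(15, 375, length.out = n + 1)
  grDevices::hcl(h = hues[seq_len(n)], l = 65, c = 100)
}

#' Radar-style profile plot
#'
#' Per-pattern mean item scores as closed polygons over the 16 items (drawn
#' on a polar-style wrapped axis), one facet per pattern, optionally
#' overlaying exploration and validation cohorts.
#'
#' @param radar Long tibble from [export_radar()].
#' @return A ggplot.
#' @export
plot_radar <- function(radar) {
  radar$item <- factor(radar$item, levels = item_names())
  ggplot2::ggplot(radar, ggplot2::aes(.data$item, .data$mean_score,
                                      group = .data$cohort,
                                      colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~ .data$name) +
    ggplot2::ylim(0, 3) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}

#' Forest plot of association estimates
#'
#' Odds ratios (log scale, reference line at 1) or slopes (reference at 0)
#' with 95% confidence intervals, one row per exposure level, faceted by
#' outcome and timepoint.
#'
#' @param forest Forest tibble from [run_association_suite()].
#' @param effect `"OR"` or `"beta"` rows to show.
#' @return A ggplot.
#' @export
plot_forest <- function(forest, effect = c("OR", "beta")) {
  effect <- match.arg(effect)
  d <- forest[forest$effect_type == effect & !is.na(forest$estimate), ]
  d$label <- paste0(d$outcome, ifelse(d$timepoint == "", "", paste0(" @", d$timepoint)))
  ref <- if (effect == "OR") 1 else 0
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$exposure_level)) +
    ggplot2::geom_vline(xintercept = ref, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high), size = 0.3) +
    ggplot2::facet_wrap(~ .data$label, scales = "free_x") +
    ggplot2::labs(x = if (effect == "OR") "odds ratio (95% CI)" else "beta (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (effect == "OR") p <- p + ggplot2::scale_x_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
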