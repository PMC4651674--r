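#' @method autoplot spc_de
#' @export
autoplot.spc_de <- function(object, alpha = attr(object, "alpha") %||% 0.05, ...) {
  df <- tidy(object)
  df$direction <- factor(df$direction,
                         levels = c("increased", "unchanged", "decreased"))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ratio),
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(increased = "#d7301f",
                                            unchanged = "grey60",
                                            decreased = "#0570b0")) +
    ggplot2::labs(x = "log2 expression ratio (treatment/control)",
                  y = "-log10 p-value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot spc_r2
#' @export
autoplot.spc_r2 <- function(object, ...) {
  df <- tidy(object)
  df$pair <- paste(df$sample_1, df$sample_2, sep = " vs ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$r_squared,
                                   fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = glance(object)$mean_r_squared,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(R^2), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot binned property distributions for two populations
#'
#' Companion to [profile_distributions()]: side-by-side bars of per-bin
#' fractions for the focal and reference populations, e.g. identified
#' proteins versus the whole database, for pI or molecular weight.
#'
#' @param profile Tibble from [profile_distributions()].
#' @param xlab X-axis label (property name with units).
#' @return A ggplot object.
#' @export
plot_property_profile <- function(profile, xlab = "value") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                        fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = xlab, y = "fraction of proteins", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot target and decoy PSM score distributions
#'
#' Overlaid score histograms for target and decoy PSMs, the visual check
#' that the decoy score distribution tracks the incorrect-target
#' component.
#'
#' @param psms PSM tibble with `score` and `is_decoy`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(psms, bins = 60) {
  df <- psms %>%
    mutate(class = ifelse(.data$is_decoy, "decoy", "target"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(alpha = 0.55, position = "identity", bins = bins) +
    ggplot2::labs(x = "search score", y = "PSMs", fill = NULL) +
    ggplot2::theme_minimal()
}
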