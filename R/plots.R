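# ggplot2 views of the main result types; every plot function takes the
# tidy output of an analysis step and returns a ggplot object

region_boundaries <- function(bins_per_region = 20L) {
  c(bins_per_region, 2L * bins_per_region) + 0.5
}

#' Plot group mean reactivity along the metagene
#'
#' High- vs low-TE mean reactivity per bin, one panel per probing
#' condition, with the region boundaries marked.
#'
#' @param bin_summary A `te_bin_summary` from [summarize_bins()].
#' @return A ggplot object.
#' @export
plot_bin_reactivity <- function(bin_summary) {
  dat <- tidyr::pivot_longer(bin_summary, c("mean_high", "mean_low"),
                             names_to = "te_class", values_to = "mean_reactivity",
                             names_prefix = "mean_")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$mean_reactivity,
                                    colour = .data$te_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = region_boundaries(max(dat$bin) / 3),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(~condition, ncol = 1L) +
    ggplot2::labs(x = "bin along transcript (5'UTR | CDS | 3'UTR)",
                  y = "mean reactivity", colour = "TE class") +
    ggplot2::theme_minimal()
}

#' Plot per-bin differential-reactivity significance
#'
#' `-log10` adjusted KS p-value per bin and condition, with the nominal
#' cutoff line.
#'
#' @param bin_summary A `te_bin_summary`.
#' @param alpha Cutoff drawn as a horizontal line, default 0.05.
#' @return A ggplot object.
#' @export
plot_bin_significance <- function(bin_summary, alpha = 0.05) {
  ggplot2::ggplot(bin_summary, ggplot2::aes(x = .data$bin, y = .data$neglog10_padj,
                                            colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "grey50") +
    ggplot2::geom_vline(xintercept = region_boundaries(max(bin_summary$bin) / 3),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "bin along transcript (5'UTR | CDS | 3'UTR)",
                  y = "-log10(adjusted p)", colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot delta (vivo - vitro) reactivity profiles per TE class
#'
#' @param deltas Output of [delta_profile()].
#' @return A ggplot object.
#' @export
plot_delta_profile <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$bin, y = .data$delta,
                                       colour = .data$te_class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = region_boundaries(max(deltas$bin) / 3),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "bin along transcript (5'UTR | CDS | 3'UTR)",
                  y = "in vivo - in vitro reactivity", colour = "TE class") +
    ggplot2::theme_minimal()
}

#' Plot grouped feature importances across splits
#'
#' Boxplot of the per-split summed importance of each feature group.
#'
#' @param importance_summary A `te_importance_summary` from
#'   [grouped_importance()].
#' @return A ggplot object.
#' @export
plot_importance_groups <- function(importance_summary) {
  ggplot2::ggplot(importance_summary$groups,
                  ggplot2::aes(x = .data$group, y = .data$importance)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "feature group", y = "summed importance per split") +
    ggplot2::theme_minimal()
}

#' Plot per-bin importance curves
#'
#' Mean (over splits) importance of each metagene-bin reactivity feature,
#' by condition.
#'
#' @param importance_summary A `te_importance_summary`.
#' @return A ggplot object.
#' @export
plot_importance_bins <- function(importance_summary) {
  dat <- importance_summary$bins
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$mean_importance,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = region_boundaries(max(dat$bin) / 3),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "bin along transcript (5'UTR | CDS | 3'UTR)",
                  y = "mean importance", colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot a single transcript's binned reactivity profiles
#'
#' @param report Output of [transcript_profile_report()].
#' @return A ggplot object.
#' @export
plot_transcript_profile <- function(report) {
  dat <- tidyr::pivot_longer(report, c("vivo", "vitro"),
                             names_to = "condition", values_to = "reactivity")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$reactivity,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = region_boundaries(max(dat$bin) / 3),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "bin along transcript (5'UTR | CDS | 3'UTR)",
                  y = "reactivity", colour = "condition") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_bin_reactivity
#' @param object,... `autoplot` arguments.
autoplot.te_bin_summary <- function(object, ...) plot_bin_reactivity(object)

#' @export
#' @rdname plot_importance_groups
#' @param object,... `autoplot` arguments.
autoplot.te_importance_summary <- function(object, ...) plot_importance_groups(object)
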