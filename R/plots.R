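#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_point
#'   geom_smooth scale_fill_gradient2 labs theme_minimal facet_wrap
NULL

#' Plot a group-contrast statistical map
#'
#' Tile map of the Welch t statistic over ROI pairs (rows) and frequency
#' bands (columns); FDR-surviving cells are starred. Positive t (blue by
#' convention reversed: red) means the control group has the higher
#' envelope correlation.
#'
#' @param object An `oaec_statmap` from [group_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oaec_statmap <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$band <- factor(df$band, levels = unique(df$band))
  df$star <- ifelse(df$fdr_reject, "*", "")
  ggplot(df, aes(x = band, y = pair, fill = t)) +
    geom_tile(color = "grey85") +
    geom_text(aes(label = star), size = 6, vjust = 0.75) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = "frequency band", y = "ROI pair", fill = "Welch t",
         title = "Group contrast of envelope connectivity",
         subtitle = sprintf("* FDR q = %g (step-up threshold %.4g)",
                            attr(object, "q"), attr(object, "threshold"))) +
    theme_minimal()
}

#' Plot group-mean connectivity
#'
#' Tile map of the mean envelope correlation per ROI pair and band,
#' faceted by group.
#'
#' @param conn Long connectivity tibble from [cohort_connectivity()].
#' @param groups Tibble (`subject_id`, `group`) or named vector.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(conn, groups) {
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$subject_id)
  conn$group <- unname(groups[conn$subject_id])
  df <- dplyr::summarise(dplyr::group_by(conn, group, pair, band),
                         aec = mean(aec), .groups = "drop")
  df$band <- factor(df$band, levels = unique(df$band))
  ggplot(df, aes(x = band, y = pair, fill = aec)) +
    geom_tile(color = "grey85") +
    facet_wrap(~group) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = "frequency band", y = "ROI pair", fill = "mean AEC",
         title = "Group-mean amplitude-envelope correlation") +
    theme_minimal()
}

#' Scatter of a connectivity cell against a covariate
#'
#' The classic marker plot: per-subject envelope correlation of one
#' (pair, band) cell against a clinical covariate, with a least-squares
#' trend line.
#'
#' @param conn Long connectivity tibble.
#' @param cohort Cohort tibble with `subject_id` and the covariate.
#' @param pair,band Cell to plot.
#' @param covariate Cohort column name (default `"episodes"`).
#' @param subjects Optional subject subset (e.g. patients only).
#' @return A ggplot object.
#' @export
plot_covariate_scatter <- function(conn, cohort, pair, band,
                                   covariate = "episodes", subjects = NULL) {
  cell <- conn[conn$pair == pair & conn$band == band, ]
  if (!is.null(subjects)) cell <- cell[cell$subject_id %in% subjects, ]
  cell$covariate <- cohort[[covariate]][match(cell$subject_id,
                                              cohort$subject_id)]
  ggplot(cell, aes(x = aec, y = covariate)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                color = "#B2182B") +
    labs(x = sprintf("AEC (%s, %s)", pair, band), y = covariate,
         title = sprintf("%s vs %s connectivity", covariate, pair)) +
    theme_minimal()
}
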