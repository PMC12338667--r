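#' Plot composite stress-susceptibility scores by group
#'
#' Group mean +/- SEM with per-animal points, the standard presentation of
#' composite phenotyping scores (lower = more susceptible).
#'
#' @param scores Output of [composite_scores()].
#' @return A ggplot object.
#' @export
plot_composite <- function(scores) {
  summ <- summarise_composites(scores)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean_composite)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_composite - .data$sem,
                   ymax = .data$mean_composite + .data$sem),
      width = 0.2
    ) +
    ggplot2::geom_jitter(
      data = scores,
      ggplot2::aes(x = .data$group, y = .data$composite),
      width = 0.12, alpha = 0.6, size = 1.4
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "composite score (oriented z)",
                  title = "Composite stress-susceptibility score") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' log2 fold change against -log10 unadjusted p, with the DEG thresholds
#' (|log2FC| >= 1, p < 0.05) drawn and DEGs highlighted.
#'
#' @param results A [nb_wald_test()] table.
#' @param lfc_threshold,p_threshold Thresholds to draw (defaults 1 and 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, lfc_threshold = 1, p_threshold = 0.05) {
  df <- as_tibble(results)
  df$status <- ifelse(!df$is_deg, "not DEG",
                      ifelse(df$log2fc > 0, "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`not DEG` = "grey70",
                                            up = "firebrick",
                                            down = "steelblue")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p (Wald)",
                  colour = NULL,
                  title = attr(results, "contrast") %||% "contrast") +
    ggplot2::theme_minimal()
}

#' Plot a Sholl profile
#'
#' @param profile A [sholl_crossings()] tibble, or several row-bound together
#'   with an extra `group` column.
#' @return A ggplot object.
#' @export
plot_sholl <- function(profile) {
  aes <- if ("group" %in% names(profile)) {
    ggplot2::aes(x = .data$radius_um, y = .data$crossings,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$radius_um, y = .data$crossings)
  }
  ggplot2::ggplot(as_tibble(profile), aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius from soma (um)", y = "process crossings",
                  title = "Sholl profile") +
    ggplot2::theme_minimal()
}

#' Plot spine class proportions
#'
#' @param classified Output of [classify_spines()]; an optional `group`
#'   column splits the bars.
#' @return A ggplot object.
#' @export
plot_spine_classes <- function(classified) {
  df <- as_tibble(classified)
  if (!"group" %in% names(df)) df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, fill = .data$class)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = NULL, y = "% of spines", fill = "spine class",
                  title = "Spine class composition") +
    ggplot2::theme_minimal()
}
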