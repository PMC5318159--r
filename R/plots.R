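#' Lorenz curve of a Gini result
#'
#' The cumulative fraction of total DMS-seq signal against the cumulative
#' fraction of positions; the sag below the diagonal is the structure signal
#' the Gini index quantifies.
#'
#' @param object A [gini_result()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gini_result <- function(object, ...) {
  ggplot2::ggplot(object$lorenz, ggplot2::aes(x = .data$p, y = .data$L)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative fraction of positions",
      y = "Cumulative fraction of signal",
      title = sprintf("Lorenz curve (Gini = %.3f)", object$gini)
    ) +
    ggplot2::theme_minimal()
}

#' Replicate reproducibility vs coverage cutoff
#'
#' @param curve Output of [reproducibility_curve()].
#' @return A ggplot.
#' @export
plot_reproducibility <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$cutoff, y = .data$median_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "DMS-seq depth cutoff (reads/nt)",
                  y = "Median Pearson R between replicates") +
    ggplot2::theme_minimal()
}

#' Translation efficiency against ORF structure
#'
#' @param expr Expression table (with `te`).
#' @param gini_tbl Per-ORF Gini table.
#' @return A ggplot (log-scaled TE axis).
#' @export
plot_te_vs_structure <- function(expr, gini_tbl) {
  df <- left_join(expr, gini_tbl[, c("orf_id", "gini", "included")],
                  by = "orf_id")
  df <- df[!is.na(df$te) & !is.na(df$gini) & df$included, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gini, y = .data$te)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Gini index (DMS-seq)",
                  y = "Translation efficiency") +
    ggplot2::theme_minimal()
}

#' Metagene pairing probability across ORF boundaries
#'
#' @param metagene Output of [metagene_pairing()].
#' @return A ggplot.
#' @export
plot_metagene <- function(metagene) {
  ggplot2::ggplot(metagene,
                  ggplot2::aes(x = .data$position, y = .data$mean_pairing)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "Position relative to downstream start codon (nt)",
                  y = "Mean base-pairing probability") +
    ggplot2::theme_minimal()
}

#' Folding directionality profile
#'
#' @param object A [boundary_directionality()] profile.
#' @param ... Unused.
#' @return A ggplot of the down/up ratio on a log scale.
#' @exportS3Method ggplot2::autoplot
autoplot.directionality_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Position relative to downstream start codon (nt)",
                  y = "Downstream/upstream pairing ratio") +
    ggplot2::theme_minimal()
}

#' Cumulative distribution of adjacent-ORF spacing
#'
#' @param pairs Pair table from [classify_overlap()].
#' @return A ggplot.
#' @export
plot_spacing_cdf <- function(pairs) {
  cdf <- attr(pairs, "spacing_cdf")
  if (is.null(cdf)) {
    pairs <- classify_overlap(pairs)
    cdf <- attr(pairs, "spacing_cdf")
  }
  ggplot2::ggplot(cdf, ggplot2::aes(x = .data$spacing, y = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Spacing between adjacent ORFs (nt)",
                  y = "Cumulative fraction of pairs") +
    ggplot2::theme_minimal()
}
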