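#' Plot training scores and projected samples of a component model
#'
#' Scatter of the first two components: training samples colored by
#' group, with optionally overlaid projected held-out samples (triangle
#' symbols).
#'
#' @param object A `dmr_pca` from [fit_pca()].
#' @param projected Optional tibble from [project_samples()], ideally
#'   after [assign_group()]; a `group` column is used for color when
#'   present.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_pca <- function(object, projected = NULL, ...) {
  scores <- tidy(object)
  p <- ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, colour = .data$group
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1] /
                    sum(object$explained_variance)),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2] /
                    sum(object$explained_variance)),
      colour = "group",
      title = "DMR RPKM principal components"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(projected)) {
    if (!"group" %in% names(projected)) {
      projected$group <- "held-out"
    }
    p <- p + ggplot2::geom_point(
      data = projected, shape = 17, size = 3
    )
  }
  p
}

#' Plot a permutation null distribution against the observed DMR count
#'
#' Histogram of null DMR counts with a vertical line at the observed
#' count.
#'
#' @param object A `dmr_permutation` from [permutation_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_permutation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$dmr_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_dmr_count,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "DMRs per permutation", y = "permutations",
      title = sprintf(
        "Observed %d DMRs vs %d-permutation null (empirical p = %.3f)",
        object$observed_dmr_count, object$n_permutations,
        object$empirical_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot DMR counts across p-value thresholds
#'
#' @param tt A tibble from [threshold_table()].
#' @return A ggplot object (log10 x-axis, all-window and multiple-window
#'   counts as separate series).
#' @export
plot_threshold_table <- function(tt) {
  check_df_cols(tt, c("threshold", "all_dmrs", "multiple_window_dmrs"),
                "tt")
  long <- tidyr::pivot_longer(tt, c("all_dmrs", "multiple_window_dmrs"),
                              names_to = "series", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$n, colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "seed p-value threshold", y = "DMRs",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot DMR CpG-density and length histograms
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @return A ggplot object, one facet per feature.
#' @export
plot_dmr_features <- function(dmrs) {
  stats <- dmr_feature_stats(dmrs)
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey60", colour = "grey30") +
    ggplot2::facet_wrap(~ .data$feature, scales = "free",
                        labeller = ggplot2::as_labeller(c(
                          cpg_per_100bp = "CpG per 100 bp",
                          length_kb = "length (kb)"
                        ))) +
    ggplot2::labs(x = NULL, y = "DMRs") +
    ggplot2::theme_minimal()
}

#' Plot the number of significant windows per DMR
#'
#' @param dmrs A `dmr_set`.
#' @return A ggplot object.
#' @export
plot_multiwindow_histogram <- function(dmrs) {
  h <- multiwindow_histogram(dmrs)
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$sig_windows),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "grey60", colour = "grey30") +
    ggplot2::labs(x = "significant windows per DMR", y = "DMRs") +
    ggplot2::theme_minimal()
}

#' Plot DMR positions along chromosomes
#'
#' Simple coordinate plot: one horizontal lane per chromosome, a marker
#' per DMR, clusters (if supplied) as shaded boxes.
#'
#' @param dmrs A `dmr_set`.
#' @param clusters Optional cluster tibble from [find_clusters()].
#' @return A ggplot object.
#' @export
plot_dmr_locations <- function(dmrs, clusters = NULL) {
  check_df_cols(dmrs, c("chrom", "start", "direction"), "dmrs")
  p <- ggplot2::ggplot(tibble::as_tibble(dmrs)) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$start / 1e6, y = .data$chrom,
                   colour = .data$direction),
      shape = 17, size = 2
    ) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "methylation") +
    ggplot2::theme_minimal()
  if (!is.null(clusters) && nrow(clusters)) {
    p <- p + ggplot2::geom_segment(
      data = clusters,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$chrom, yend = .data$chrom),
      linewidth = 4, alpha = 0.3
    )
  }
  p
}
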