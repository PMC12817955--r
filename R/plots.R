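#' Plot read-start tracks around a site call
#'
#' Mirrored +TEX / -TEX read-start counts over a genomic window, with site
#' calls marked -- the visual signature of a TSS is a +TEX spike, of a TPS a
#' -TEX spike.
#'
#' @param plus_tex,minus_tex [strand_track()]s (replicates are summed).
#' @param calls Optional site-call tibble to mark.
#' @param from,to 0-based window bounds (half-open).
#' @return A ggplot object.
#' @export
plot_site_tracks <- function(plus_tex, minus_tex, calls = NULL,
                             from = 0L, to = NULL) {
  pt <- sum_tracks(plus_tex)
  mt <- sum_tracks(minus_tex)
  if (is.null(to)) to <- length(pt$counts)
  idx <- (from + 1L):to
  df <- dplyr::bind_rows(
    tibble::tibble(position = idx - 1L, count = pt$counts[idx],
                   library = "+TEX"),
    tibble::tibble(position = idx - 1L, count = -mt$counts[idx],
                   library = "-TEX")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$count,
                                        fill = .data$library)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c("+TEX" = "black",
                                          "-TEX" = "darkorange")) +
    ggplot2::labs(x = "genome position (0-based)",
                  y = "read starts (+TEX up, -TEX down)") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    calls <- calls[calls$position >= from & calls$position < to, ]
    p <- p + ggplot2::geom_vline(
      data = calls,
      ggplot2::aes(xintercept = .data$position),
      linetype = "dashed", colour = "steelblue")
  }
  p
}

#' Plot the asRNA/mRNA pair correlation spectrum
#'
#' Histogram of pair Pearson correlation coefficients coloured by
#' correlation class, the summary view of coordinated versus antagonistic
#' sense/antisense expression.
#'
#' @param pairs Pair tibble from [pair_pcc()].
#' @return A ggplot object.
#' @export
plot_pair_correlation <- function(pairs) {
  df <- pairs[!is.na(pairs$pcc), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcc, fill = .data$corr_class)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(positive = "forestgreen",
                                          negative = "steelblue",
                                          uncorrelated = "grey40")) +
    ggplot2::labs(x = "Pearson correlation (log2FC across contrasts)",
                  y = "asRNA/mRNA pairs", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot direction agreement per timepoint
#'
#' Stacked percentage bars of same-direction versus opposite-direction
#' correlated pairs.
#'
#' @param summary_tbl Output of [direction_agreement()].
#' @return A ggplot object.
#' @export
plot_direction_agreement <- function(summary_tbl) {
  df <- tidyr::pivot_longer(summary_tbl, c("pct_same", "pct_opposite"),
                            names_to = "direction", values_to = "pct")
  df$direction <- ifelse(df$direction == "pct_same", "same", "opposite")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$timepoint),
                                   y = .data$pct, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(same = "steelblue",
                                          opposite = "firebrick")) +
    ggplot2::labs(x = "timepoint", y = "% of correlated pairs") +
    ggplot2::theme_minimal()
}

#' Plot bound-versus-unbound expression trajectories
#'
#' Ribbon plot (mean +/- standard error) of group log2 fold changes over
#' timepoints, one line per binding group.
#'
#' @param trajectories Output of [smap_group_trajectories()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  df <- trajectories
  df$t <- as.numeric(factor(df$timepoint))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mean_log2fc,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_log2fc - .data$se,
                                      ymax = .data$mean_log2fc + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = unique(df$t),
                                labels = unique(df$timepoint)) +
    ggplot2::labs(x = "timepoint", y = "mean log2 fold change") +
    ggplot2::theme_minimal()
}

#' Volcano plot for a differential-expression result
#'
#' @param object A `de_result` from [de_stand_in()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$pvalue),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' GC distribution of peaks against the genome background
#'
#' @param object A `gc_bg_test` from [gc_background_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_bg_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$gc_fraction,
                                   fill = .data$set)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "GC fraction") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
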