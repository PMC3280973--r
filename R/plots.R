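#' Locus map with RSS sites and deletion targets
#'
#' Draws the gene model (exons as boxes on the minus strand), the hotspot
#' 23-RSS, and the distal deletion target sites with or without a 12-RSS.
#'
#' @param locus A `ragdel_locus`.
#' @return A ggplot.
#' @export
plot_locus_map <- function(locus) {
  stopifnot(inherits(locus, "ragdel_locus"))
  sites <- locus$distal_sites |>
    dplyr::mutate(kind = ifelse(.data$has_rss, "12-RSS", "breakpoint only"))
  exons <- dplyr::bind_rows(
    dplyr::mutate(locus$exon1, name = "exon 1"),
    dplyr::mutate(locus$exon2, name = "exon 2")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = locus$gene,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      linewidth = 0.4) +
    ggplot2::geom_rect(
      data = exons,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.18, ymax = 0.18),
      fill = "grey30") +
    ggplot2::geom_point(
      data = locus$hotspot,
      ggplot2::aes(x = .data$heptamer_start, y = 0.45),
      shape = 25, size = 3, fill = "firebrick") +
    ggplot2::geom_point(
      data = sites,
      ggplot2::aes(x = .data$breakpoint, y = 0.45, shape = .data$kind),
      size = 2.4, colour = "steelblue") +
    ggplot2::geom_text(
      data = sites,
      ggplot2::aes(x = .data$breakpoint, y = 0.62, label = .data$label),
      size = 2.8) +
    ggplot2::scale_shape_manual(values = c("12-RSS" = 17,
                                           "breakpoint only" = 4)) +
    ggplot2::scale_y_continuous(limits = c(-0.5, 0.9), breaks = NULL) +
    ggplot2::labs(x = "locus position (bp)", y = NULL, shape = NULL,
                  title = "Simulated locus: hotspot 23-RSS (red) and distal target sites") +
    ggplot2::theme_minimal()
}

#' @rdname plot_locus_map
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.ragdel_locus <- function(object, ...) plot_locus_map(object)

#' Breakpoint positions coloured by cluster
#'
#' @param positions Integer vector of breakpoint positions.
#' @param tolerance Clustering tolerance passed to
#'   [cluster_breakpoints()] (default 10).
#' @return A ggplot.
#' @export
plot_breakpoint_clusters <- function(positions, tolerance = 10) {
  catalog <- cluster_breakpoints(positions, tolerance = tolerance)
  members <- catalog |>
    dplyr::select("cluster_id", "members") |>
    tidyr::unnest("members") |>
    dplyr::rename(position = "members")
  ggplot2::ggplot(members,
                  ggplot2::aes(x = .data$position,
                               fill = .data$cluster_id)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(x = "breakpoint position (bp)", y = "breakpoints",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Bar chart of recurrent deletion-type frequencies
#'
#' @param freqs Tibble from [deletion_type_frequencies()].
#' @return A ggplot.
#' @export
plot_deletion_frequencies <- function(freqs) {
  classified <- dplyr::filter(freqs, .data$classified)
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$label, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = "deletion type", y = "share of classified cases") +
    ggplot2::theme_minimal()
}

#' ChIP percent-recovery by region and lineage
#'
#' @param data Tibble with `region`, `lineage`, `antibody` and
#'   `pct_recovery` columns (see [pct_recovery()]).
#' @return A ggplot.
#' @export
plot_recovery <- function(data) {
  stopifnot(all(c("region", "lineage", "pct_recovery") %in% names(data)))
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$region,
                                    y = .data$pct_recovery,
                                    colour = .data$lineage)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::labs(x = NULL, y = "% recovery of input", colour = NULL) +
    ggplot2::theme_minimal()
  if ("antibody" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$antibody),
                                 scales = "free_y")
  }
  p
}
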