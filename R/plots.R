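#' Plot a hotspot profile
#'
#' Per-bin unique-recombinant counts across the reference, with the hotspot
#' threshold and lettered hotspot regions.
#'
#' @param object A `hotspot_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hotspot_profile <- function(object, ...) {
  bins <- tibble::as_tibble(object)
  hs <- hotspots(object)
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = (.data$bin_start +
                                                 .data$bin_end) / 2000,
                                          y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_size") / 1000,
                      fill = "grey35") +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Position (kb)",
                  y = "Unique recombination intervals per bin") +
    ggplot2::theme_minimal()
  if (nrow(hs) > 0) {
    p <- p + ggplot2::annotate("text",
                               x = (hs$start_bp + hs$end_bp) / 2000,
                               y = max(bins$count) * 1.05,
                               label = hs$letter, fontface = "bold")
  }
  p
}

#' Plot endpoint-fluorescence points coloured by genotype call
#'
#' The two-dimensional cluster diagram of a KASP plate: FAM signal on the
#' x axis, VIC on the y axis, one cluster per genotype code.
#'
#' @param points Data frame with `vic`, `fam` and optionally `call` (added
#'   with [classify_kasp()] when absent).
#' @param centroids,max_radius Passed to [classify_kasp()] when calls are
#'   missing.
#' @return A ggplot.
#' @export
plot_kasp <- function(points, centroids = kasp_centroids(),
                      max_radius = 0.25) {
  points <- tibble::as_tibble(points)
  if (!"call" %in% names(points)) {
    points$call <- classify_kasp(points, centroids, max_radius)
  }
  ggplot2::ggplot(points, ggplot2::aes(x = .data$fam, y = .data$vic,
                                       colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "FAM (allele y)", y = "VIC (allele x)",
                  colour = "cluster") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a cluster assignment summary
#'
#' Per-family MPPD against the percentile threshold, with bootstrap
#' reliability shown by fill.
#'
#' @param object A `bsnp_clusters`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bsnp_clusters <- function(object, ...) {
  df <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(object),
                                         .data$family),
                         mppd = .data$mppd[1],
                         reliable = .data$meets_bootstrap[1],
                         n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$mppd,
                                   fill = .data$reliable)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Family", y = "Median pairwise patristic distance",
                  fill = paste0("bootstrap >= ",
                                attr(object, "bootstrap_min"), "%")) +
    ggplot2::theme_minimal()
}

#' Plot the clustering tree with family-coloured tips
#'
#' @param x A `bsnp_clusters`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.bsnp_clusters <- function(x, ...) {
  tr <- attr(x, "tree")
  fam <- factor(x$family[match(tr$tip.label, x$haplotype)])
  cols <- grDevices::rainbow(nlevels(fam))[as.integer(fam)]
  ape::plot.phylo(tr, tip.color = cols, ...)
  invisible(x)
}
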