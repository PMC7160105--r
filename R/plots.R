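#' Plot a per-section score surface
#'
#' Tile map of the score over each section's grid, one facet per section
#' — the flat-map analogue of mapping scores onto the stacked tumor
#' slices.
#'
#' @param object A `spatialith_surface` from [map_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatialith_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y, y = .data$x,
                                       fill = .data$score)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::facet_wrap(~section, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row")
}

#' Plot the consensus delta-area curve
#'
#' The relative increase in consensus-CDF area per added cluster; the
#' chosen k (largest k above the flattening threshold) is marked.
#'
#' @param object A `consensus_clustering` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_clustering <- function(object, ...) {
  ggplot2::ggplot(object$area, ggplot2::aes(x = .data$k, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "relative area increase",
                  title = sprintf("Delta-area plot (chosen k = %d)", object$k_opt))
}

#' Plot a DNA vs RNA clone-frequency activation fit
#'
#' Shared clones with the least-squares line; points above the line are
#' transcriptionally over-active.
#'
#' @param object A `tcr_activation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_activation <- function(object, ...) {
  ggplot2::ggplot(object$clones,
                  ggplot2::aes(x = .data$dna_frequency, y = .data$rna_frequency)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$residual > 0)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
                                name = "over-active") +
    ggplot2::labs(x = "DNA productive frequency", y = "RNA productive frequency")
}

#' Bar chart of a clone or mutation sharing spectrum
#'
#' @param spectrum Output of [sharing_spectrum()] or
#'   [mutation_sharing()].
#' @return A ggplot object.
#' @export
plot_sharing_spectrum <- function(spectrum) {
  s <- spectrum$summary
  count_col <- intersect(c("n_clones", "n_mutations"), names(s))[1]
  s$class <- factor(s$class, levels = c("private", "intermediate", "ubiquitous"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data[[count_col]]), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "fraction of clones/mutations")
}
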