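#' Tidy a consensus clustering result
#'
#' @param x A `consensus_clustering` object.
#' @param ... Unused.
#' @return The delta-area tibble (`k`, `A`, `delta`).
#' @export
tidy.consensus_clustering <- function(x, ...) x$area

#' @rdname tidy.consensus_clustering
#' @return `glance()`: a one-row tibble with `k_opt`, `kmax`, `B`,
#'   `resample_fraction`, `distance`.
#' @export
glance.consensus_clustering <- function(x, ...) {
  tibble::tibble(k_opt = x$k_opt, kmax = x$kmax, B = x$B,
                 resample_fraction = x$resample_fraction,
                 distance = x$distance)
}

#' Tidy a TCR activation fit
#'
#' @param x A `tcr_activation` object from [activation_residuals()].
#' @param ... Unused.
#' @return The per-clone tibble with frequencies, fits and residuals.
#' @export
tidy.tcr_activation <- function(x, ...) x$clones

#' @rdname tidy.tcr_activation
#' @return `glance()`: a one-row tibble with `slope`, `intercept`,
#'   `n_shared`, `log_scale`.
#' @export
glance.tcr_activation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_shared = x$n_shared, log_scale = x$log_scale)
}

#' Tidy a similarity network
#'
#' @param x A `spatialith_network` from [top_quartile_links()].
#' @param ... Unused.
#' @return The linked edges as a plain tibble.
#' @export
tidy.spatialith_network <- function(x, ...) {
  out <- tibble::as_tibble(x[x$linked, c("from", "to", "distance", "similarity")])
  attr(out, "cutoff") <- NULL
  out
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("Consensus clustering: %d samples, k = 2..%d, B = %d\n",
              nrow(x$assignments), x$kmax, x$B))
  cat(sprintf("Chosen k = %d (delta-area rule)\n", x$k_opt))
  invisible(x)
}

#' @export
print.tcr_activation <- function(x, ...) {
  cat(sprintf("TCR activation fit over %d shared clones: RNA = %.3g + %.3g * DNA\n",
              x$n_shared, x$intercept, x$slope))
  invisible(x)
}

#' @export
print.spatialith_sim <- function(x, ...) {
  cat(sprintf("Synthetic spatial tumor: %d regions (%d sections), %d genes, %d mutations, %d TCR clones\n",
              nrow(x$regions), x$config$n_sections, nrow(x$genes),
              nrow(x$truth$mutation_classes), x$config$n_clones))
  invisible(x)
}

#' @export
print.spatialith_run <- function(x, ...) {
  cat("spatialith pipeline run\n")
  cat(sprintf("  regions: %d  consensus k: %d  margin-test p: %.3g\n",
              nrow(x$sim$regions), x$consensus$k_opt, x$margin_test$p))
  cat(sprintf("  mean DNA clonality: %.3f  ubiquitous TCR fraction: %.3f\n",
              mean(x$clonality$clonality),
              x$tcr_sharing$summary$fraction[
                x$tcr_sharing$summary$class == "ubiquitous"]))
  invisible(x)
}
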