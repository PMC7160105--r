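#' Collapse copy-number segments to gene-level log2 ratios
#'
#' Each gene's value is the length-weighted mean of the log2 ratios of the
#' segments overlapping it (SEG coordinates are 1-based inclusive; overlap
#' widths are computed on that convention). Genes with no overlapping
#' segment in a sample are `NA`.
#'
#' @param segments Segment tibble (`sample`, `chrom`, `start`, `end`,
#'   `log2_ratio`), e.g. from [read_seg()] or [simulate_copy_number()].
#' @param genes Gene annotation tibble (`gene`, `chrom`, `start`, `end`,
#'   1-based inclusive).
#' @return A gene x sample tibble of log2 ratios (first column `gene`).
#' @export
genes_from_segments <- function(segments, genes) {
  if (any(genes$end < genes$start)) {
    bad <- genes$gene[genes$end < genes$start]
    abort(paste0("zero- or negative-length gene(s): ", paste(bad, collapse = ", ")))
  }
  if (length(intersect(unique(genes$chrom), unique(segments$chrom))) == 0) {
    abort(paste0(
      "no shared chromosome names between genes and segments; gene chroms: ",
      paste(head(unique(genes$chrom), 5), collapse = ", "), " vs segment chroms: ",
      paste(head(unique(segments$chrom), 5), collapse = ", ")))
  }
  hits <- dplyr::inner_join(
    dplyr::rename(genes[c("gene", "chrom", "start", "end")],
                  g_start = "start", g_end = "end"),
    dplyr::rename(segments[c("sample", "chrom", "start", "end", "log2_ratio")],
                  s_start = "start", s_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(width = pmin(.data$g_end, .data$s_end) -
                    pmax(.data$g_start, .data$s_start) + 1) |>
    dplyr::filter(.data$width > 0) |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(log2_ratio = sum(.data$log2_ratio * .data$width) /
                       sum(.data$width), .groups = "drop")
  wide <- tidyr::pivot_wider(hits, names_from = "sample",
                             values_from = "log2_ratio")
  # keep every annotated gene and every sample, NA where uncovered
  all_samples <- unique(segments$sample)
  missing_samples <- setdiff(all_samples, names(wide))
  for (s in missing_samples) wide[[s]] <- NA_real_
  out <- dplyr::left_join(genes["gene"], wide, by = "gene")
  out <- out[c("gene", all_samples)]
  set_transform(tibble::as_tibble(out), "log2ratio")
}

#' Call gene-level copy-number events
#'
#' An event is called where the absolute gene-level log2 ratio reaches the
#' threshold: `+1` for log2 >= threshold, `-1` for log2 <= -threshold, `0`
#' otherwise (boundary equality counts as an event). `NA` propagates.
#'
#' @param cn_matrix Gene x sample log2-ratio tibble from
#'   [genes_from_segments()].
#' @param threshold Positive log2 threshold (default 0.6).
#' @return A gene x sample tibble with values in `-1, 0, +1, NA`.
#' @export
call_gene_events <- function(cn_matrix, threshold = 0.6) {
  if (!is.numeric(threshold) || threshold <= 0) abort("threshold must be positive.")
  m <- counts_matrix(cn_matrix)
  ev <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  ev[m >= threshold] <- 1
  ev[m <= -threshold] <- -1
  ev[is.na(m)] <- NA
  matrix_counts(ev, "event")
}

#' Call whole-chromosome copy-number events
#'
#' A chromosome is called gained in a sample when segments with log2 ratio
#' strictly above `mean_threshold` cover strictly more than
#' `frac_threshold` of the chromosome length (symmetrically for losses
#' below `-mean_threshold`). Chromosome length defaults to the span from
#' the first to the last segment of that sample on the chromosome; an
#' optional assembly length table overrides this.
#'
#' @param segments Segment tibble.
#' @param chrom Chromosome(s) to call; `NULL` calls every chromosome
#'   present.
#' @param mean_threshold Log2 threshold (strict; default 0.3).
#' @param frac_threshold Covered-fraction threshold (strict; default 0.7).
#' @param chrom_lengths Optional tibble (`chrom`, `length`) overriding the
#'   segment-span length.
#' @return A tibble `sample`, `chrom`, `call` (`gain`/`loss`/`none`),
#'   `covered_fraction_gain`, `covered_fraction_loss`.
#' @export
call_chromosome_event <- function(segments, chrom = NULL, mean_threshold = 0.3,
                                  frac_threshold = 0.7, chrom_lengths = NULL) {
  chroms <- chrom %||% unique(segments$chrom)
  combos <- tidyr::expand_grid(sample = unique(segments$sample), chrom = chroms)
  out <- purrr::pmap_dfr(combos, function(sample, chrom) {
    seg <- segments[segments$sample == sample & segments$chrom == chrom, ]
    if (nrow(seg) == 0) {
      warn(sprintf("no segments for %s on %s; call is missing.", sample, chrom))
      return(tibble::tibble(sample = sample, chrom = chrom, call = NA_character_,
                            covered_fraction_gain = NA_real_,
                            covered_fraction_loss = NA_real_))
    }
    len <- if (!is.null(chrom_lengths)) {
      chrom_lengths$length[match(chrom, chrom_lengths$chrom)]
    } else {
      max(seg$end) - min(seg$start) + 1
    }
    w <- seg$end - seg$start + 1
    fg <- sum(w[seg$log2_ratio > mean_threshold]) / len
    fl <- sum(w[seg$log2_ratio < -mean_threshold]) / len
    call <- if (fg > frac_threshold) "gain" else if (fl > frac_threshold) "loss" else "none"
    tibble::tibble(sample = sample, chrom = chrom, call = call,
                   covered_fraction_gain = fg, covered_fraction_loss = fl)
  })
  out
}

#' Per-sample copy-number burden
#'
#' The number of genes with a called event (gain or loss) per sample;
#' genes with missing calls are excluded, not imputed.
#'
#' @param events Gene x sample event tibble from [call_gene_events()].
#' @return A tibble `sample`, `burden`.
#' @export
cna_burden <- function(events) {
  m <- counts_matrix(events)
  tibble::tibble(sample = colnames(m),
                 burden = as.integer(colSums(abs(m) > 0, na.rm = TRUE)))
}
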