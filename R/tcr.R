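# Clone identity: nucleotide level keys on (CDR3nt, V, J); amino-acid level
# aggregates all nucleotide clones sharing one CDR3aa.
clone_key <- function(rep, level) {
  switch(level,
    nucleotide = paste(rep$cdr3_nt, rep$v_gene, rep$j_gene, sep = "|"),
    amino_acid = rep$cdr3_aa,
    abort("level must be 'nucleotide' or 'amino_acid'."))
}

#' Productive clone frequencies
#'
#' Frequencies over productive clones only, at the chosen clone-identity
#' level; they sum to 1 per repertoire. At the amino-acid level a clone's
#' frequency is the sum of its nucleotide-level frequencies.
#'
#' @param rep A clone tibble for one sample/assay (columns as in
#'   [read_clones()]).
#' @param level `"nucleotide"` (default) or `"amino_acid"`.
#' @return A tibble `clone`, `count`, `frequency`, sorted by decreasing
#'   frequency (ties by clone key).
#' @export
productive_frequencies <- function(rep, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  rep <- rep[rep$productive, , drop = FALSE]
  if (nrow(rep) == 0) abort("no productive clones.")
  tibble::tibble(clone = clone_key(rep, level), count = rep$count) |>
    dplyr::group_by(.data$clone) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$clone)
}

#' TCR repertoire clonality
#'
#' `1 - H / ln(R)` where H is the Shannon entropy (natural log) of the
#' productive nucleotide-level clone frequencies and R their richness;
#' defined as 1 for a monoclonal repertoire. 0 means perfectly even, 1
#' monoclonal; the value is invariant to rescaling all counts.
#'
#' @param rep A clone tibble for one sample/assay.
#' @param level Clone identity level (default nucleotide).
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(rep, level = "nucleotide") {
  f <- productive_frequencies(rep, level)$frequency
  R <- length(f)
  if (R == 1) return(1)
  H <- -sum(f * log(f))
  1 - H / log(R)
}

#' Morisita overlap between two repertoires
#'
#' Default is the Morisita-Horn index on productive frequencies over the
#' clone union, `2 sum(p q) / (sum(p^2) + sum(q^2))` — 0 for disjoint, 1
#' for identical frequency profiles. `method = "morisita"` gives the
#' classical Morisita index, which uses raw counts.
#'
#' @param rep_a,rep_b Clone tibbles.
#' @param level Clone identity level.
#' @param method `"horn"` (default) or `"morisita"`.
#' @return Overlap in `[0, 1]`.
#' @export
morisita_overlap <- function(rep_a, rep_b, level = "nucleotide",
                             method = c("horn", "morisita")) {
  method <- match.arg(method)
  fa <- productive_frequencies(rep_a, level)
  fb <- productive_frequencies(rep_b, level)
  clones <- union(fa$clone, fb$clone)
  p <- setNames(rep(0, length(clones)), clones); p[fa$clone] <- fa$frequency
  q <- setNames(rep(0, length(clones)), clones); q[fb$clone] <- fb$frequency
  if (method == "horn") {
    return(2 * sum(p * q) / (sum(p^2) + sum(q^2)))
  }
  xa <- setNames(rep(0, length(clones)), clones); xa[fa$clone] <- fa$count
  xb <- setNames(rep(0, length(clones)), clones); xb[fb$clone] <- fb$count
  Na <- sum(xa); Nb <- sum(xb)
  la <- sum(xa * (xa - 1)) / (Na * (Na - 1))
  lb <- sum(xb * (xb - 1)) / (Nb * (Nb - 1))
  2 * sum(xa * xb) / ((la + lb) * Na * Nb)
}

#' Clone sharing spectrum across regions
#'
#' A clone counts as present in a region when its productive count reaches
#' `min_count`. Ubiquitous clones are present in all regions, private
#' clones in exactly one; everything else is intermediate.
#'
#' @param reps A clone tibble covering several samples (a `sample` column)
#'   for one assay.
#' @param level Clone identity level.
#' @param min_count Presence threshold (default 1).
#' @return A list: `per_clone` tibble (`clone`, `n_regions`, `class`) and
#'   `summary` (counts and fractions per class; fractions sum to 1).
#' @export
sharing_spectrum <- function(reps, level = "nucleotide", min_count = 1) {
  samples <- unique(reps$sample)
  if (length(samples) < 2) abort("sharing spectrum needs at least 2 regions.")
  prod <- reps[reps$productive & reps$count >= min_count, , drop = FALSE]
  per_clone <- tibble::tibble(clone = clone_key(prod, level),
                              sample = prod$sample) |>
    dplyr::distinct() |>
    dplyr::count(.data$clone, name = "n_regions") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_regions == length(samples) ~ "ubiquitous",
      .data$n_regions == 1 ~ "private",
      TRUE ~ "intermediate"))
  summary <- per_clone |>
    dplyr::count(.data$class, name = "n_clones") |>
    tidyr::complete(class = c("ubiquitous", "intermediate", "private"),
                    fill = list(n_clones = 0L)) |>
    dplyr::mutate(fraction = .data$n_clones / sum(.data$n_clones))
  list(per_clone = per_clone, summary = summary,
       n_regions_total = length(samples))
}

#' Top clones per assay for one sample
#'
#' The top `n` productive clones by frequency in each assay (ties broken
#' by clone key, lexicographically), plus a joint table aligning the union
#' of both top lists across assays.
#'
#' @param rep_dna,rep_rna Clone tibbles for the same sample.
#' @param n Number of clones per assay (default 5). If `n` exceeds the
#'   richness, all clones are returned with a note.
#' @param level Clone identity level.
#' @return A list: `dna`, `rna` (ranked tibbles) and `joint` (one row per
#'   clone in the union, with both frequencies).
#' @export
top_clones <- function(rep_dna, rep_rna, n = 5, level = "nucleotide") {
  take_top <- function(rep, assay) {
    f <- productive_frequencies(rep, level)
    if (n > nrow(f)) inform(sprintf("%s assay has only %d clones (< n = %d); returning all.",
                                    assay, nrow(f), n))
    dplyr::mutate(head(f, n), assay = assay, rank = dplyr::row_number())
  }
  dna <- take_top(rep_dna, "DNA")
  rna <- take_top(rep_rna, "RNA")
  fd <- productive_frequencies(rep_dna, level)
  fr <- productive_frequencies(rep_rna, level)
  joint <- tibble::tibble(clone = union(dna$clone, rna$clone)) |>
    dplyr::left_join(dplyr::select(fd, "clone", dna_frequency = "frequency"),
                     by = "clone") |>
    dplyr::left_join(dplyr::select(fr, "clone", rna_frequency = "frequency"),
                     by = "clone") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("frequency"),
                                ~ tidyr::replace_na(.x, 0)))
  list(dna = dna, rna = rna, joint = joint)
}

#' Transcriptional activation of TCR clones from paired DNA/RNA assays
#'
#' Ordinary least squares of RNA productive frequency on DNA productive
#' frequency over the clones detected in both assays; the residual of a
#' clone from the line of best fit measures its transcriptional
#' activation (positive = over-active). A log-log fit is offered because
#' heavy-tailed frequencies dominate OLS on the raw scale; `top_n`
#' restricts the regression to the top clones by DNA frequency.
#'
#' @param rep_dna,rep_rna Clone tibbles for one sample.
#' @param min_shared Minimum shared productive clones (default 3).
#' @param level Clone identity level.
#' @param log_scale Fit on log10 frequencies (default FALSE).
#' @param top_n Optional: use only the top `top_n` clones by DNA
#'   frequency.
#' @return A `tcr_activation` object: `clones` tibble (`clone`,
#'   `dna_frequency`, `rna_frequency`, `fitted`, `residual`), `slope`,
#'   `intercept`, `n_shared`.
#' @export
activation_residuals <- function(rep_dna, rep_rna, min_shared = 3,
                                 level = "nucleotide", log_scale = FALSE,
                                 top_n = NULL) {
  fd <- productive_frequencies(rep_dna, level)
  fr <- productive_frequencies(rep_rna, level)
  shared <- dplyr::inner_join(
    dplyr::select(fd, "clone", dna_frequency = "frequency"),
    dplyr::select(fr, "clone", rna_frequency = "frequency"), by = "clone")
  if (!is.null(top_n)) {
    shared <- head(dplyr::arrange(shared, dplyr::desc(.data$dna_frequency),
                                  .data$clone), top_n)
  }
  if (nrow(shared) < min_shared) {
    abort(sprintf("only %d shared clones (< min_shared = %d).",
                  nrow(shared), min_shared))
  }
  x <- shared$dna_frequency; y <- shared$rna_frequency
  if (log_scale) { x <- log10(x); y <- log10(y) }
  fit <- lm(y ~ x)
  shared$fitted <- unname(stats::fitted(fit))
  shared$residual <- unname(resid(fit))
  structure(list(clones = shared,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_shared = nrow(shared), log_scale = log_scale),
            class = "tcr_activation")
}

#' Correlate clone frequencies with truncal mutation VAFs across regions
#'
#' Spearman rank correlation per (clone, mutation) pair over the regions
#' carrying both measurements, with BH adjustment within each clone's
#' family of mutations. Constant vectors give a missing correlation with
#' a flag.
#'
#' @param clone_freqs Tibble `region_id`, `clone`, `frequency`.
#' @param vafs Tibble `region_id`, `mutation_id`, `vaf` (e.g. pivoted
#'   from [truncal_vaf_table()]).
#' @param min_regions Minimum shared regions per pair (default 4).
#' @return A tibble `clone`, `mutation_id`, `n`, `rho`, `p`, `padj`,
#'   `constant_input`.
#' @export
clone_vaf_correlation <- function(clone_freqs, vafs, min_regions = 4) {
  pairs <- tidyr::expand_grid(clone = unique(clone_freqs$clone),
                              mutation_id = unique(vafs$mutation_id))
  out <- purrr::pmap_dfr(pairs, function(clone, mutation_id) {
    cf <- clone_freqs[clone_freqs$clone == clone, ]
    vf <- vafs[vafs$mutation_id == mutation_id, ]
    j <- dplyr::inner_join(cf[c("region_id", "frequency")],
                           vf[c("region_id", "vaf")], by = "region_id")
    if (nrow(j) < min_regions) {
      return(tibble::tibble(clone = clone, mutation_id = mutation_id,
                            n = nrow(j), rho = NA_real_, p = NA_real_,
                            constant_input = NA))
    }
    constant <- sd(j$frequency) == 0 || sd(j$vaf) == 0
    if (constant) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(j$frequency, j$vaf, method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    tibble::tibble(clone = clone, mutation_id = mutation_id, n = nrow(j),
                   rho = rho, p = p, constant_input = constant)
  })
  dplyr::mutate(dplyr::group_by(out, .data$clone),
                padj = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
}
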