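#' Log2-transform a counts table
#'
#' Elementwise `log2(x + pseudocount)`. The transform state is stamped on
#' the result so an accidental double transform raises an error.
#'
#' @param counts Raw counts tibble (first column `gene`).
#' @param pseudocount Added before the log (default 1).
#' @return The transformed tibble, flagged `log2p1`.
#' @export
log2_counts <- function(counts, pseudocount = 1) {
  assert_counts(counts)
  if (transform_state(counts) == "log2p1") {
    abort("counts are already log2-transformed.")
  }
  out <- dplyr::mutate(counts, dplyr::across(!dplyr::all_of("gene"),
                                             ~ log2(.x + pseudocount)))
  set_transform(out, "log2p1")
}

as_gene_sets <- function(gene_sets) {
  if (is.character(gene_sets)) gene_sets <- list(signature = gene_sets)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("gene sets must be named.")
  }
  lapply(gene_sets, unique)
}

score_mean_log2 <- function(log2_mat, gene_sets, min_genes, method) {
  assert_counts(log2_mat, "log2_mat")
  if (transform_state(log2_mat) != "log2p1") {
    abort("matrix must be log2-transformed first (see log2_counts()).")
  }
  gene_sets <- as_gene_sets(gene_sets)
  m <- counts_matrix(log2_mat)
  purrr::imap_dfr(gene_sets, function(members, nm) {
    present <- intersect(members, rownames(m))
    if (length(present) == 0) {
      warn(sprintf("gene set '%s' shares no genes with the matrix.", nm))
    }
    score <- if (length(present) < min_genes) {
      rep(NA_real_, ncol(m))
    } else {
      unname(colMeans(m[present, , drop = FALSE]))
    }
    tibble::tibble(sample = colnames(m), signature = nm, score = score,
                   n_genes = length(present), method = method)
  })
}

#' Geometric-mean gene-set scores
#'
#' The score of sample j for a set S is the arithmetic mean over members of
#' `log2(count + pseudocount)` — i.e. the geometric mean of
#' (count + pseudocount) expressed on the log2 scale. Sets with fewer than
#' `min_genes` measured members score `NA`.
#'
#' @param log2_mat A log2-transformed counts tibble (see [log2_counts()]).
#' @param gene_sets A named list of character vectors (or one character
#'   vector).
#' @param min_genes Minimum measured members (default 3).
#' @return A long tibble `sample`, `signature`, `score`, `n_genes`,
#'   `method`.
#' @export
geometric_mean_score <- function(log2_mat, gene_sets, min_genes = 3) {
  score_mean_log2(log2_mat, gene_sets, min_genes, "geomean")
}

#' Marker-based cell-population abundance scores
#'
#' An explicit stand-in for deconvolution tools: the mean log2 count of a
#' population's marker genes, tagged `marker_mean` so downstream consumers
#' can tell these scores from signature enrichment.
#'
#' @inheritParams geometric_mean_score
#' @param marker_sets Named list of marker gene vectors, one per
#'   population.
#' @return A long score tibble with `method = "marker_mean"`.
#' @export
marker_abundance <- function(log2_mat, marker_sets, min_genes = 3) {
  score_mean_log2(log2_mat, marker_sets, min_genes, "marker_mean")
}

# Single-sample enrichment walk for one sample. `expr` is a named numeric
# vector; ties in expression are broken by gene identifier order.
ssgsea_walk <- function(expr, members, tau) {
  genes <- names(expr)
  ord <- order(-expr, genes)
  in_set <- genes[ord] %in% members
  N <- length(genes)
  ranks <- N - seq_len(N) + 1          # top gene carries the largest rank
  w <- ifelse(in_set, ranks^tau, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (N - sum(in_set))
  sum(p_in - p_out)
}

#' Single-sample rank-based gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending, ties broken by
#' gene identifier); the score is the sum of the running difference
#' between the rank-weighted in-set ECDF (weights `rank^tau`) and the
#' uniform out-of-set ECDF. No cross-sample normalization is applied.
#'
#' @param mat Expression tibble (any monotone transform gives identical
#'   scores; the statistic is rank-based).
#' @param gene_sets Named list of character vectors (or one vector).
#' @param tau Rank-weighting exponent (default 0.25).
#' @return A long tibble `sample`, `signature`, `score`, `n_genes`,
#'   `method = "ssgsea"`.
#' @export
ssgsea_score <- function(mat, gene_sets, tau = 0.25) {
  assert_counts(mat, "mat")
  gene_sets <- as_gene_sets(gene_sets)
  m <- counts_matrix(mat)
  if (nrow(m) < 2) abort("ssGSEA needs at least 2 genes.")
  purrr::imap_dfr(gene_sets, function(members, nm) {
    present <- intersect(members, rownames(m))
    if (length(present) == 0) abort(sprintf("gene set '%s' is empty after intersection.", nm))
    if (length(present) == nrow(m)) {
      abort(sprintf("gene set '%s' covers every gene; out-of-set ECDF undefined.", nm))
    }
    score <- vapply(colnames(m), function(s) {
      ssgsea_walk(setNames(m[, s], rownames(m)), present, tau)
    }, 0)
    tibble::tibble(sample = colnames(m), signature = nm, score = unname(score),
                   n_genes = length(present), method = "ssgsea")
  })
}

#' Compare signature scores between two groups
#'
#' Welch two-sided t-test per signature, with Benjamini-Hochberg adjustment
#' across the signatures passed in one call (that call defines the
#' adjustment family).
#'
#' @param scores Long score tibble (`sample`, `signature`, `score`).
#' @param labels Two-group labels: a named vector (names = samples) or a
#'   two-column data frame (sample, group).
#' @return A tibble per signature: group means, `t` (group2 minus group1
#'   orientation), `p`, `padj`.
#' @export
compare_groups <- function(scores, labels) {
  by_sig <- split(scores, scores$signature)
  out <- purrr::imap_dfr(by_sig, function(tab, nm) {
    tab <- tab[!is.na(tab$score), ]
    grp <- split_two_groups(labels, tab$sample)
    x <- tab$score[grp$idx[[1]]]; y <- tab$score[grp$idx[[2]]]
    ht <- welch_safe(y, x)            # statistic oriented group2 - group1
    tibble::tibble(signature = nm, group1 = grp$groups[1], group2 = grp$groups[2],
                   mean1 = mean(x), mean2 = mean(y),
                   t = ht$statistic, p = ht$p.value)
  })
  out$padj <- p.adjust(out$p, method = "BH")
  dplyr::arrange(out, .data$p)
}

#' Bin values into tertiles
#'
#' Boundaries sit at the 1/3 and 2/3 empirical quantiles of the non-missing
#' values; ties at a boundary fall into the lower bin, so an all-equal
#' input is all `low`.
#'
#' @param values Numeric vector (>= 3 non-missing values).
#' @return A factor with levels `low`, `medium`, `high` (NA preserved).
#' @export
tertile_categorize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("tertile binning needs at least 3 non-missing values.")
  q <- quantile(values[ok], c(1, 2) / 3, names = FALSE)
  lab <- ifelse(values <= q[1], "low", ifelse(values <= q[2], "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"))
}
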