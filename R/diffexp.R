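#' Simplified two-group differential expression
#'
#' A deliberately simple DE stage so the pipeline runs end-to-end: per-gene
#' Welch two-sided t-test on log2 counts, log2 fold change as the
#' difference of group means (group2 minus group1), BH adjustment across
#' all tested genes. Genes whose identifier starts with `RPL` or `RPS`
#' (ribosomal L/S subunits) can be excluded before testing. An optional
#' empirical-Bayes variance moderation shrinks per-gene variances toward
#' the pooled mean variance with `prior_df` prior degrees of freedom.
#'
#' @param log2_mat Log2-transformed counts tibble ([log2_counts()]).
#' @param labels Two-group labels (named vector or two-column data frame).
#' @param exclude_ribosomal Drop `RPL`/`RPS`-prefixed genes first
#'   (default TRUE).
#' @param moderate_variance Apply empirical-Bayes variance moderation
#'   (default FALSE).
#' @param prior_df Prior degrees of freedom for moderation (default 4).
#' @return A tibble `gene`, `log2fc`, `t`, `p`, `padj`, `constant`
#'   (method tag `"welch_simplified"` in the `method` attribute).
#' @export
differential_expression <- function(log2_mat, labels, exclude_ribosomal = TRUE,
                                    moderate_variance = FALSE, prior_df = 4) {
  assert_counts(log2_mat, "log2_mat")
  if (transform_state(log2_mat) != "log2p1") {
    abort("differential_expression expects log2-transformed counts.")
  }
  m <- counts_matrix(log2_mat)
  if (exclude_ribosomal) {
    m <- m[!grepl("^RP[LS]", rownames(m)), , drop = FALSE]
  }
  grp <- split_two_groups(labels, colnames(m))
  x <- m[, grp$idx[[1]], drop = FALSE]
  y <- m[, grp$idx[[2]], drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  mean1 <- rowMeans(x); mean2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  if (moderate_variance) {
    pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    prior <- mean(pooled[pooled > 0])
    shrink <- function(v, n) ((n - 1) * v + prior_df * prior) / (n - 1 + prior_df)
    v1 <- shrink(v1, n1); v2 <- shrink(v2, n2)
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean2 - mean1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  constant <- v1 == 0 & v2 == 0 & mean1 == mean2
  tstat[constant] <- 0
  p[constant] <- 1
  # zero within-group variance but different means: maximally significant
  degenerate <- (v1 == 0 & v2 == 0) & !constant
  tstat[degenerate] <- sign(mean2 - mean1)[degenerate] * Inf
  p[degenerate] <- 0
  out <- tibble::tibble(gene = rownames(m), log2fc = mean2 - mean1,
                        t = tstat, p = p,
                        padj = p.adjust(p, method = "BH"),
                        constant = constant)
  attr(out, "method") <- "welch_simplified"
  attr(out, "groups") <- grp$groups
  dplyr::arrange(out, .data$p)
}

#' Select differentially expressed genes by strict thresholds
#'
#' Genes with adjusted p strictly below `padj_threshold` and log2 fold
#' change strictly beyond `lfc_threshold` in the requested direction
#' (`"up"`: log2fc > threshold; `"down"`: log2fc < -threshold; `"both"`:
#' |log2fc| > threshold).
#'
#' @param results DE tibble from [differential_expression()].
#' @param lfc_threshold Log2 fold-change threshold (strict).
#' @param padj_threshold Adjusted-p threshold (strict).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return Character vector of gene identifiers.
#' @export
select_de_genes <- function(results, lfc_threshold, padj_threshold,
                            direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (!is.finite(lfc_threshold) || !is.finite(padj_threshold)) {
    abort("thresholds must be finite.")
  }
  keep_fc <- switch(direction,
    up = results$log2fc > lfc_threshold,
    down = results$log2fc < -lfc_threshold,
    both = abs(results$log2fc) > lfc_threshold)
  results$gene[keep_fc & results$padj < padj_threshold]
}

#' Hypergeometric over-representation of a gene list in term sets
#'
#' For each term with K background members, a list of n genes containing k
#' of them scores `p = P(X >= k)` under `X ~ Hypergeometric(N, K, n)` on a
#' background of N genes. Gene ratio `k/n` and background ratio `K/N` are
#' reported both numerically and as the conventional `"k/n"` strings. BH
#' adjustment runs across all terms in the call; results are sorted by p.
#'
#' @param gene_list Character vector of query genes (non-empty).
#' @param background Character vector: the gene universe.
#' @param term_sets Named list of character vectors (e.g. [read_gmt()]).
#' @return A tibble `term`, `description`, `k`, `n`, `K`, `N`,
#'   `gene_ratio`, `bg_ratio`, `gene_ratio_num`, `bg_ratio_num`, `p`,
#'   `padj`.
#' @export
hypergeom_enrichment <- function(gene_list, background, term_sets) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (length(gene_list) == 0) abort("gene_list is empty.")
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) not in the background were dropped.",
                 length(outside)))
    gene_list <- intersect(gene_list, background)
    if (length(gene_list) == 0) abort("gene_list is empty after background intersection.")
  }
  desc <- attr(term_sets, "descriptions") %||% setNames(names(term_sets), names(term_sets))
  N <- length(background)
  n <- length(gene_list)
  out <- purrr::imap_dfr(term_sets, function(members, nm) {
    members <- intersect(unique(members), background)
    K <- length(members)
    if (K == 0) {
      inform(sprintf("term '%s' has no background members; skipped.", nm))
      return(NULL)
    }
    k <- length(intersect(gene_list, members))
    tibble::tibble(term = nm, description = desc[[nm]] %||% nm,
                   k = k, n = n, K = K, N = N,
                   p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (is.null(out) || nrow(out) == 0) abort("no testable terms.")
  out <- dplyr::mutate(out,
    gene_ratio = sprintf("%d/%d", .data$k, .data$n),
    bg_ratio = sprintf("%d/%d", .data$K, .data$N),
    gene_ratio_num = .data$k / .data$n,
    bg_ratio_num = .data$K / .data$N,
    padj = p.adjust(.data$p, method = "BH"))
  dplyr::arrange(
    out[c("term", "description", "k", "n", "K", "N", "gene_ratio", "bg_ratio",
          "gene_ratio_num", "bg_ratio_num", "p", "padj")],
    .data$p)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Standard step-up BH (monotone, capped at 1) via [stats::p.adjust()],
#' rejecting p-values outside `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}
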