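#' Collapse methylation probes to gene-level beta values
#'
#' Gene beta = arithmetic mean of the gene's probe betas per sample (the
#' mean normalized beta). Probes with no map entry raise an error listing
#' the offenders; probes mapped to `NA` genes are dropped.
#'
#' @param beta Probe x sample tibble (first column `probe`, values in
#'   `[0, 1]`).
#' @param probe_map Tibble `probe`, `gene`.
#' @return A gene x sample tibble of mean betas (first column `gene`).
#' @export
collapse_probes <- function(beta, probe_map) {
  unmapped <- setdiff(beta$probe, probe_map$probe)
  if (length(unmapped)) {
    abort(paste0("probes without a map entry: ",
                 paste(head(unmapped, 10), collapse = ", "),
                 if (length(unmapped) > 10) ", ..."))
  }
  long <- dplyr::inner_join(
    tidyr::pivot_longer(beta, -"probe", names_to = "sample", values_to = "beta"),
    probe_map, by = "probe")
  long <- long[!is.na(long$gene), ]
  out <- long |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(beta = mean(.data$beta), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "beta")
  samples <- setdiff(names(beta), "probe")
  tibble::as_tibble(out[c("gene", samples)])
}

#' Select the most variable genes
#'
#' Top `n` genes by median absolute deviation of the (log2) values across
#' samples; `statistic = "aad"` switches to the mean absolute deviation
#' about the mean. Ties are broken by gene identifier, so the selection is
#' deterministic.
#'
#' @param mat Gene x sample tibble (pass log2 counts for expression).
#' @param n Number of genes to keep.
#' @param statistic `"mad"` (median absolute deviation, default) or
#'   `"aad"` (mean absolute deviation).
#' @return Character vector of `n` gene identifiers.
#' @export
most_variable_genes <- function(mat, n, statistic = c("mad", "aad")) {
  statistic <- match.arg(statistic)
  m <- counts_matrix(mat)
  if (n > nrow(m)) abort("n exceeds the number of genes.")
  v <- switch(statistic,
    mad = apply(m, 1, mad),
    aad = apply(m, 1, function(x) mean(abs(x - mean(x)))))
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

classify_axis <- function(rho, gate, concordant_sign) {
  dplyr::case_when(
    is.na(rho) ~ "undetermined",
    abs(rho) < gate ~ "negligible",
    sign(rho) == concordant_sign ~ "concordant",
    TRUE ~ "discordant")
}

#' Per-gene concordance of copy number and methylation with expression
#'
#' Spearman correlations of gene-level CN log2 ratio and gene-level beta
#' with log2 expression across shared samples. A correlation passes the
#' gate when `|rho| >= gate`; copy number is concordant when positive,
#' methylation when negative. The overall class is the single passing
#' axis, `mixed` when both pass, `undetermined` when neither does.
#'
#' @param expr Log2 expression tibble.
#' @param cn Gene-level CN tibble ([genes_from_segments()]).
#' @param meth Gene-level beta tibble ([collapse_probes()]).
#' @param gate Correlation gate (default 0.3).
#' @param min_samples Minimum shared samples (default 5).
#' @return A tibble `gene`, `rho_cn_expr`, `rho_meth_expr`, `cn_class`,
#'   `meth_class`, `class`.
#' @export
gene_correlations <- function(expr, cn, meth, gate = 0.3, min_samples = 5) {
  samples <- Reduce(intersect, list(sample_cols(expr), sample_cols(cn),
                                    sample_cols(meth)))
  if (length(samples) < min_samples) abort("too few shared samples.")
  genes <- Reduce(intersect, list(expr$gene, cn$gene, meth$gene))
  em <- counts_matrix(expr)[genes, samples, drop = FALSE]
  cm <- counts_matrix(cn)[genes, samples, drop = FALSE]
  mm <- counts_matrix(meth)[genes, samples, drop = FALSE]
  spear <- function(x, y) {
    if (anyNA(x) || anyNA(y) || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }
  rho_cn <- vapply(seq_along(genes), function(i) spear(cm[i, ], em[i, ]), 0)
  rho_me <- vapply(seq_along(genes), function(i) spear(mm[i, ], em[i, ]), 0)
  cn_class <- classify_axis(rho_cn, gate, 1)
  meth_class <- classify_axis(rho_me, gate, -1)
  class <- dplyr::case_when(
    cn_class %in% c("concordant", "discordant") &
      meth_class %in% c("concordant", "discordant") ~ "mixed",
    cn_class == "concordant" ~ "cn_concordant",
    cn_class == "discordant" ~ "cn_discordant",
    meth_class == "concordant" ~ "meth_concordant",
    meth_class == "discordant" ~ "meth_discordant",
    TRUE ~ "undetermined")
  tibble::tibble(gene = genes, rho_cn_expr = rho_cn, rho_meth_expr = rho_me,
                 cn_class = cn_class, meth_class = meth_class, class = class)
}

# Deterministic leaf order for an hclust tree: at each merge, the subtree
# containing the lexicographically smallest label goes left.
deterministic_leaf_order <- function(hc) {
  labels <- hc$labels
  walk <- function(node) {
    if (node < 0) return(-node)
    left <- walk(hc$merge[node, 1])
    right <- walk(hc$merge[node, 2])
    if (min(labels[left]) <= min(labels[right])) c(left, right) else c(right, left)
  }
  labels[walk(nrow(hc$merge))]
}

#' Agglomerative clustering with a deterministic leaf order
#'
#' Complete-linkage hierarchical clustering over rows (`items = "genes"`)
#' or columns (`items = "samples"`) of a gene-keyed table, with Euclidean
#' or 1 - Pearson distance. The leaf order is made deterministic by
#' placing, at every merge, the subtree containing the lexicographically
#' smallest item on the left.
#'
#' @param mat Gene x sample tibble.
#' @param items Cluster `"samples"` (columns, default) or `"genes"`
#'   (rows).
#' @param distance `"one_minus_pearson"` (default for samples) or
#'   `"euclidean"`.
#' @param linkage Agglomeration method (default `"complete"`).
#' @return A `spatialith_dendro` object: the `hclust` fit, `labels`, and
#'   the deterministic `leaf_order`.
#' @export
build_dendrogram <- function(mat, items = c("samples", "genes"),
                             distance = c("one_minus_pearson", "euclidean"),
                             linkage = "complete") {
  items <- match.arg(items)
  distance <- match.arg(distance)
  m <- counts_matrix(mat)
  if (items == "samples") m <- t(m)
  if (anyNA(m)) abort("matrix contains missing values; impute or drop first.")
  if (nrow(m) < 2) abort("need at least 2 items to cluster.")
  d <- if (distance == "one_minus_pearson") cor_distance(m) else dist(m)
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, labels = hc$labels,
                 leaf_order = deterministic_leaf_order(hc),
                 distance = distance, linkage = linkage),
            class = "spatialith_dendro")
}

leaf_order_of <- function(tree) {
  if (inherits(tree, "spatialith_dendro")) return(tree$leaf_order)
  if (inherits(tree, "hclust")) return(tree$labels[tree$order])
  if (is.character(tree)) return(tree)
  abort("expected a spatialith_dendro, hclust, or a character leaf order.")
}

# All leaf orders reachable by flipping internal branches of an hclust.
all_flip_orders <- function(hc) {
  labels <- hc$labels
  rec <- function(node) {
    if (node < 0) return(list(-node))
    L <- rec(hc$merge[node, 1]); R <- rec(hc$merge[node, 2])
    out <- list()
    for (l in L) for (r in R) out <- c(out, list(c(l, r)), list(c(r, l)))
    out
  }
  lapply(rec(nrow(hc$merge)), function(idx) labels[idx])
}

#' Entanglement between two dendrogram leaf orders
#'
#' With rank vectors `r_A`, `r_B` of the shared leaves in each tree's leaf
#' order, entanglement is `sum(|r_A - r_B|^L)` normalized by its maximum —
#' the value attained by an order against its exact reversal — so it is 0
#' for identical orders and 1 for a reversal. With `untangle = TRUE`
#' (trees of at most 12 leaves), every branch-flip of the second tree is
#' searched exhaustively for the minimum.
#'
#' @param tree_a,tree_b `spatialith_dendro` objects, `hclust` fits, or
#'   plain character leaf orders over the same leaf set.
#' @param L Rank-difference exponent (default 1.5).
#' @param untangle Exhaustive branch-flip minimization over `tree_b`
#'   (default FALSE; requires a tree, not a plain order).
#' @return An `entanglement_result` tibble with `entanglement`, `L`,
#'   `n_leaves` (leaf orders in attributes).
#' @export
entanglement <- function(tree_a, tree_b, L = 1.5, untangle = FALSE) {
  ord_a <- leaf_order_of(tree_a)
  ord_b <- leaf_order_of(tree_b)
  if (!setequal(ord_a, ord_b)) abort("trees have different leaf sets.")
  n <- length(ord_a)
  max_val <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  score <- function(ob) {
    r_a <- seq_len(n)
    r_b <- match(ord_a, ob)
    sum(abs(r_a - r_b)^L) / max_val
  }
  ent <- score(ord_b)
  if (untangle) {
    if (n > 12) abort("exhaustive untangling is limited to 12 leaves.")
    hc_b <- if (inherits(tree_b, "spatialith_dendro")) tree_b$hclust
            else if (inherits(tree_b, "hclust")) tree_b
            else abort("untangle needs tree_b to be a tree, not a plain order.")
    ent <- min(vapply(all_flip_orders(hc_b), score, 0))
  }
  out <- tibble::tibble(entanglement = ent, L = L, n_leaves = n)
  attr(out, "leaf_order_a") <- ord_a
  attr(out, "leaf_order_b") <- ord_b
  class(out) <- c("entanglement_result", class(out))
  out
}

#' Cross-modality tanglegram report
#'
#' Builds a sample dendrogram per data type (1 - Pearson distance,
#' complete linkage), computes all pairwise entanglements, and — given
#' immune categories — the fraction of k-cut clusters per modality that
#' mix at least two distinct immune categories (label dispersion).
#'
#' @param expr,cn,meth Gene-keyed tibbles sharing sample columns.
#' @param immune_labels Optional tibble `region_id`/`sample`,
#'   `immune_category`.
#' @param k Cluster count for the dispersion cut (default 4).
#' @return A list: `entanglement` tibble (`modality_a`, `modality_b`,
#'   `entanglement`), `memberships` (sample x modality cluster ids),
#'   `dispersion` (per modality), `trees`.
#' @export
tangle_report <- function(expr, cn, meth, immune_labels = NULL, k = 4) {
  mats <- list(expression = expr, copy_number = cn, methylation = meth)
  samples <- Reduce(intersect, lapply(mats, sample_cols))
  if (length(samples) < 3) abort("need at least 3 shared samples.")
  mats <- lapply(mats, function(m) {
    m <- m[c("gene", samples)]
    m[stats::complete.cases(m[samples]), ]
  })
  trees <- lapply(mats, build_dendrogram, items = "samples")
  pairs <- combn(names(mats), 2)
  ent <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(modality_a = a, modality_b = b,
                   entanglement = entanglement(trees[[a]], trees[[b]])$entanglement)
  })
  memberships <- purrr::imap_dfr(trees, function(tr, nm) {
    cl <- cutree(tr$hclust, k = k)
    tibble::tibble(sample = names(cl), modality = nm, cluster = unname(cl))
  })
  dispersion <- NULL
  if (!is.null(immune_labels)) {
    key <- if ("region_id" %in% names(immune_labels)) "region_id" else "sample"
    lab <- setNames(as.character(immune_labels$immune_category),
                    immune_labels[[key]])
    dispersion <- memberships |>
      dplyr::mutate(immune = lab[.data$sample]) |>
      dplyr::group_by(.data$modality, .data$cluster) |>
      dplyr::summarise(mixed = dplyr::n_distinct(.data$immune) >= 2,
                       .groups = "drop_last") |>
      dplyr::summarise(dispersion = mean(.data$mixed), .groups = "drop")
  }
  list(entanglement = ent, memberships = memberships,
       dispersion = dispersion, trees = trees)
}
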