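# Variant tables key on `mutation_id` x `region_id`; accept `sample` as a
# synonym for the region column.
normalize_variant_cols <- function(calls) {
  if (!"region_id" %in% names(calls) && "sample" %in% names(calls)) {
    calls <- dplyr::rename(calls, region_id = "sample")
  }
  calls
}

#' Power-filter mutations into a binary presence matrix
#'
#' Keeps mutations whose detection power reaches `power_threshold`
#' (inclusive) in every region where they were assessed; presence is then
#' the passing call. Mutations with a missing power value anywhere are
#' flagged and excluded with a note.
#'
#' @param calls Variant tibble with `mutation_id`, `region_id` (or
#'   `sample`), `present`, `power`.
#' @param power_threshold Minimum detection power (default 0.8,
#'   inclusive).
#' @return A mutation x region binary tibble (first column `mutation_id`);
#'   excluded mutations are listed in the `"excluded"` attribute.
#' @export
power_filter <- function(calls, power_threshold = 0.8) {
  calls <- normalize_variant_cols(calls)
  if (!"power" %in% names(calls)) abort("calls need a `power` column.")
  by_mut <- dplyr::summarise(dplyr::group_by(calls, .data$mutation_id),
                             any_na = anyNA(.data$power),
                             min_power = suppressWarnings(min(.data$power, na.rm = TRUE)),
                             .groups = "drop")
  flagged <- by_mut$mutation_id[by_mut$any_na]
  if (length(flagged)) {
    inform(paste0("mutation(s) with missing power excluded: ",
                  paste(flagged, collapse = ", ")))
  }
  keep <- by_mut$mutation_id[!by_mut$any_na & by_mut$min_power >= power_threshold]
  wide <- calls |>
    dplyr::filter(.data$mutation_id %in% keep) |>
    dplyr::mutate(presence = as.integer(.data$present)) |>
    tidyr::pivot_wider(id_cols = "mutation_id", names_from = "region_id",
                       values_from = "presence", values_fill = 0L)
  attr(wide, "excluded") <- flagged
  wide
}

#' Neoantigen-grade variant filter
#'
#' Strict inequalities on all five conditions: tumor read count > 30,
#' normal read count > 10, tumor VAF > 0.05, normal VAF < 0.01, tumor
#' power > 0.8. Rows with a missing field fail with the reason recorded.
#'
#' @param calls Variant tibble with `tumor_count`, `normal_count`,
#'   `tumor_vaf`, `normal_vaf`, `power`.
#' @return The input with logical `pass` and character `fail_reason`
#'   columns appended.
#' @export
neoantigen_variant_filter <- function(calls) {
  need <- c("tumor_count", "normal_count", "tumor_vaf", "normal_vaf", "power")
  miss <- setdiff(need, names(calls))
  if (length(miss)) abort(paste0("calls missing columns: ", paste(miss, collapse = ", ")))
  checks <- list(
    tumor_count = calls$tumor_count > 30,
    normal_count = calls$normal_count > 10,
    tumor_vaf = calls$tumor_vaf > 0.05,
    normal_vaf = calls$normal_vaf < 0.01,
    power = calls$power > 0.8
  )
  fail <- vapply(seq_len(nrow(calls)), function(i) {
    bad <- names(checks)[vapply(checks, function(x) is.na(x[i]) || !x[i], TRUE)]
    paste(bad, collapse = ",")
  }, "")
  dplyr::mutate(calls, pass = !nzchar(fail),
                fail_reason = dplyr::na_if(fail, ""))
}

#' Call predicted neoantigens from peptide-binding predictions
#'
#' Keeps peptides with predicted IC50 strictly below 500 nM that are
#' expressed (FPKM strictly above 1) with RNA support (alternate allele
#' count strictly above 4), and reports each mutation's best (minimum)
#' IC50. Binding affinities are consumed as input; no predictor is
#' embedded.
#'
#' @param predictions Tibble `mutation_id`, `peptide`, `ic50`, `fpkm`,
#'   `rna_alt_count` (optionally `wt_ic50`).
#' @param ic50_max,fpkm_min,alt_min Strict thresholds (defaults 500, 1,
#'   4).
#' @return A list: `peptides` (passing rows) and `per_mutation` (best
#'   IC50 per neoantigen-positive mutation).
#' @export
call_neoantigens <- function(predictions, ic50_max = 500, fpkm_min = 1,
                             alt_min = 4) {
  pass <- predictions$ic50 < ic50_max & predictions$fpkm > fpkm_min &
    predictions$rna_alt_count > alt_min
  peptides <- predictions[pass & !is.na(pass), , drop = FALSE]
  per_mutation <- peptides |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(best_ic50 = min(.data$ic50), n_peptides = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$best_ic50)
  list(peptides = tibble::as_tibble(peptides), per_mutation = per_mutation)
}

#' Mutation sharing spectrum
#'
#' Per-mutation region counts from a binary presence matrix, summarized
#' as ubiquitous (all regions), private (exactly one) and intermediate
#' fractions.
#'
#' @param matrix Mutation x region binary tibble (first column
#'   `mutation_id`).
#' @return A list: `per_mutation` (`mutation_id`, `n_regions`, `class`)
#'   and `summary` (counts and fractions).
#' @export
mutation_sharing <- function(matrix) {
  m <- as.matrix(matrix[setdiff(names(matrix), "mutation_id")])
  if (ncol(m) < 2) abort("sharing needs at least 2 regions.")
  if (!all(m %in% c(0, 1))) abort("presence matrix must be binary.")
  n_regions <- rowSums(m)
  per_mutation <- tibble::tibble(
    mutation_id = matrix$mutation_id, n_regions = as.integer(n_regions),
    class = dplyr::case_when(n_regions == ncol(m) ~ "ubiquitous",
                             n_regions == 1 ~ "private",
                             TRUE ~ "intermediate"))
  summary <- per_mutation |>
    dplyr::count(.data$class, name = "n_mutations") |>
    tidyr::complete(class = c("ubiquitous", "intermediate", "private"),
                    fill = list(n_mutations = 0L)) |>
    dplyr::mutate(fraction = .data$n_mutations / sum(.data$n_mutations))
  list(per_mutation = per_mutation, summary = summary, n_regions_total = ncol(m))
}

#' Hamming distances between samples over a binary mutation matrix
#'
#' `d(i, j)` is the number of mutations whose presence differs between
#' samples i and j.
#'
#' @param matrix Mutation x region binary tibble (first column
#'   `mutation_id`).
#' @return A symmetric integer matrix with zero diagonal.
#' @export
hamming_distances <- function(matrix) {
  m <- as.matrix(matrix[setdiff(names(matrix), "mutation_id")])
  if (!all(m %in% c(0, 1))) abort("matrix must be binary (0/1).")
  # pairs differ where exactly one of the two entries is 1
  d <- crossprod(m, 1 - m) + crossprod(1 - m, m)
  storage.mode(d) <- "integer"
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with the Q-matrix (Studier-Keppler)
#' criterion. Ties in Q are broken by the lexicographically smallest label
#' pair; negative branch lengths are clamped to zero with a note. Three
#' taxa resolve by the three-point formulas.
#'
#' @param distances Symmetric numeric matrix with labeled rows/columns and
#'   zero diagonal (at least 3 taxa).
#' @return An unrooted `phylo` tree (class from the ape package).
#' @export
neighbor_joining <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa.")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  labs <- rownames(d)
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-9)) {
    abort("distance matrix must be symmetric with a zero diagonal.")
  }
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  # Each active node carries its Newick subtree string; pick the joined
  # pair by minimal Q, ties by the sorted label pair.
  nwk <- setNames(labs, labs)
  key <- setNames(labs, labs)   # lexicographically smallest leaf of each subtree
  act <- labs
  while (length(act) > 3) {
    N <- length(act)
    dm <- d[act, act]
    r <- rowSums(dm)
    q <- (N - 2) * dm - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij) {
      paste(sort(c(key[act[ij[1]]], key[act[ij[2]]])), collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    li <- clamp(dm[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2)))
    lj <- clamp(dm[i, j] - (dm[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))))
    u <- paste0("u", length(act))
    others <- setdiff(act, c(i, j))
    du <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- u
    d[u, others] <- du; d[others, u] <- du
    nwk[u] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    key[u] <- min(key[i], key[j])
    act <- c(others, u)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((d[a, b] + d[a, c3] - d[b, c3]) / 2)
  lb <- clamp((d[a, b] + d[b, c3] - d[a, c3]) / 2)
  lc <- clamp((d[a, c3] + d[b, c3] - d[a, b]) / 2)
  ord <- order(c(key[a], key[b], key[c3]))
  parts <- sprintf("%s:%.10g", nwk[c(a, b, c3)], c(la, lb, lc))[ord]
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  if (clamped) inform("negative branch length(s) clamped to 0.")
  tree
}

# Non-trivial bipartitions of an unrooted tree, canonicalized to the side
# not containing the alphabetically first tip.
tree_splits <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  sets <- lapply(pp, function(i) labs[i])
  canon <- lapply(sets, function(s) {
    if (ref %in% s) sort(setdiff(labs, s)) else sort(s)
  })
  keys <- vapply(canon, paste, "", collapse = "|")
  sizes <- lengths(canon)
  unique(keys[sizes >= 2 & sizes <= length(labs) - 2])
}

#' Bootstrap support for a neighbor-joining mutation tree
#'
#' Resamples mutations (characters) with replacement B times, rebuilds the
#' Hamming + neighbor-joining tree each time, and reports the percentage
#' of replicates containing each internal split of the original tree.
#'
#' @param matrix Mutation x region binary tibble.
#' @param B Bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @return A list: `tree` (the original `phylo` with `node.label` set to
#'   supports where applicable), `splits` tibble (`split`, `support`),
#'   `B`.
#' @export
bootstrap_support <- function(matrix, B = 100, seed = 1) {
  tree <- neighbor_joining(hamming_distances(matrix))
  if (length(tree$tip.label) < 4) abort("bootstrap support needs at least 4 samples.")
  orig <- tree_splits(tree)
  counts <- setNames(rep(0L, length(orig)), orig)
  rows <- seq_len(nrow(matrix))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      res <- matrix[sample(rows, replace = TRUE), , drop = FALSE]
      rep_tree <- neighbor_joining(hamming_distances(res))
      hit <- intersect(orig, tree_splits(rep_tree))
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- 100 * counts / B
  splits <- tibble::tibble(split = names(support), support = unname(support))
  # attach supports as internal node labels where a node defines the split
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  nn <- tree$Nnode
  node_lab <- rep("", nn)
  pp <- ape::prop.part(tree)
  for (i in seq_along(pp)) {
    s <- labs[pp[[i]]]
    k <- if (ref %in% s) paste(sort(setdiff(labs, s)), collapse = "|") else
      paste(sort(s), collapse = "|")
    hit <- match(k, names(support))
    if (!is.na(hit)) node_lab[i] <- format(support[hit])
  }
  tree$node.label <- node_lab
  list(tree = tree, splits = splits, B = B)
}

#' Truncal mutation VAF matrix
#'
#' Extracts the VAFs of a designated truncal mutation set across all
#' regions, erroring (by name) if any supposed truncal mutation is absent
#' from a region.
#'
#' @param calls Variant tibble with `mutation_id`, `region_id` (or
#'   `sample`), `present`, `tumor_vaf`.
#' @param truncal_ids Character vector of truncal mutation ids.
#' @return A mutation x region tibble of VAFs (first column
#'   `mutation_id`), no missing entries.
#' @export
truncal_vaf_table <- function(calls, truncal_ids) {
  calls <- normalize_variant_cols(calls)
  sub <- calls[calls$mutation_id %in% truncal_ids, ]
  absent <- sub |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(ok = all(.data$present), .groups = "drop")
  missing_ids <- union(setdiff(truncal_ids, sub$mutation_id),
                       absent$mutation_id[!absent$ok])
  if (length(missing_ids)) {
    abort(paste0("not truncal (absent in some region): ",
                 paste(sort(missing_ids), collapse = ", ")))
  }
  tidyr::pivot_wider(sub[c("mutation_id", "region_id", "tumor_vaf")],
                     names_from = "region_id", values_from = "tumor_vaf")
}
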