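#' Euclidean distance between samples over signature scores
#'
#' Rows (samples) with any missing score are dropped with a warning.
#'
#' @param scores Long score tibble (`sample`, `signature`, `score`) or a
#'   wide data frame with a `sample` column.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
immune_distance_matrix <- function(scores) {
  wide <- if (all(c("signature", "score") %in% names(scores))) {
    tidyr::pivot_wider(scores[c("sample", "signature", "score")],
                       names_from = "signature", values_from = "score")
  } else scores
  m <- as.matrix(wide[setdiff(names(wide), "sample")])
  rownames(m) <- wide$sample
  ok <- complete.cases(m)
  if (any(!ok)) {
    warn(sprintf("%d sample(s) with missing scores dropped.", sum(!ok)))
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 samples with complete scores.")
  as.matrix(dist(m))
}

#' Link sample pairs in the top quartile of similarity
#'
#' Similarity is negative distance; pairs at or above the empirical 75th
#' percentile of pair similarities are linked (ties included), so the edge
#' set is invariant under any strictly decreasing transform of distance.
#'
#' @param dist_matrix Symmetric distance matrix
#'   (e.g. [immune_distance_matrix()]).
#' @return A `spatialith_network`: tibble `from`, `to`, `distance`,
#'   `similarity`, `linked`, with the cutoff in the `"cutoff"` attribute.
#' @export
top_quartile_links <- function(dist_matrix) {
  n <- nrow(dist_matrix)
  pairs <- which(upper.tri(dist_matrix), arr.ind = TRUE)
  if (nrow(pairs) < 4) abort("need at least 4 unordered pairs.")
  edges <- tibble::tibble(
    from = rownames(dist_matrix)[pairs[, 1]],
    to = colnames(dist_matrix)[pairs[, 2]],
    distance = dist_matrix[pairs],
    similarity = -dist_matrix[pairs]
  )
  cutoff <- quantile(edges$similarity, 0.75, names = FALSE)
  edges$linked <- edges$similarity >= cutoff
  if (all(edges$linked)) warn("all distances equal; every pair is linked.")
  structure(dplyr::arrange(edges, dplyr::desc(.data$similarity)),
            cutoff = cutoff, class = c("spatialith_network", class(edges)))
}

#' Map per-region scores onto the section grids
#'
#' Returns one row per occupied grid cell per section with the region's
#' score (`NA` where a region was not scored); no interpolation is
#' performed.
#'
#' @param scores Tibble `region_id`, `score` (or a named numeric vector).
#' @param regions Region table with `region_id`, `section`, `x`, `y`.
#' @return A `spatialith_surface` tibble `section`, `x`, `y`, `region_id`,
#'   `score`.
#' @export
map_surface <- function(scores, regions) {
  if (!is.data.frame(scores)) {
    scores <- tibble::tibble(region_id = names(scores), score = unname(scores))
  }
  unknown <- setdiff(scores$region_id, regions$region_id)
  if (length(unknown)) {
    abort(paste0("scores reference unknown region(s): ",
                 paste(unknown, collapse = ", ")))
  }
  out <- dplyr::left_join(regions[c("section", "x", "y", "region_id")],
                          scores[c("region_id", "score")], by = "region_id")
  structure(out, class = c("spatialith_surface", class(out)))
}

#' Test over-representation of immune-high regions at the tumor margin
#'
#' Builds the 2x2 table (immune high vs not high) x (margin vs core) and
#' applies a two-sided Fisher exact test (point-probability rule). A zero
#' row or column total yields p = 1 with a note.
#'
#' @param regions Region table with `location` (`core`/`margin`) and
#'   `immune_category` (`low`/`medium`/`high`).
#' @return A one-row tibble with the table cells, `odds_ratio` and `p`;
#'   the 2x2 matrix rides in the `"table"` attribute.
#' @export
margin_enrichment_test <- function(regions) {
  if (!all(c("location", "immune_category") %in% names(regions))) {
    abort("regions need `location` and `immune_category` columns.")
  }
  high <- factor(regions$immune_category == "high", levels = c(TRUE, FALSE),
                 labels = c("high", "not_high"))
  loc <- factor(regions$location, levels = c("margin", "core"))
  tab <- table(high, loc)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    inform("degenerate 2x2 table (a zero margin); p set to 1.")
    p <- 1; or <- NA_real_
  } else {
    ht <- fisher.test(tab)
    p <- ht$p.value; or <- unname(ht$estimate)
  }
  out <- tibble::tibble(
    high_margin = tab["high", "margin"], high_core = tab["high", "core"],
    nothigh_margin = tab["not_high", "margin"], nothigh_core = tab["not_high", "core"],
    odds_ratio = or, p = p
  )
  attr(out, "table") <- tab
  out
}

# 1 - Pearson correlation distance between rows of a matrix.
cor_distance <- function(m) as.dist(1 - stats::cor(t(m)))

#' Consensus clustering with delta-area model selection
#'
#' Repeated subsampling (fraction `resample_fraction` of samples, without
#' replacement), hierarchical clustering (1 - Pearson distance, complete
#' linkage by default) cut at each k in `2..kmax`. The consensus of a
#' sample pair at k is its co-clustering rate among resamples containing
#' both. `A(k)` is the area under the empirical CDF of consensus values;
#' `delta(2) = A(2)` and `delta(k) = (A(k) - A(k-1)) / A(k-1)` for k > 2.
#'
#' @param features Sample x feature numeric matrix, or a data frame with a
#'   `sample` column.
#' @param kmax Maximum cluster count (default 20).
#' @param resample_fraction Subsample fraction (default 0.8).
#' @param B Number of resamples (default 500).
#' @param seed RNG seed.
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @return A `consensus_clustering` object: consensus matrices per k,
#'   `area` tibble (`k`, `A`, `delta`), chosen `k_opt`, and `assignments`
#'   at `k_opt`.
#' @export
consensus_cluster <- function(features, kmax = 20, resample_fraction = 0.8,
                              B = 500, seed = 1,
                              distance = c("one_minus_pearson", "euclidean")) {
  distance <- match.arg(distance)
  if (is.data.frame(features)) {
    m <- as.matrix(features[setdiff(names(features), "sample")])
    rownames(m) <- features$sample %||% rownames(features)
  } else m <- as.matrix(features)
  n <- nrow(m)
  if (n < kmax + 2) abort("need at least kmax + 2 samples.")
  if (B < 1) abort("B must be at least 1.")
  ks <- 2:kmax
  hits <- array(0L, c(n, n, length(ks)))
  both <- matrix(0L, n, n)
  ns <- ceiling(resample_fraction * n)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sort(sample.int(n, ns))
      sub <- m[idx, , drop = FALSE]
      d <- if (distance == "one_minus_pearson") cor_distance(sub) else dist(sub)
      hc <- hclust(d, method = "complete")
      cuts <- cutree(hc, k = ks)
      both[idx, idx] <- both[idx, idx] + 1L
      for (j in seq_along(ks)) {
        co <- outer(cuts[, j], cuts[, j], "==")
        hits[idx, idx, j] <- hits[idx, idx, j] + co
      }
    }
  })
  if (any(both[upper.tri(both)] == 0)) {
    warn("some sample pairs were never co-sampled; their consensus is missing.")
  }
  consensus <- lapply(seq_along(ks), function(j) {
    cm <- hits[, , j] / ifelse(both == 0, NA, both)
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(m), rownames(m))
    cm
  })
  names(consensus) <- paste0("k", ks)
  A <- vapply(consensus, function(cm) consensus_cdf_area(cm), 0)
  delta <- c(A[1], diff(A) / A[-length(A)])
  area <- tibble::tibble(k = ks, A = unname(A), delta = unname(delta))
  k_opt <- optimal_k(area)
  full_d <- if (distance == "one_minus_pearson") cor_distance(m) else dist(m)
  hc_full <- hclust(full_d, method = "complete")
  assignments <- tibble::tibble(sample = rownames(m),
                                cluster = unname(cutree(hc_full, k = k_opt)))
  structure(list(consensus = consensus, area = area, k_opt = k_opt,
                 assignments = assignments, kmax = kmax, B = B,
                 resample_fraction = resample_fraction, distance = distance),
            class = "consensus_clustering")
}

# Area under the empirical CDF of off-diagonal consensus values, computed
# over sorted unique values (pairs never co-sampled are excluded).
consensus_cdf_area <- function(cm) {
  v <- cm[upper.tri(cm)]
  v <- v[!is.na(v)]
  x <- sort(unique(c(0, v, 1)))
  F <- ecdf(v)(x)
  sum(diff(x) * F[-length(F)])
}

#' Choose the cluster number from the delta-area curve
#'
#' The chosen k is the largest k whose relative consensus-area increase
#' `delta(k)` still reaches `flatten_threshold`; if none does, k = 2.
#' This makes the usual by-eye reading of the delta-area plot
#' deterministic.
#'
#' @param delta_areas Tibble with columns `k` and `delta` (as in
#'   `consensus_cluster()$area`), or a numeric delta vector for k = 2...
#' @param flatten_threshold Minimum relative increase (default 0.1).
#' @return The chosen integer k.
#' @export
optimal_k <- function(delta_areas, flatten_threshold = 0.1) {
  if (is.data.frame(delta_areas)) {
    k <- delta_areas$k; delta <- delta_areas$delta
  } else {
    delta <- delta_areas; k <- seq_along(delta) + 1L
  }
  keep <- which(delta >= flatten_threshold)
  if (length(keep) == 0) return(2L)
  as.integer(max(k[keep]))
}

# Adjacency among regions: 4-neighborhood within a section plus identical
# (x, y) in adjacent sections (cross-section adjacency is approximate
# because each slice is gridded independently).
region_adjacency <- function(regions) {
  n <- nrow(regions)
  adj <- matrix(FALSE, n, n, dimnames = list(regions$region_id, regions$region_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_sec <- regions$section[i] == regions$section[j]
      manh <- abs(regions$x[i] - regions$x[j]) + abs(regions$y[i] - regions$y[j])
      near_sec <- abs(regions$section[i] - regions$section[j]) == 1
      if ((same_sec && manh == 1) || (near_sec && manh == 0)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

#' Spatial contiguity of cluster assignments
#'
#' Per cluster: the fraction of member regions with at least one
#' same-cluster 4-neighbor, and whether the cluster forms a single
#' connected component under within-section 4-adjacency plus same-(x,y)
#' adjacency across neighboring sections. Singleton clusters are
#' contiguous by convention and flagged.
#'
#' @param assignments Tibble `region_id` (or `sample`), `cluster`.
#' @param regions Region table with coordinates.
#' @return A tibble `cluster`, `size`, `neighbor_fraction`, `contiguous`,
#'   `n_components`, `singleton`.
#' @export
cluster_contiguity <- function(assignments, regions) {
  if ("sample" %in% names(assignments) && !"region_id" %in% names(assignments)) {
    assignments <- dplyr::rename(assignments, region_id = "sample")
  }
  missing <- setdiff(assignments$region_id, regions$region_id)
  if (length(missing)) {
    abort(paste0("assigned regions lack coordinates: ", paste(missing, collapse = ", ")))
  }
  regions <- regions[match(assignments$region_id, regions$region_id), ]
  adj <- region_adjacency(regions)
  purrr::map_dfr(sort(unique(assignments$cluster)), function(cl) {
    members <- which(assignments$cluster == cl)
    size <- length(members)
    if (size == 1) {
      return(tibble::tibble(cluster = cl, size = 1L, neighbor_fraction = 1,
                            contiguous = TRUE, n_components = 1L,
                            singleton = TRUE))
    }
    sub <- adj[members, members, drop = FALSE]
    frac <- mean(rowSums(sub) > 0)
    # connected components by breadth-first search
    comp <- rep(NA_integer_, size); nc <- 0L
    for (s in seq_len(size)) {
      if (!is.na(comp[s])) next
      nc <- nc + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- nc
        queue <- c(queue, which(sub[v, ] & is.na(comp)))
      }
    }
    tibble::tibble(cluster = cl, size = size, neighbor_fraction = frac,
                   contiguous = nc == 1L, n_components = nc, singleton = FALSE)
  })
}
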