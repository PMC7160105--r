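test_that("immune distance matrix is plain Euclidean over score vectors", {
  scores <- tibble::tibble(
    sample = rep(c("A", "B", "C"), each = 2),
    signature = rep(c("s1", "s2"), 3),
    score = c(0, 0, 3, 4, 0, 0))
  d <- immune_distance_matrix(scores)
  expect_equal(d["A", "B"], 5)
  expect_equal(d["A", "C"], 0)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
  expect_equal(d, t(d))
  # elementwise recomputation oracle
  set.seed(2)
  wide <- tibble::tibble(sample = paste0("r", 1:6),
                         a = rnorm(6), b = rnorm(6), c = rnorm(6))
  dm <- immune_distance_matrix(wide)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(dm[i, j],
                 sqrt(sum((unlist(wide[i, -1]) - unlist(wide[j, -1]))^2)))
  }
})

test_that("top-quartile linking keeps the closest pairs, rank-invariantly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d[upper.tri(d)] <- c(1, 2, 3, 4, 5, 6)
  d <- d + t(d)
  # 6 pairs: 75th percentile of similarity keeps ~2 closest
  net <- top_quartile_links(d)
  kept <- tidy(net)
  expect_true(all(kept$distance <= sort(d[upper.tri(d)])[2]))
  net2 <- top_quartile_links(d + 10 - diag(10, 4))
  expect_equal(tidy(net2)[c("from", "to")], kept[c("from", "to")])
  # sort-and-cut oracle
  sims <- -d[upper.tri(d)]
  cutoff <- quantile(sims, 0.75, names = FALSE)
  expect_equal(nrow(kept), sum(sims >= cutoff))
  expect_warning(top_quartile_links(matrix(1, 4, 4) - diag(1, 4)), "all pairs|linked")
})

test_that("surface mapping round-trips the grid and rejects unknown regions", {
  regions <- generate_tumor_grid(sim_config(n_sections = 2, grid_dims = c(3, 3)))
  const <- tibble::tibble(region_id = regions$region_id, score = 1.5)
  surf <- map_surface(const, regions)
  expect_true(all(surf$score == 1.5))
  one <- map_surface(tibble::tibble(region_id = "1A1", score = 2), regions)
  expect_equal(sum(!is.na(one$score)), 1)
  back <- one[!is.na(one$score), c("region_id", "score")]
  expect_equal(map_surface(back, regions)$score, one$score)
  expect_error(map_surface(tibble::tibble(region_id = "9Z9", score = 1), regions),
               "unknown")
})

test_that("margin enrichment equals an exhaustive two-sided Fisher enumeration", {
  regions <- tibble::tibble(
    region_id = sprintf("r%02d", 1:20),
    location = rep(c("margin", "core"), c(9, 11)),
    immune_category = c(rep("high", 8), rep("low", 1),    # margin: 8 high, 1 not
                        rep("high", 2), rep("low", 9)))   # core: 2 high, 9 not
  res <- margin_enrichment_test(regions)
  # enumerate all tables with fixed margins; sum point probs <= observed
  tab <- attr(res, "table")
  rs <- rowSums(tab); cs <- colSums(tab)
  p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  p_two <- sum(vapply(0:min(rs[1], cs[1]), function(k) {
    pk <- dhyper(k, rs[1], rs[2], cs[1])
    if (pk <= p_obs * (1 + 1e-7)) pk else 0
  }, 0))
  expect_equal(res$p, p_two, tolerance = 1e-9)

  sep <- tibble::tibble(region_id = sprintf("r%02d", 1:20),
                        location = rep(c("margin", "core"), each = 10),
                        immune_category = rep(c("high", "low"), each = 10))
  expect_lt(margin_enrichment_test(sep)$p, 1e-4)

  degenerate <- tibble::tibble(region_id = c("a", "b", "c"),
                               location = "margin",
                               immune_category = c("high", "low", "low"))
  expect_message(out <- margin_enrichment_test(degenerate), "degenerate")
  expect_equal(out$p, 1)
})

test_that("margin test is valid (conservative) under independent labels", {
  set.seed(31)
  ps <- replicate(300, {
    regions <- tibble::tibble(
      region_id = sprintf("r%03d", 1:60),
      location = sample(c("margin", "core"), 60, TRUE),
      immune_category = sample(c("high", "medium", "low"), 60, TRUE))
    margin_enrichment_test(regions)$p
  })
  expect_lte(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("a single full-sample resample reduces consensus to co-membership", {
  blobs <- make_blobs(1, n_per = 6, k = 3, p = 20)
  cc <- consensus_cluster(blobs$x, kmax = 5, resample_fraction = 1, B = 1,
                          seed = 1)
  cm <- cc$consensus$k3
  expect_true(all(cm %in% c(0, 1)))
  d <- as.dist(1 - cor(t(blobs$x)))
  ref <- cutree(hclust(d, "complete"), 3)
  expect_equal(unname(cm), unname(outer(ref, ref, "==") + 0))
})

test_that("well-separated blobs give clean consensus and recover k", {
  blobs <- make_blobs(7, n_per = 8, k = 2, p = 30, center_sd = 5, noise_sd = 0.3)
  cc <- consensus_cluster(blobs$x, kmax = 4, B = 100, seed = 3)
  cm <- cc$consensus$k2
  within <- cm[outer(blobs$truth, blobs$truth, "==") & upper.tri(cm)]
  between <- cm[outer(blobs$truth, blobs$truth, "!=") & upper.tri(cm)]
  expect_true(all(within > 0.99, na.rm = TRUE))
  expect_true(all(between < 0.01, na.rm = TRUE))
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), setNames(rep(1, 16), rownames(blobs$x)))
})

test_that("consensus matrices converge as B doubles on a fixed instance", {
  blobs <- make_blobs(11, n_per = 7, k = 4, p = 30)
  c1 <- consensus_cluster(blobs$x, kmax = 6, B = 250, seed = 5)
  c2 <- consensus_cluster(blobs$x, kmax = 6, B = 500, seed = 6)
  fro <- sqrt(mean((c1$consensus$k4 - c2$consensus$k4)^2, na.rm = TRUE))
  expect_lt(fro, 0.05)
})

test_that("the delta-area rule picks the last k above the flattening threshold", {
  area <- tibble::tibble(k = 2:6, delta = c(0.6, 0.3, 0.15, 0.04, 0.02))
  expect_equal(optimal_k(area), 4L)
  expect_equal(optimal_k(tibble::tibble(k = 2:5, delta = rep(0.01, 4))), 2L)
  expect_equal(optimal_k(c(0.6, 0.3, 0.15, 0.04, 0.02)), 4L)
})

test_that("cluster contiguity follows 4-adjacency with a graph-component oracle", {
  regions <- generate_tumor_grid(sim_config(n_sections = 1, grid_dims = c(4, 4)))
  block <- c("1A1", "1A2", "1B1", "1B2")          # 2x2 block
  diag2 <- c("1C3", "1D4")                        # diagonal only
  asg <- tibble::tibble(region_id = c(block, diag2),
                        cluster = rep(c(1L, 2L), c(4, 2)))
  ct <- cluster_contiguity(asg, regions)
  expect_equal(ct$neighbor_fraction[ct$cluster == 1], 1)
  expect_true(ct$contiguous[ct$cluster == 1])
  expect_equal(ct$neighbor_fraction[ct$cluster == 2], 0)
  expect_false(ct$contiguous[ct$cluster == 2])

  # random assignment vs igraph component oracle
  set.seed(13)
  all_asg <- tibble::tibble(region_id = regions$region_id,
                            cluster = sample(1:3, nrow(regions), TRUE))
  ct2 <- cluster_contiguity(all_asg, regions)
  for (cl in unique(all_asg$cluster)) {
    members <- all_asg$region_id[all_asg$cluster == cl]
    sub <- regions[regions$region_id %in% members, ]
    n <- nrow(sub)
    am <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sub$section[i] == sub$section[j] &&
          abs(sub$x[i] - sub$x[j]) + abs(sub$y[i] - sub$y[j]) == 1) am[i, j] <- 1
    }
    ncomp <- igraph::components(igraph::graph_from_adjacency_matrix(am, "undirected"))$no
    expect_equal(ct2$n_components[ct2$cluster == cl], ncomp)
  }
})

test_that("contiguity is invariant under grid translation", {
  regions <- generate_tumor_grid(sim_config(n_sections = 1, grid_dims = c(4, 4)))
  asg <- tibble::tibble(region_id = c("1A1", "1A2", "1B1"), cluster = 1L)
  shifted <- dplyr::mutate(regions, x = x + 10, y = y + 3)
  expect_equal(cluster_contiguity(asg, regions)$neighbor_fraction,
               cluster_contiguity(asg, shifted)$neighbor_fraction)
})
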