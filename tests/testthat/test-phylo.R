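tree_splits_for_test <- function(tree) {
  labs <- tree$tip.label; ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(i) {
    s <- labs[i]
    if (ref %in% s) paste(sort(setdiff(labs, s)), collapse = "|")
    else paste(sort(s), collapse = "|")
  }, "")
  unique(keys[nchar(keys) > 0])
}

toy_calls <- function() {
  tidyr::expand_grid(mutation_id = paste0("M", 1:5),
                     region_id = paste0("R", 1:3)) |>
    dplyr::mutate(present = TRUE,
                  power = c(0.9, 0.9, 0.9,     # M1 kept
                            0.8, 0.95, 0.9,    # M2 boundary: kept (>= 0.8)
                            0.79, 0.9, 0.9,    # M3 dropped
                            0.9, 0.9, 0.9,     # M4 kept
                            NA, 0.9, 0.9))     # M5 missing power: excluded
}

test_that("power filter keeps mutations at the 0.8 boundary and flags missing power", {
  expect_message(mm <- power_filter(toy_calls()), "M5")
  expect_setequal(mm$mutation_id, c("M1", "M2", "M4"))
  expect_equal(attr(mm, "excluded"), "M5")
  # predicate-scan oracle
  calls <- toy_calls()
  keep <- vapply(split(calls, calls$mutation_id), function(g) {
    !anyNA(g$power) && all(g$power >= 0.8)
  }, TRUE)
  expect_setequal(mm$mutation_id, names(keep)[keep])
})

test_that("neoantigen variant filter is a strict five-way conjunction", {
  calls <- tibble::tibble(
    tumor_count = c(31, 30, 100, 100), normal_count = c(11, 50, 10, 50),
    tumor_vaf = c(0.06, 0.2, 0.2, 0.05), normal_vaf = c(0.005, 0, 0, 0),
    power = c(0.81, 0.9, 0.9, 0.9))
  out <- neoantigen_variant_filter(calls)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$fail_reason[2], "tumor_count")
  # random-table oracle
  set.seed(15)
  rnd <- tibble::tibble(tumor_count = sample(20:40, 50, TRUE),
                        normal_count = sample(5:15, 50, TRUE),
                        tumor_vaf = runif(50, 0, 0.1),
                        normal_vaf = runif(50, 0, 0.02),
                        power = runif(50, 0.7, 1))
  got <- neoantigen_variant_filter(rnd)$pass
  oracle <- rnd$tumor_count > 30 & rnd$normal_count > 10 &
    rnd$tumor_vaf > 0.05 & rnd$normal_vaf < 0.01 & rnd$power > 0.8
  expect_equal(got, oracle)
})

test_that("neoantigen calling keeps expressed strong binders, strictly", {
  preds <- tibble::tibble(
    mutation_id = c("ZDHHC17_H507Y", "M2", "M3", "M4"),
    peptide = c("KTDPLLLAY", "AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
    ic50 = c(77.17, 500, 100, 100),
    fpkm = c(2, 5, 1, 5), rna_alt_count = c(5, 9, 9, 4))
  res <- call_neoantigens(preds)
  expect_equal(res$per_mutation$mutation_id, "ZDHHC17_H507Y")
  expect_equal(res$per_mutation$best_ic50, 77.17)
})

test_that("mutation sharing reproduces a constructed 15/22/16 spectrum", {
  m <- rbind(matrix(1L, 15, 41),
             do.call(rbind, lapply(1:22, function(i) {
               r <- integer(41); r[seq_len(2 + (i %% 38))] <- 1L; r
             })),
             do.call(rbind, lapply(1:16, function(i) {
               r <- integer(41); r[1 + (i %% 41)] <- 1L; r
             })))
  colnames(m) <- paste0("R", 1:41)
  tab <- dplyr::mutate(tibble::as_tibble(m),
                       mutation_id = paste0("M", 1:53), .before = 1)
  sh <- mutation_sharing(tab)
  s <- sh$summary
  expect_equal(s$fraction[s$class == "ubiquitous"], 15 / 53)
  expect_equal(s$fraction[s$class == "private"], 16 / 53)
  expect_equal(sh$per_mutation$n_regions, unname(rowSums(m)))
  all1 <- tab; all1[-1] <- 1L
  expect_equal(mutation_sharing(all1)$summary$fraction[
    mutation_sharing(all1)$summary$class == "ubiquitous"], 1)
})

test_that("Hamming distances count differing rows and form a metric", {
  m <- tibble::tibble(mutation_id = paste0("M", 1:4),
                      A = c(0L, 1L, 1L, 0L), B = c(0L, 1L, 0L, 1L),
                      C = c(0L, 1L, 1L, 0L))
  d <- hamming_distances(m)
  expect_equal(d["A", "B"], 2L)
  expect_equal(d["A", "C"], 0L)
  expect_error(hamming_distances(dplyr::mutate(m, A = A + 0.5)), "binary")
  set.seed(19)
  rnd <- tibble::as_tibble(matrix(rbinom(120, 1, 0.4), 20, 6,
    dimnames = list(NULL, paste0("S", 1:6))))
  rnd <- dplyr::mutate(rnd, mutation_id = paste0("M", 1:20), .before = 1)
  dr <- hamming_distances(rnd)
  expect_equal(dr, t(dr))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(dr[i, j], dr[i, k] + dr[k, j])
  }
})

test_that("neighbor joining solves the three-point problem exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("neighbor joining recovers additive four-taxon metrics exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 7;  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 8;  d["B", "D"] <- d["D", "B"] <- 9
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- neighbor_joining(d)
  expect_equal(sum(tr$edge.length), 15)  # total branch length 2+3+1+4+5
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)], d)
  # topology: AB vs CD split present
  expect_true("C|D" %in% tree_splits_for_test(tr) ||
                "A|B" %in% tree_splits_for_test(tr))
})

test_that("identical taxa become zero-length siblings; order does not matter", {
  m <- tibble::tibble(mutation_id = paste0("M", 1:6),
                      A = c(1L, 1L, 0L, 0L, 1L, 0L),
                      B = c(1L, 1L, 0L, 0L, 1L, 0L),
                      C = c(0L, 0L, 1L, 1L, 0L, 0L),
                      D = c(0L, 0L, 1L, 0L, 0L, 1L))
  tr <- neighbor_joining(hamming_distances(m))
  pair <- ape::cophenetic.phylo(tr)["A", "B"]
  expect_equal(pair, 0)
  perm <- m[c("mutation_id", "C", "A", "D", "B")]
  tr2 <- neighbor_joining(hamming_distances(perm))
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
})

test_that("NJ agrees with the ape reference implementation on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(27)
  for (i in 1:5) {
    m <- matrix(rbinom(9 * 40, 1, 0.5), 40, 9,
                dimnames = list(NULL, paste0("S", 1:9)))
    tab <- dplyr::mutate(tibble::as_tibble(m),
                         mutation_id = sprintf("M%02d", 1:40), .before = 1)
    d <- hamming_distances(tab)
    ours <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ape::unroot(ours), ape::unroot(ref)), 0)
  }
})

test_that("bootstrap supports are deterministic and hit 100 on clean signal", {
  cm <- simulate_clonal_mutations(8, n_per_clade = 20, n_truncal = 5, seed = 2)
  b1 <- bootstrap_support(cm$matrix, B = 100, seed = 5)
  b2 <- bootstrap_support(cm$matrix, B = 100, seed = 5)
  expect_equal(b1$splits, b2$splits)
  expect_true(all(b1$splits$support == 100))
  bs1 <- bootstrap_support(cm$matrix, B = 1, seed = 9)
  expect_true(all(bs1$splits$support %in% c(0, 100)))
})

test_that("support grows with the number of diagnostic characters", {
  weak <- simulate_clonal_mutations(8, n_per_clade = 2, n_truncal = 2,
                                    n_private = 3, seed = 4)
  strong <- simulate_clonal_mutations(8, n_per_clade = 20, n_truncal = 2,
                                      n_private = 3, seed = 4)
  bw <- bootstrap_support(weak$matrix, B = 50, seed = 1)
  bs <- bootstrap_support(strong$matrix, B = 50, seed = 1)
  expect_gte(mean(bs$splits$support), mean(bw$splits$support))
})

test_that("truncal VAF tables are complete or fail loudly", {
  sim <- simulate_tumor(sim_config(seed = 16, n_sections = 1, grid_dims = c(3, 3)))
  truncal <- sim$truth$mutation_classes$mutation_id[
    sim$truth$mutation_classes$class == "truncal"]
  tab <- truncal_vaf_table(sim$variants, truncal)
  expect_equal(nrow(tab), length(truncal))
  expect_false(anyNA(tab))
  # join oracle on a spot check
  v <- sim$variants
  expect_equal(tab$`1A1`[tab$mutation_id == truncal[1]],
               v$tumor_vaf[v$mutation_id == truncal[1] & v$region_id == "1A1"])
  private <- sim$truth$mutation_classes$mutation_id[
    sim$truth$mutation_classes$class == "private"][1]
  expect_error(truncal_vaf_table(sim$variants, c(truncal, private)), private)
})
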