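test_that("tumor grid labels boundary cells margin and interiors core", {
  cfg <- sim_config(n_sections = 1, grid_dims = c(3, 3))
  g <- generate_tumor_grid(cfg)
  expect_equal(nrow(g), 9)
  expect_equal(sum(g$location == "margin"), 8)
  expect_equal(g$region_id[g$location == "core"], "1B2")

  cfg2 <- sim_config(n_sections = 2, grid_dims = c(4, 4))
  g2 <- generate_tumor_grid(cfg2)
  expect_equal(nrow(g2), 32)
  expect_setequal(unique(g2$section), c(1, 2))
  expect_false(anyDuplicated(g2$region_id) > 0)

  expect_warning(generate_tumor_grid(sim_config(n_sections = 1, grid_dims = c(2, 2))),
                 "margin")
})

test_that("identical config gives byte-identical simulations", {
  cfg <- sim_config(seed = 11, n_genes = 60, n_clones = 10,
                    grid_dims = c(3, 3), n_sections = 1)
  s1 <- simulate_tumor(cfg)
  s2 <- simulate_tumor(cfg)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$tcr, s2$tcr)
})

test_that("planted events land on affected regions only, at the set magnitude", {
  cfg <- sim_config(seed = 1, n_sections = 1, grid_dims = c(3, 3),
                    segment_noise_sd = 0,
                    cn_events = list(list(chrom = "chr7", type = "gain",
                                          magnitude = 0.58,
                                          regions = c("1A1", "1B2"))))
  regions <- generate_tumor_grid(cfg)
  cn <- simulate_copy_number(cfg, regions)
  seg7 <- cn$segments[cn$segments$chrom == "chr7", ]
  expect_true(all(seg7$log2_ratio[seg7$sample %in% c("1A1", "1B2")] == 0.58))
  expect_true(all(seg7$log2_ratio[!seg7$sample %in% c("1A1", "1B2")] == 0))

  cfg0 <- sim_config(seed = 2, n_sections = 1, grid_dims = c(3, 3),
                     cn_events = list())
  cn0 <- simulate_copy_number(cfg0, generate_tumor_grid(cfg0))
  expect_lt(abs(mean(cn0$segments$log2_ratio)), 4 * 0.05)

  expect_error(simulate_copy_number(
    sim_config(n_sections = 1, grid_dims = c(3, 3),
               cn_events = list(list(chrom = "chr7", type = "gain",
                                     magnitude = 0.5, regions = "9Z9"))),
    generate_tumor_grid(cfg)), "unknown region")
})

test_that("chromosome caller recovers a planted gain perfectly across seeds", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_sections = 1, grid_dims = c(3, 3),
                      cn_events = list(list(chrom = "chr7", type = "gain",
                                            magnitude = 0.58,
                                            regions = list(x = c(1, 2)))))
    regions <- generate_tumor_grid(cfg)
    cn <- simulate_copy_number(cfg, regions)
    calls <- call_chromosome_event(cn$segments, "chr7")
    truth <- regions$region_id %in% cn$events$region_id
    called <- calls$call[match(regions$region_id, calls$sample)] == "gain"
    all(called == truth)
  }, TRUE)
  expect_true(all(hits))
})

test_that("expression obeys the dosage and immune models", {
  # gamma = 0: expression independent of copy number
  cfg <- sim_config(seed = 3, n_sections = 1, grid_dims = c(4, 4),
                    n_genes = 60, dosage_coefficient = 0, immune_effect = 0)
  sim <- simulate_tumor(cfg)
  cn <- genes_from_segments(sim$segments, sim$genes)
  cm <- as.matrix(cn[-1]); em <- as.matrix(sim$counts[-1])
  rho <- vapply(seq_len(nrow(cm)), function(i) {
    if (sd(cm[i, ]) == 0 || sd(em[i, ]) == 0) return(NA_real_)
    abs(cor(cm[i, ], em[i, ], method = "spearman"))
  }, 0)
  expect_lt(median(rho, na.rm = TRUE), 0.2)

  # immune-high regions score higher on the immune program
  cfg2 <- sim_config(seed = 4)
  sim2 <- simulate_tumor(cfg2)
  sc <- geometric_mean_score(log2_counts(sim2$counts),
                             list(imm = sim2$truth$immune_genes))
  cat_ <- sim2$immune$immune_category[match(sc$sample, sim2$immune$region_id)]
  hi <- sc$score[cat_ == "high"]; lo <- sc$score[cat_ == "low"]
  expect_gte(length(hi), 10); expect_gte(length(lo), 10)
  expect_lt(t.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("methylation coupling is inverse and betas stay inside (0,1)", {
  cfg <- sim_config(seed = 5, n_sections = 1, grid_dims = c(5, 5),
                    n_genes = 40, meth_noise_sd = 0,
                    baseline_log2_mean = 8)
  sim <- simulate_tumor(cfg)
  b <- as.matrix(sim$beta[-1]); rownames(b) <- sim$beta$probe
  expect_true(all(b > 0 & b < 1))
  em <- as.matrix(sim$counts[-1]); rownames(em) <- sim$counts$gene
  coupled <- sim$truth$coupled_genes
  p1 <- paste0(coupled[1], "_p1")
  expect_equal(cor(b[p1, ], em[coupled[1], ], method = "spearman"), -1)
  # uncoupled genes: negligible correlation on median
  unc <- setdiff(sim$counts$gene, coupled)
  rho <- vapply(unc, function(g) {
    abs(cor(b[paste0(g, "_p1"), ], em[g, ], method = "spearman"))
  }, 0)
  expect_lt(median(rho), 0.2)
})

test_that("mutation spectrum and VAF model follow the configuration", {
  cfg <- sim_config(seed = 6, n_sections = 1, grid_dims = c(3, 3),
                    n_private_mutations = 0, n_intermediate_mutations = 0)
  mm <- power_filter(simulate_tumor(cfg)$variants)
  sh <- mutation_sharing(mm)
  expect_equal(sh$summary$fraction[sh$summary$class == "ubiquitous"], 1)

  # the default spectrum by construction: 15 truncal + 16 private of 53
  cfg2 <- sim_config(seed = 7)
  sim2 <- simulate_tumor(cfg2)
  sh2 <- mutation_sharing(power_filter(sim2$variants))
  expect_equal(sh2$summary$n_mutations[sh2$summary$class == "ubiquitous"], 15L)
  expect_equal(sh2$summary$n_mutations[sh2$summary$class == "private"], 16L)
  expect_equal(sh2$summary$fraction[sh2$summary$class == "ubiquitous"], 15 / 53)

  # purity 1, CCF 1 (truncal), deep sequencing: VAF -> 0.5
  cfg3 <- sim_config(seed = 8, n_sections = 1, grid_dims = c(3, 3),
                     purity_range = c(1, 1), sequencing_depth = 100000L,
                     n_private_mutations = 0, n_intermediate_mutations = 0)
  v <- simulate_mutations(cfg3, generate_tumor_grid(cfg3))$variants
  expect_equal(mean(v$tumor_vaf), 0.5, tolerance = 0.01)
})

test_that("TCR generator limits: neutral multipliers and flat fields", {
  cfg <- sim_config(seed = 9, n_sections = 1, grid_dims = c(2, 2),
                    n_clones = 8, reads_per_region = 200000L,
                    activation_multipliers = rep(1, 8),
                    clone_spatial_sd = Inf, nonproductive_fraction = 0)
  grid22 <- suppressWarnings(generate_tumor_grid(cfg))  # 2x2: all margin
  tcr <- simulate_tcr(cfg, grid22)
  dna <- tcr$clones[tcr$clones$assay == "DNA" & tcr$clones$sample == "1A1", ]
  rna <- tcr$clones[tcr$clones$assay == "RNA" & tcr$clones$sample == "1A1", ]
  fd <- productive_frequencies(dna); fr <- productive_frequencies(rna)
  expect_equal(fr$frequency[match(fd$clone, fr$clone)], fd$frequency,
               tolerance = 0.02)
  # flat spatial field: overlap between regions -> 1 at high depth
  d2 <- tcr$clones[tcr$clones$assay == "DNA", ]
  moi <- morisita_overlap(d2[d2$sample == "1A1", ], d2[d2$sample == "1B2", ])
  expect_equal(moi, 1, tolerance = 0.001)
})

test_that("simulated files round-trip through the package readers", {
  cfg <- sim_config(seed = 10, n_sections = 1, grid_dims = c(3, 3),
                    n_genes = 30, n_clones = 8)
  sim <- simulate_tumor(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  seg <- read_seg(file.path(dir, "segments.seg"))
  expect_equal(seg$log2_ratio, sim$segments$log2_ratio)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(as.matrix(counts[-1]), as.matrix(sim$counts[-1]))
  clones <- read_clones(file.path(dir, "clones.tsv"))
  expect_equal(nrow(clones), nrow(sim$tcr))
  genes <- read_gene_bed(file.path(dir, "genes.bed"))
  expect_equal(genes$start, sim$genes$start)
  expect_equal(genes$end, sim$genes$end)
})
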