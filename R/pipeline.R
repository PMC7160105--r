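#' Run the full synthetic-tumor analysis pipeline
#'
#' Simulates a spatial tumor from `config`, then runs every analysis
#' stage in dependency order: chromosome and gene-level copy-number
#' calls, signature scoring and margin enrichment, similarity network and
#' consensus clustering, TCR repertoire statistics and activation,
#' multi-omic concordance with tanglegram entanglement, and the mutation
#' phylogeny with bootstrap supports. All randomness derives from
#' `config$seed`, so identical configs reproduce identical results.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON and checksummed into the manifest.
#' @param consensus_B,consensus_kmax Consensus-clustering resamples and
#'   maximum k for the pipeline run (defaults 200 and 10 keep the default
#'   run light; [consensus_cluster()] itself defaults to 500/20).
#' @param bootstrap_B Phylogeny bootstrap iterations (default 100).
#' @param top_n_genes Variable-gene count for clustering (default 200,
#'   capped at the gene universe).
#' @return A `spatialith_run` list of stage results plus a `manifest`
#'   tibble (`file`, `md5`) when `out_dir` is given.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         consensus_B = 200, consensus_kmax = 10,
                         bootstrap_B = 100, top_n_genes = 200) {
  sim <- simulate_tumor(config)

  # copy number
  chrom_calls <- call_chromosome_event(sim$segments)
  gene_cn <- genes_from_segments(sim$segments, sim$genes)
  gene_events <- call_gene_events(gene_cn)
  burden <- cna_burden(gene_events)

  # signatures
  log2m <- log2_counts(sim$counts)
  immune_set <- list(immune_program = sim$truth$immune_genes)
  scores <- geometric_mean_score(log2m, immune_set)
  measured <- scores[scores$signature == "immune_program", ]
  region_calls <- dplyr::mutate(
    dplyr::left_join(sim$regions, measured[c("sample", "score")],
                     by = c(region_id = "sample")),
    immune_category = tertile_categorize(.data$score))
  margin_test <- margin_enrichment_test(region_calls)

  # spatial structure
  ssgsea <- ssgsea_score(log2m, immune_set)
  dist_scores <- dplyr::mutate(
    dplyr::bind_rows(scores, ssgsea),
    signature = paste(.data$signature, .data$method, sep = "."))
  dmat <- immune_distance_matrix(dist_scores)
  network <- top_quartile_links(dmat)
  surface <- map_surface(
    dplyr::rename(measured[c("sample", "score")], region_id = "sample"),
    sim$regions)
  var_genes <- most_variable_genes(log2m, min(top_n_genes, nrow(log2m)))
  feat <- t(counts_matrix(log2m)[var_genes, , drop = FALSE])
  kmax <- min(consensus_kmax, nrow(feat) - 2)
  consensus <- consensus_cluster(feat, kmax = kmax, B = consensus_B,
                                 seed = stream_seed(config$seed, "analysis"))
  contiguity <- cluster_contiguity(consensus$assignments, sim$regions)

  # differential expression + enrichment (immune high vs low regions)
  hi_lo <- region_calls[region_calls$immune_category %in% c("high", "low"), ]
  de <- differential_expression(
    log2m[c("gene", hi_lo$region_id)],
    setNames(as.character(hi_lo$immune_category), hi_lo$region_id))
  de_genes <- select_de_genes(de, lfc_threshold = 1, padj_threshold = 0.05,
                              direction = "both")
  enrichment <- if (length(de_genes) > 0) {
    hypergeom_enrichment(de_genes, de$gene, immune_set)
  } else NULL

  # TCR repertoire
  dna <- sim$tcr[sim$tcr$assay == "DNA", ]
  rna <- sim$tcr[sim$tcr$assay == "RNA", ]
  region_ids <- sim$regions$region_id
  clon <- tibble::tibble(
    region_id = region_ids,
    clonality = vapply(region_ids,
                       function(r) clonality(dna[dna$sample == r, ]), 0))
  moi <- outer(region_ids, region_ids, Vectorize(function(a, b) {
    morisita_overlap(dna[dna$sample == a, ], dna[dna$sample == b, ])
  }))
  dimnames(moi) <- list(region_ids, region_ids)
  tcr_sharing <- sharing_spectrum(dna)
  activation <- purrr::map(setNames(region_ids, region_ids), function(r) {
    tryCatch(activation_residuals(dna[dna$sample == r, ],
                                  rna[rna$sample == r, ]),
             error = function(e) NULL)
  })
  activation <- activation[!vapply(activation, is.null, TRUE)]

  # variants + phylogeny
  mut_matrix <- power_filter(sim$variants)
  mut_sharing <- mutation_sharing(mut_matrix)
  boot <- bootstrap_support(mut_matrix, B = bootstrap_B,
                            seed = stream_seed(config$seed, "analysis"))
  truncal_ids <- sim$truth$mutation_classes$mutation_id[
    sim$truth$mutation_classes$class == "truncal"]
  vaf_tab <- truncal_vaf_table(sim$variants, truncal_ids)

  # multi-omic concordance
  gene_beta <- collapse_probes(sim$beta, sim$probe_map)
  cn_filled <- gene_cn
  cn_filled[is.na(cn_filled)] <- 0
  concordance <- gene_correlations(log2m, cn_filled, gene_beta)
  tangle <- tangle_report(log2m, cn_filled, gene_beta,
                          immune_labels = region_calls[c("region_id", "immune_category")])

  run <- structure(list(
    config = config, sim = sim, chrom_calls = chrom_calls,
    gene_cn = gene_cn, gene_events = gene_events, burden = burden,
    scores = scores, region_calls = region_calls, margin_test = margin_test,
    network = network, surface = surface, consensus = consensus,
    contiguity = contiguity, de = de, de_genes = de_genes,
    enrichment = enrichment, clonality = clon, morisita = moi,
    tcr_sharing = tcr_sharing, activation = activation,
    mutation_matrix = mut_matrix, mutation_sharing = mut_sharing,
    phylogeny = boot, truncal_vafs = vaf_tab,
    concordance = concordance, tangle = tangle,
    manifest = NULL
  ), class = "spatialith_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run(run, out_dir)
  }
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(run$sim, file.path(out_dir, "simulated"))
  p <- function(f) file.path(out_dir, f)
  write_table_tsv(run$chrom_calls, p("chromosome_calls.tsv"))
  write_table_tsv(run$burden, p("cna_burden.tsv"))
  write_table_tsv(run$scores, p("signature_scores.tsv"))
  write_table_tsv(run$de, p("differential_expression.tsv"))
  if (!is.null(run$enrichment)) write_table_tsv(run$enrichment, p("enrichment.tsv"))
  write_table_tsv(run$clonality, p("clonality.tsv"))
  write_table_tsv(tibble::as_tibble(run$morisita, rownames = "region_id"),
                  p("morisita.tsv"))
  write_table_tsv(run$tcr_sharing$summary, p("tcr_sharing.tsv"))
  write_table_tsv(run$mutation_sharing$summary, p("mutation_sharing.tsv"))
  write_table_tsv(run$consensus$area, p("consensus_delta_area.tsv"))
  write_table_tsv(run$consensus$assignments, p("cluster_assignments.tsv"))
  write_table_tsv(run$contiguity, p("cluster_contiguity.tsv"))
  write_table_tsv(run$concordance, p("gene_concordance.tsv"))
  write_table_tsv(run$tangle$entanglement, p("entanglement.tsv"))
  ape::write.tree(run$phylogeny$tree, p("phylogeny.nwk"))
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  tibble::tibble(file = sub(paste0("^", out_dir, "/?"), "", files),
                 md5 = unname(tools::md5sum(files)))
}

#' Summarize a pipeline run
#'
#' One machine-readable summary of the run's headline numbers. Stages
#' absent from the run are omitted with a note in the `omitted` field.
#'
#' @param run A `spatialith_run` from [run_pipeline()].
#' @param path Optional path; when given the summary is written as JSON.
#' @return The summary list, invisibly when `path` is given.
#' @export
report <- function(run, path = NULL) {
  omitted <- character()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      omitted <<- c(omitted, name)
      NULL
    })
  }
  summary <- list(
    seed = run$config$seed,
    n_regions = nrow(run$sim$regions),
    chromosome_events = grab("chromosome_events", {
      calls <- run$chrom_calls[!is.na(run$chrom_calls$call) &
                                 run$chrom_calls$call != "none", ]
      as.list(table(paste(calls$chrom, calls$call)))
    }),
    margin_test_p = grab("margin_test_p", run$margin_test$p),
    consensus_k = grab("consensus_k", run$consensus$k_opt),
    mean_clonality = grab("mean_clonality", mean(run$clonality$clonality)),
    mean_morisita = grab("mean_morisita",
                         mean(run$morisita[upper.tri(run$morisita)])),
    tcr_sharing = grab("tcr_sharing",
                       setNames(as.list(run$tcr_sharing$summary$fraction),
                                run$tcr_sharing$summary$class)),
    mutation_sharing = grab("mutation_sharing",
                            setNames(as.list(run$mutation_sharing$summary$fraction),
                                     run$mutation_sharing$summary$class)),
    n_de_genes = grab("n_de_genes", length(run$de_genes)),
    entanglement = grab("entanglement", {
      e <- run$tangle$entanglement
      setNames(as.list(e$entanglement),
               paste(e$modality_a, e$modality_b, sep = "_vs_"))
    }),
    tree_newick = grab("tree_newick", ape::write.tree(run$phylogeny$tree)),
    omitted = I(omitted)
  )
  if (!is.null(path)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(summary))
  }
  summary
}
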