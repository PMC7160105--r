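#' Configuration for the synthetic spatial tumor generator
#'
#' Bundles every knob of the simulator into one validated list. The defaults
#' describe a sectioned cutaneous metastasis profiled in 3 frozen sections,
#' each sliced on a 4 x 4 grid (48 sub-regions), carrying one truncal
#' chromosome-level gain plus three spatially localized subclonal events
#' (a chr7 gain at +0.58 log2, a chr10 loss, a chr13 gain), dosage-coupled
#' negative-binomial expression with a smooth immune field of discrete hot
#' pockets, methylation inversely coupled to expression for half the genes,
#' a 15 truncal / 22 intermediate / 16 private mutation spectrum, and paired
#' DNA/RNA TCR repertoires with Zipf clone abundances, per-clone spatial
#' gradients and a few transcriptionally over- and under-active clones.
#'
#' @param seed Master seed. Each modality draws from its own RNG stream
#'   derived from this seed, so simulating one modality never perturbs
#'   another.
#' @param n_sections,grid_dims Sections (z levels) and per-section grid size
#'   `c(rows, cols)`.
#' @param n_chromosomes,chrom_length,segments_per_chrom Simulated genome:
#'   chromosomes `chr1..chrN`, each of `chrom_length` bp, tiled into equal
#'   segments.
#' @param n_genes,n_immune_genes,n_ribosomal_genes Gene universe; immune
#'   program genes respond to the immune field, and a few `RPL`/`RPS`-named
#'   genes exercise ribosomal-exclusion logic downstream. `NULL` defaults
#'   to 10 percent immune genes and up to 6 ribosomal genes.
#' @param cn_events List of events, each
#'   `list(chrom =, type = "gain"|"loss", magnitude =, regions =)` where
#'   `regions` is `"all"`, a character vector of region ids, or a block
#'   spec `list(section =, x =, y =)` of ranges.
#' @param segment_noise_sd Gaussian noise added to each segment mean.
#' @param dosage_coefficient Log2-expression shift per unit log2 copy-number
#'   ratio (gamma).
#' @param immune_effect Log2-expression shift of immune-program genes per
#'   unit immune level (delta).
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi mu^2); values below 1e-8 fall back to Poisson.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline log2 means.
#' @param n_immune_pockets,pocket_sd,immune_noise_sd Immune field: sum of
#'   Gaussian bumps over the grid (sd in cell units) plus white noise,
#'   rescaled to `[0, 1]`.
#' @param meth_coupling_fraction,probes_per_gene,meth_slope,meth_noise_sd
#'   Methylation model: for the coupled gene fraction,
#'   `logit(beta) = a - meth_slope * log2(count + 1) + noise`.
#' @param n_truncal_mutations,n_intermediate_mutations,n_private_mutations
#'   Mutation sharing spectrum (defaults 15/22/16 = 53 mutations).
#' @param sequencing_depth,purity_range Read depth for binomial VAF noise
#'   and the per-region tumor purity interval.
#' @param n_clones,truncal_clone_count,zipf_exponent TCR clone pool: base
#'   abundances proportional to `rank^-zipf_exponent`; the top
#'   `truncal_clone_count` clones are ubiquitous with only mild spatial
#'   modulation, the rest carry strong Gaussian spatial bumps.
#' @param clone_spatial_sd Width (cells) of per-clone spatial bumps.
#' @param reads_per_region Template count per region per assay.
#' @param activation_multipliers Per-clone positive multipliers applied to
#'   RNA frequencies before renormalization; `NULL` means all 1 except
#'   clones 2 and 4 (multipliers 4 and 2.5, over-active) and clone 6 (0.4,
#'   under-active).
#' @param nonproductive_fraction Fraction of clones flagged non-productive.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_sections = 3L, grid_dims = c(4L, 4L),
                       n_chromosomes = 14L, chrom_length = 1e8,
                       segments_per_chrom = 10L,
                       n_genes = 400L, n_immune_genes = NULL,
                       n_ribosomal_genes = NULL,
                       cn_events = NULL, segment_noise_sd = 0.05,
                       dosage_coefficient = 1, immune_effect = 2,
                       nb_dispersion = 0.1,
                       baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                       n_immune_pockets = 3L, pocket_sd = 1.2,
                       immune_noise_sd = 0.05,
                       meth_coupling_fraction = 0.5, probes_per_gene = 3L,
                       meth_slope = 1.5, meth_noise_sd = 0.3,
                       n_truncal_mutations = 15L,
                       n_intermediate_mutations = 22L,
                       n_private_mutations = 16L,
                       sequencing_depth = 100L, purity_range = c(0.6, 0.9),
                       n_clones = 40L, truncal_clone_count = 5L,
                       zipf_exponent = 1, clone_spatial_sd = 1.5,
                       reads_per_region = 3000L,
                       activation_multipliers = NULL,
                       nonproductive_fraction = 0.05) {
  if (is.null(n_immune_genes)) n_immune_genes <- max(4L, round(n_genes / 10))
  if (is.null(n_ribosomal_genes)) {
    n_ribosomal_genes <- min(6L, max(0L, n_genes - n_immune_genes - 10L))
  }
  if (is.null(cn_events)) {
    candidates <- list(
      list(chrom = "chr2", type = "gain", magnitude = 0.7, regions = "all"),
      list(chrom = "chr7", type = "gain", magnitude = 0.58,
           regions = list(section = 1, y = c(1, 2))),
      list(chrom = "chr13", type = "gain", magnitude = 0.65,
           regions = list(section = 2, x = c(1, 2), y = c(1, 2))),
      list(chrom = "chr10", type = "loss", magnitude = -0.7,
           regions = list(section = 3, x = c(3, 4)))
    )
    # only keep subclonal defaults whose section exists in this grid
    cn_events <- Filter(function(ev) {
      is.character(ev$regions) || is.null(ev$regions$section) ||
        ev$regions$section <= n_sections
    }, candidates)
  }
  if (is.null(activation_multipliers)) {
    activation_multipliers <- rep(1, n_clones)
    if (n_clones >= 6) activation_multipliers[c(2, 4, 6)] <- c(4, 2.5, 0.4)
  }
  cfg <- list(
    seed = as.integer(seed), n_sections = as.integer(n_sections),
    grid_dims = as.integer(grid_dims), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, segments_per_chrom = as.integer(segments_per_chrom),
    n_genes = as.integer(n_genes), n_immune_genes = as.integer(n_immune_genes),
    n_ribosomal_genes = as.integer(n_ribosomal_genes),
    cn_events = cn_events, segment_noise_sd = segment_noise_sd,
    dosage_coefficient = dosage_coefficient, immune_effect = immune_effect,
    nb_dispersion = nb_dispersion, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    n_immune_pockets = as.integer(n_immune_pockets), pocket_sd = pocket_sd,
    immune_noise_sd = immune_noise_sd,
    meth_coupling_fraction = meth_coupling_fraction,
    probes_per_gene = as.integer(probes_per_gene),
    meth_slope = meth_slope, meth_noise_sd = meth_noise_sd,
    n_truncal_mutations = as.integer(n_truncal_mutations),
    n_intermediate_mutations = as.integer(n_intermediate_mutations),
    n_private_mutations = as.integer(n_private_mutations),
    sequencing_depth = as.integer(sequencing_depth), purity_range = purity_range,
    n_clones = as.integer(n_clones),
    truncal_clone_count = as.integer(truncal_clone_count),
    zipf_exponent = zipf_exponent, clone_spatial_sd = clone_spatial_sd,
    reads_per_region = as.integer(reads_per_region),
    activation_multipliers = activation_multipliers,
    nonproductive_fraction = nonproductive_fraction
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) abort(msg)
  stopifnot_msg(all(cfg$grid_dims >= 1) && length(cfg$grid_dims) == 2,
                "grid_dims must be two positive integers.")
  stopifnot_msg(cfg$grid_dims[1] <= 26, "at most 26 grid rows are supported (row letters).")
  stopifnot_msg(cfg$n_sections >= 1, "n_sections must be positive.")
  stopifnot_msg(cfg$zipf_exponent > 0, "zipf_exponent must be positive.")
  stopifnot_msg(cfg$nb_dispersion >= 0, "nb_dispersion must be non-negative.")
  fracs <- c(cfg$meth_coupling_fraction, cfg$nonproductive_fraction)
  stopifnot_msg(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0, 1].")
  stopifnot_msg(length(cfg$purity_range) == 2 &&
                  all(cfg$purity_range >= 0 & cfg$purity_range <= 1) &&
                  diff(cfg$purity_range) >= 0,
                "purity_range must be an increasing interval in [0, 1].")
  stopifnot_msg(length(cfg$activation_multipliers) == cfg$n_clones,
                "activation_multipliers must have one entry per clone.")
  stopifnot_msg(all(cfg$activation_multipliers > 0),
                "activation_multipliers must be positive.")
  stopifnot_msg(cfg$n_clones >= 2, "n_clones must be at least 2.")
  stopifnot_msg(cfg$n_immune_genes + cfg$n_ribosomal_genes <= cfg$n_genes,
                "immune + ribosomal genes exceed n_genes.")
  invisible(cfg)
}

#' Lay out the sectioned tumor grid
#'
#' One region per occupied grid cell per section. Cells on the outer
#' boundary of the grid are labeled `margin`, interior cells `core`,
#' emulating a histologic core/margin call. Region identifiers follow the
#' `{section}{row letter}{column}` convention (e.g. `2B3`).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `region_id`, `section`, `x` (row),
#'   `y` (column), `location` (`core`/`margin`).
#' @export
generate_tumor_grid <- function(config) {
  rows <- config$grid_dims[1]; cols <- config$grid_dims[2]
  grid <- tidyr::expand_grid(section = seq_len(config$n_sections),
                             x = seq_len(rows), y = seq_len(cols))
  out <- dplyr::mutate(
    grid,
    region_id = paste0(.data$section, LETTERS[.data$x], .data$y),
    location = dplyr::if_else(.data$x %in% c(1L, rows) | .data$y %in% c(1L, cols),
                              "margin", "core")
  )
  if (!any(out$location == "core")) {
    warn("grid too small to contain a core region; all regions labeled margin.")
  }
  dplyr::select(out, "region_id", "section", "x", "y", "location")
}

#' Simulated gene annotation
#'
#' Genes are laid out evenly across the simulated chromosomes in contiguous
#' blocks; immune-program genes are spread across the genome and a few
#' genes carry `RPL`/`RPS` identifiers.
#'
#' @param config A [sim_config()].
#' @return A tibble `gene`, `chrom`, `start`, `end` (1-based inclusive)
#'   plus logical columns `immune` and `ribosomal`.
#' @export
simulate_gene_annotation <- function(config) {
  n <- config$n_genes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  per_chrom <- rep(n %/% config$n_chromosomes, config$n_chromosomes)
  rem <- n %% config$n_chromosomes
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
  ann <- purrr::map2_dfr(chroms, per_chrom, function(ch, k) {
    if (k == 0) return(NULL)
    starts <- floor(seq(1, config$chrom_length * 0.98, length.out = k))
    tibble::tibble(chrom = ch, start = as.numeric(starts),
                   end = as.numeric(starts + 5e4 - 1))
  })
  ann$gene <- sprintf("G%04d", seq_len(nrow(ann)))
  immune_idx <- unique(floor(seq(1, n, length.out = config$n_immune_genes)))
  ann$immune <- seq_len(n) %in% immune_idx
  ribo_idx <- setdiff(seq_len(n), immune_idx)
  ribo_idx <- utils::tail(ribo_idx, config$n_ribosomal_genes)
  ann$ribosomal <- seq_len(n) %in% ribo_idx
  if (config$n_ribosomal_genes > 0) {
    half <- ceiling(length(ribo_idx) / 2)
    ann$gene[ribo_idx] <- c(sprintf("RPL%d", seq_len(half)),
                            sprintf("RPS%d", seq_len(length(ribo_idx) - half)))
  }
  dplyr::select(ann, "gene", "chrom", "start", "end", "immune", "ribosomal")
}

# Resolve an event's `regions` spec against the grid: "all", explicit ids,
# or a block spec list(section =, x = range, y = range).
resolve_region_subset <- function(spec, regions) {
  if (identical(spec, "all")) return(regions$region_id)
  if (is.character(spec)) {
    missing <- setdiff(spec, regions$region_id)
    if (length(missing)) abort(paste0("event references unknown regions: ",
                                      paste(missing, collapse = ", ")))
    return(spec)
  }
  if (is.list(spec)) {
    keep <- rep(TRUE, nrow(regions))
    if (!is.null(spec$section)) keep <- keep & regions$section %in% spec$section
    if (!is.null(spec$x)) keep <- keep & regions$x >= min(spec$x) & regions$x <= max(spec$x)
    if (!is.null(spec$y)) keep <- keep & regions$y >= min(spec$y) & regions$y <= max(spec$y)
    return(regions$region_id[keep])
  }
  abort("event `regions` must be \"all\", region ids, or a block spec list.")
}

#' Simulate per-region copy-number segments
#'
#' Each simulated chromosome is tiled into equal segments for every region.
#' Regions carrying a configured event get that event's log2 magnitude on
#' every segment of the chromosome, plus Gaussian segment noise; unaffected
#' regions are centered at zero.
#'
#' @param config A [sim_config()].
#' @param regions Region table from [generate_tumor_grid()].
#' @return A list with `segments` (tibble `sample`, `chrom`, `start`,
#'   `end`, `num_mark`, `log2_ratio`) and `events` (ground-truth tibble
#'   `chrom`, `type`, `magnitude`, `region_id`).
#' @export
simulate_copy_number <- function(config, regions) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  empty_truth <- tibble::tibble(chrom = character(), type = character(),
                                magnitude = numeric(), region_id = character())
  event_truth <- purrr::map_dfr(config$cn_events, function(ev) {
    if (!ev$chrom %in% chroms) abort(paste0("event chromosome not simulated: ", ev$chrom))
    ids <- resolve_region_subset(ev$regions, regions)
    if (length(ids) == 0) abort(paste0("event on ", ev$chrom, " matches no regions."))
    tibble::tibble(chrom = ev$chrom, type = ev$type,
                   magnitude = ev$magnitude, region_id = ids)
  })
  if (nrow(event_truth) == 0) event_truth <- empty_truth
  bounds <- floor(seq(1, config$chrom_length + 1,
                      length.out = config$segments_per_chrom + 1))
  tiles <- tibble::tibble(
    chrom = rep(chroms, each = config$segments_per_chrom),
    start = rep(bounds[-length(bounds)], times = config$n_chromosomes),
    end = rep(bounds[-1] - 1, times = config$n_chromosomes)
  )
  segments <- with_stream(config$seed, "cn", {
    grid <- tidyr::expand_grid(sample = regions$region_id, tiles)
    grid <- dplyr::left_join(
      grid,
      dplyr::summarise(dplyr::group_by(event_truth, .data$region_id, .data$chrom),
                       magnitude = sum(.data$magnitude), .groups = "drop"),
      by = c(sample = "region_id", chrom = "chrom")
    )
    dplyr::mutate(grid,
      magnitude = tidyr::replace_na(.data$magnitude, 0),
      num_mark = as.integer(round((.data$end - .data$start + 1) / 5e4)),
      log2_ratio = .data$magnitude +
        rnorm(dplyr::n(), 0, config$segment_noise_sd),
      magnitude = NULL)
  })
  list(segments = dplyr::select(segments, "sample", "chrom", "start", "end",
                                "num_mark", "log2_ratio"),
       events = event_truth)
}

# Smooth immune field: sum of Gaussian bumps at random grid positions plus
# white noise, rescaled to [0, 1]. Sections are one "cell" apart in z.
immune_field <- function(config, regions) {
  k <- config$n_immune_pockets
  centers <- regions[sample.int(nrow(regions), k, replace = FALSE), ]
  field <- rep(0, nrow(regions))
  for (i in seq_len(k)) {
    d2 <- (regions$x - centers$x[i])^2 + (regions$y - centers$y[i])^2 +
      (regions$section - centers$section[i])^2
    field <- field + exp(-d2 / (2 * config$pocket_sd^2))
  }
  field <- field + rnorm(length(field), 0, config$immune_noise_sd)
  field <- pmax(field, 0)
  if (max(field) > 0) field <- field / max(field)
  field
}

#' Simulate dosage- and immune-coupled expression counts
#'
#' Counts are negative-binomial with
#' `log2(mu) = baseline_g + gamma * cn_g + delta_g * immune_j`, where
#' `cn_g` is the gene-level log2 copy-number ratio implied by the segments,
#' `immune_j` is a smooth spatial field with discrete hot pockets, and
#' `delta_g = immune_effect` for immune-program genes and 0 otherwise.
#'
#' @param config A [sim_config()].
#' @param regions Region table.
#' @param segments Segment tibble from [simulate_copy_number()].
#' @param genes Gene annotation from [simulate_gene_annotation()].
#' @return A list with `counts` (raw counts tibble, genes x regions),
#'   `immune` (tibble `region_id`, `immune_level`, `immune_category`), and
#'   `baseline` (per-gene baseline log2 means).
#' @export
simulate_expression <- function(config, regions, segments, genes) {
  cn <- genes_from_segments(segments, genes)
  cn_m <- counts_matrix(cn)[genes$gene, regions$region_id, drop = FALSE]
  cn_m[is.na(cn_m)] <- 0
  with_stream(config$seed, "expr", {
    immune_j <- immune_field(config, regions)
    baseline <- rnorm(nrow(genes), config$baseline_log2_mean,
                      config$baseline_log2_sd)
    delta_g <- ifelse(genes$immune, config$immune_effect, 0)
    log2mu <- baseline + config$dosage_coefficient * cn_m +
      outer(delta_g, immune_j)
    mu <- 2^log2mu
    n <- length(mu)
    counts <- if (config$nb_dispersion < 1e-8) {
      stats::rpois(n, mu)
    } else {
      rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }
    counts <- matrix(as.numeric(counts), nrow = nrow(genes),
                     dimnames = list(genes$gene, regions$region_id))
    list(
      counts = matrix_counts(counts, "raw"),
      immune = tibble::tibble(
        region_id = regions$region_id,
        immune_level = immune_j,
        immune_category = tertile_categorize(immune_j)
      ),
      baseline = setNames(baseline, genes$gene)
    )
  })
}

#' Simulate methylation beta values coupled to expression
#'
#' Each gene carries `probes_per_gene` probes. For the coupled fraction of
#' genes, `logit(beta) = a_p - meth_slope * log2(count + 1) + noise`
#' (so beta falls as expression rises); uncoupled genes get independent
#' Gaussian logits. The logistic transform keeps every beta strictly in
#' (0, 1).
#'
#' @param config A [sim_config()].
#' @param counts Raw counts tibble from [simulate_expression()].
#' @return A list with `beta` (tibble, first column `probe`), `probe_map`
#'   (tibble `probe`, `gene`) and `coupled_genes` (character).
#' @export
simulate_methylation <- function(config, counts) {
  m <- counts_matrix(counts)
  l2e <- log2(m + 1)
  genes <- rownames(m)
  with_stream(config$seed, "meth", {
    n_coupled <- floor(config$meth_coupling_fraction * length(genes))
    coupled <- sort(sample(genes, n_coupled))
    k <- config$probes_per_gene
    probe_map <- tibble::tibble(
      probe = sprintf("%s_p%d", rep(genes, each = k), rep(seq_len(k), length(genes))),
      gene = rep(genes, each = k)
    )
    logits <- matrix(NA_real_, nrow(probe_map), ncol(m),
                     dimnames = list(probe_map$probe, colnames(m)))
    for (i in seq_along(genes)) {
      g <- genes[i]
      rows <- (i - 1) * k + seq_len(k)
      if (g %in% coupled) {
        a_p <- config$meth_slope * mean(l2e[g, ]) + rnorm(k, 0, 0.3)
        sig <- -config$meth_slope * l2e[g, ]
      } else {
        a_p <- rnorm(k, 0, 0.5)
        sig <- rnorm(ncol(m), 0, 1)
      }
      logits[rows, ] <- outer(a_p, rep(1, ncol(m))) +
        matrix(rep(sig, each = k), nrow = k) +
        matrix(rnorm(k * ncol(m), 0, config$meth_noise_sd), nrow = k)
    }
    beta <- 1 / (1 + exp(-logits))
    list(beta = tibble::as_tibble(beta, rownames = "probe"),
         probe_map = probe_map, coupled_genes = coupled)
  })
}

#' Simulate somatic mutations with a truncal/intermediate/private spectrum
#'
#' Truncal mutations are present in every region, private mutations in
#' exactly one, intermediate mutations in a random subset of 2 to R-1
#' regions. Expected VAF is `0.5 * purity_j * CCF` (local copy number is
#' deliberately ignored) with binomial read noise at the configured depth.
#'
#' @param config A [sim_config()].
#' @param regions Region table.
#' @return A list with `variants` (one row per mutation x region:
#'   `mutation_id`, `region_id`, `present`, alt/ref counts, depth-style
#'   `tumor_count`/`normal_count`, VAFs, `power`), `purity` (per-region)
#'   and `classes` (ground-truth tibble `mutation_id`, `class`).
#' @export
simulate_mutations <- function(config, regions) {
  R <- nrow(regions)
  n_tr <- config$n_truncal_mutations
  n_mid <- config$n_intermediate_mutations
  n_pr <- config$n_private_mutations
  n_mut <- n_tr + n_mid + n_pr
  with_stream(config$seed, "mut", {
    purity <- runif(R, config$purity_range[1], config$purity_range[2])
    classes <- tibble::tibble(
      mutation_id = sprintf("M%03d", seq_len(n_mut)),
      class = rep(c("truncal", "intermediate", "private"), c(n_tr, n_mid, n_pr))
    )
    presence <- matrix(FALSE, n_mut, R,
                       dimnames = list(classes$mutation_id, regions$region_id))
    presence[seq_len(n_tr), ] <- TRUE
    if (n_mid > 0 && R >= 3) {
      for (i in seq_len(n_mid)) {
        sz <- sample(2:(R - 1), 1)
        presence[n_tr + i, sample.int(R, sz)] <- TRUE
      }
    }
    if (n_pr > 0) {
      for (i in seq_len(n_pr)) presence[n_tr + n_mid + i, sample.int(R, 1)] <- TRUE
    }
    ccf <- ifelse(classes$class == "truncal", 1, runif(n_mut, 0.5, 1))
    depth <- config$sequencing_depth
    grid <- tidyr::expand_grid(mutation_id = classes$mutation_id,
                               region_id = regions$region_id)
    grid$present <- as.vector(t(presence))
    grid$purity <- rep(purity, times = n_mut)
    grid$vaf_true <- ifelse(grid$present,
                            0.5 * grid$purity * rep(ccf, each = R), 0)
    grid$tumor_alt_count <- rbinom(nrow(grid), depth, grid$vaf_true)
    grid <- dplyr::mutate(grid,
      tumor_ref_count = depth - .data$tumor_alt_count,
      tumor_count = depth,
      tumor_vaf = .data$tumor_alt_count / depth,
      normal_alt_count = 0L, normal_ref_count = depth,
      normal_count = depth, normal_vaf = 0,
      power = runif(dplyr::n(), 0.9, 1),
      purity = NULL, vaf_true = NULL)
    list(variants = grid,
         purity = tibble::tibble(region_id = regions$region_id, purity = purity),
         classes = classes)
  })
}

# Minimal inverse codon table (no stop codons) for building CDR3 nt/aa pairs.
aa_codons <- list(
  A = c("GCT", "GCC"), C = c("TGT", "TGC"), D = c("GAT", "GAC"),
  E = c("GAA", "GAG"), F = c("TTT", "TTC"), G = c("GGT", "GGA"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC"), K = c("AAA", "AAG"),
  L = c("CTT", "CTG"), M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCA"), Q = c("CAA", "CAG"), R = c("CGT", "AGA"),
  S = c("TCT", "AGC"), T = c("ACT", "ACC"), V = c("GTT", "GTG"),
  W = "TGG", Y = c("TAT", "TAC")
)

random_cdr3 <- function(n) {
  aas <- names(aa_codons)
  purrr::map_dfr(seq_len(n), function(i) {
    mid <- paste(sample(aas, sample(5:9, 1), replace = TRUE), collapse = "")
    aa <- paste0("CASS", mid, "QYF")
    nt <- paste(vapply(strsplit(aa, "")[[1]],
                       function(a) sample(aa_codons[[a]], 1), ""),
                collapse = "")
    tibble::tibble(cdr3_aa = aa, cdr3_nt = nt)
  })
}

#' Simulate paired DNA and RNA TCR repertoires per region
#'
#' Base clone abundances follow a Zipf law; each non-truncal clone carries a
#' spatial Gaussian bump over the grid modulating its abundance. DNA
#' template counts are multinomial draws from the region-normalized
#' abundances; RNA frequencies are the DNA frequencies times per-clone
#' activation multipliers, renormalized, then multinomially sampled.
#'
#' @param config A [sim_config()].
#' @param regions Region table.
#' @return A list with `clones` (tibble: `sample`, `assay`, `cdr3_nt`,
#'   `cdr3_aa`, `v_gene`, `j_gene`, `count`, `productive`; zero counts
#'   dropped) and `clone_truth` (per-clone tibble with base abundance,
#'   activation multiplier, truncal flag and bump center).
#' @export
simulate_tcr <- function(config, regions) {
  n <- config$n_clones
  R <- nrow(regions)
  with_stream(config$seed, "tcr", {
    pool <- random_cdr3(n)
    while (anyDuplicated(pool$cdr3_nt)) {
      dup <- which(duplicated(pool$cdr3_nt))
      pool[dup, ] <- random_cdr3(length(dup))
    }
    pool <- dplyr::mutate(pool,
      clone_id = sprintf("C%03d", seq_len(n)),
      v_gene = sample(sprintf("TRBV%d-1", c(2, 5, 6, 7, 9, 12, 19, 28)), n, TRUE),
      j_gene = sample(sprintf("TRBJ%d-%d", c(1, 1, 2, 2), c(1, 2, 1, 7)), n, TRUE),
      productive = !(seq_len(n) %in%
        sample.int(n, ceiling(config$nonproductive_fraction * n))),
      base_abundance = seq_len(n)^(-config$zipf_exponent),
      multiplier = config$activation_multipliers,
      truncal = seq_len(n) <= config$truncal_clone_count)
    centers <- regions[sample.int(R, n, replace = TRUE), c("section", "x", "y")]
    pool$center_section <- centers$section
    pool$center_x <- centers$x
    pool$center_y <- centers$y
    spatial_weight <- function(i, j) {
      d2 <- (regions$x[j] - pool$center_x[i])^2 +
        (regions$y[j] - pool$center_y[i])^2 +
        (regions$section[j] - pool$center_section[i])^2
      if (pool$truncal[i]) {
        # ubiquitous clones: mild spatial modulation, never absent
        0.5 + exp(-d2 / (2 * (2 * config$clone_spatial_sd)^2))
      } else {
        0.02 + exp(-d2 / (2 * config$clone_spatial_sd^2))
      }
    }
    w <- outer(seq_len(n), seq_len(R), Vectorize(spatial_weight))
    clone_rows <- purrr::map_dfr(seq_len(R), function(j) {
      ab <- pool$base_abundance * w[, j]
      p_dna <- ab / sum(ab)
      dna <- as.integer(rmultinom(1, config$reads_per_region, p_dna))
      p_rna <- p_dna * pool$multiplier
      p_rna <- p_rna / sum(p_rna)
      rna <- as.integer(rmultinom(1, config$reads_per_region, p_rna))
      dplyr::bind_rows(
        tibble::tibble(sample = regions$region_id[j], assay = "DNA",
                       clone_id = pool$clone_id, count = dna),
        tibble::tibble(sample = regions$region_id[j], assay = "RNA",
                       clone_id = pool$clone_id, count = rna)
      )
    })
    clones <- clone_rows |>
      dplyr::filter(.data$count > 0) |>
      dplyr::left_join(pool[c("clone_id", "cdr3_nt", "cdr3_aa", "v_gene",
                              "j_gene", "productive")], by = "clone_id") |>
      dplyr::select("sample", "assay", "cdr3_nt", "cdr3_aa", "v_gene",
                    "j_gene", "count", "productive")
    list(clones = clones, clone_truth = pool)
  })
}

#' Simulate mutations along a known clone tree
#'
#' Generates a homoplasy-free binary mutation matrix: a random bifurcating
#' clone tree over the regions, `n_per_clade` diagnostic mutations for
#' every non-trivial clade (present in exactly that clade's regions),
#' plus truncal (all-region) and private (single-region) mutations.
#' Because every character is a clean clade marker, distance-based tree
#' reconstruction should recover the generating topology exactly.
#'
#' @param n_regions Number of regions (tree leaves, >= 4).
#' @param n_per_clade Diagnostic mutations per internal clade (default 5).
#' @param n_truncal Truncal mutations (default 5).
#' @param n_private Private mutations per region (default 1).
#' @param seed RNG seed.
#' @return A list: `matrix` (mutation x region binary tibble) and `tree`
#'   (the generating `phylo` topology).
#' @export
simulate_clonal_mutations <- function(n_regions, n_per_clade = 5,
                                      n_truncal = 5, n_private = 1,
                                      seed = 1) {
  if (n_regions < 4) abort("need at least 4 regions.")
  withr::with_seed(seed, {
    tree <- ape::rtree(n_regions, tip.label = sprintf("R%02d", seq_len(n_regions)))
    labs <- tree$tip.label
    clades <- ape::prop.part(tree)
    clade_sets <- lapply(clades, function(i) labs[i])
    clade_sets <- clade_sets[lengths(clade_sets) < n_regions &
                               lengths(clade_sets) >= 2]
    rows <- list()
    add <- function(present_in) {
      rows[[length(rows) + 1]] <<- as.integer(labs %in% present_in)
    }
    for (i in seq_len(n_truncal)) add(labs)
    for (s in clade_sets) for (i in seq_len(n_per_clade)) add(s)
    for (l in labs) for (i in seq_len(n_private)) add(l)
    m <- do.call(rbind, rows)
    colnames(m) <- labs
    out <- tibble::as_tibble(m)
    out <- dplyr::mutate(out,
      mutation_id = sprintf("M%03d", dplyr::row_number()), .before = 1)
    list(matrix = out, tree = tree)
  })
}

#' Simulate a complete synthetic spatial tumor
#'
#' Runs every modality of the generator off one master seed and assembles
#' the dataset together with its ground truth. The true cluster label of a
#' region is the set of subclonal copy-number events it carries (truncal
#' events, shared by construction, do not split clusters).
#'
#' @param config A [sim_config()].
#' @return A `spatialith_sim` list: `regions`, `genes`, `segments`,
#'   `counts`, `immune`, `beta`, `probe_map`, `variants`, `tcr`, `truth`,
#'   `config`.
#' @export
simulate_tumor <- function(config = sim_config()) {
  regions <- generate_tumor_grid(config)
  genes <- simulate_gene_annotation(config)
  cn <- simulate_copy_number(config, regions)
  expr <- simulate_expression(config, regions, cn$segments, genes)
  meth <- simulate_methylation(config, expr$counts)
  mut <- simulate_mutations(config, regions)
  tcr <- simulate_tcr(config, regions)
  truncal_chroms <- unique(cn$events$chrom[
    ave(cn$events$region_id, cn$events$chrom, FUN = length) == nrow(regions)])
  cluster_lab <- vapply(regions$region_id, function(r) {
    ev <- cn$events[cn$events$region_id == r &
                      !cn$events$chrom %in% truncal_chroms, ]
    if (nrow(ev) == 0) "baseline" else
      paste(sort(paste0(ev$chrom, "_", ev$type)), collapse = "+")
  }, "")
  structure(list(
    regions = regions, genes = genes, segments = cn$segments,
    counts = expr$counts, immune = expr$immune,
    beta = meth$beta, probe_map = meth$probe_map,
    variants = mut$variants, tcr = tcr$clones,
    truth = list(
      cn_events = cn$events,
      dosage_coefficient = config$dosage_coefficient,
      immune_effect = config$immune_effect,
      immune_genes = genes$gene[genes$immune],
      immune_level = expr$immune,
      baseline = expr$baseline,
      coupled_genes = meth$coupled_genes,
      mutation_classes = mut$classes,
      purity = mut$purity,
      clone_truth = tcr$clone_truth,
      true_clusters = tibble::tibble(region_id = regions$region_id,
                                     cluster = cluster_lab)
    ),
    config = config
  ), class = "spatialith_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits the standard plain-text formats consumed by the package readers:
#' SEG segments, gene BED, counts TSV, beta + probe-map TSV, AIRR-style
#' clone TSV, variant TSV, region-coordinates TSV, and the ground truth as
#' JSON.
#'
#' @param sim A `spatialith_sim` from [simulate_tumor()].
#' @param dir Output directory (created if missing).
#' @return The vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_seg(sim$segments, p("segments.seg"))
  write_gene_bed(sim$genes, p("genes.bed"))
  write_counts(sim$counts, p("counts.tsv"))
  write_table_tsv(sim$beta, p("beta.tsv"))
  write_table_tsv(sim$probe_map, p("probe_map.tsv"))
  write_clones(sim$tcr, p("clones.tsv"))
  write_table_tsv(sim$variants, p("variants.tsv"))
  write_table_tsv(sim$regions, p("regions.tsv"))
  truth <- sim$truth
  truth$clone_truth <- as.data.frame(truth$clone_truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(vapply(c("segments.seg", "genes.bed", "counts.tsv", "beta.tsv",
                     "probe_map.tsv", "clones.tsv", "variants.tsv",
                     "regions.tsv", "truth.json"), p, ""))
}
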