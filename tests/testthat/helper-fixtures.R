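# Deterministic fixtures built in code.

# A tiny repertoire: one clone per count, distinct CDR3s unless `clones`
# names are supplied to force sharing across repertoires.
make_rep <- function(counts, productive = TRUE, clones = NULL,
                     sample = "S1", assay = "DNA") {
  n <- length(counts)
  ids <- clones %||% sprintf("CLONE%02d", seq_len(n))
  tibble::tibble(
    sample = sample, assay = assay,
    cdr3_nt = paste0("TGTGCC", ids), cdr3_aa = paste0("CASS", ids, "F"),
    v_gene = "TRBV5-1", j_gene = "TRBJ2-1",
    count = as.integer(counts),
    productive = rep_len(productive, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Segment tibble from a compact spec: list(chrom, start, end, log2)
make_segments <- function(sample, ...) {
  rows <- list(...)
  tibble::tibble(
    sample = sample,
    chrom = vapply(rows, `[[`, "", 1),
    start = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    end = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    num_mark = 10L,
    log2_ratio = vapply(rows, function(r) as.numeric(r[[4]]), 0)
  )
}

# Gene-keyed counts tibble from a matrix
make_counts <- function(m, transform = "raw") {
  out <- tibble::as_tibble(m, rownames = "gene")
  attr(out, "transform") <- transform
  out
}

# Well-separated Gaussian blobs, samples in rows
make_blobs <- function(seed, n_per = 8, k = 4, p = 50, center_sd = 3,
                       noise_sd = 0.3) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p, 0, center_sd), k, p)
  x <- do.call(rbind, lapply(seq_len(k), function(c)
    centers[rep(c, n_per), ] + matrix(rnorm(n_per * p, 0, noise_sd), n_per, p)))
  rownames(x) <- sprintf("s%02d", seq_len(k * n_per))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}
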