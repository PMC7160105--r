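# Internal helpers shared across modules.

# A counts table is a tibble whose first column is `gene` and whose remaining
# columns are one numeric vector per sample. The transform state ("raw" or
# "log2p1") rides along as an attribute so double-transforms can be caught.

sample_cols <- function(mat) setdiff(names(mat), "gene")

assert_counts <- function(mat, arg = "counts") {
  if (!is.data.frame(mat) || !"gene" %in% names(mat)) {
    abort(sprintf("`%s` must be a data frame with a `gene` column.", arg))
  }
  if (anyDuplicated(mat$gene)) {
    abort(sprintf("`%s` has duplicated gene identifiers.", arg))
  }
  vals <- as.matrix(mat[sample_cols(mat)])
  if (!is.numeric(vals)) abort(sprintf("`%s` sample columns must be numeric.", arg))
  invisible(mat)
}

transform_state <- function(mat) attr(mat, "transform") %||% "raw"

set_transform <- function(mat, state) {
  attr(mat, "transform") <- state
  mat
}

# gene-keyed tibble -> numeric matrix with gene rownames
counts_matrix <- function(mat) {
  m <- as.matrix(mat[sample_cols(mat)])
  rownames(m) <- mat$gene
  m
}

matrix_counts <- function(m, transform = "raw") {
  out <- tibble::as_tibble(m, rownames = "gene")
  set_transform(out, transform)
}

# Deterministic per-modality RNG streams: each simulator draws from its own
# stream derived from the master seed, so adding one modality never perturbs
# the draws of another. Offsets stay well below .Machine$integer.max.
stream_seed <- function(seed, stream) {
  offsets <- c(grid = 11L, cn = 23L, expr = 37L, meth = 41L,
               mut = 53L, tcr = 67L, analysis = 79L)
  if (!stream %in% names(offsets)) abort(paste0("unknown RNG stream: ", stream))
  (abs(as.integer(seed)) %% 1000000L) * 1000L + offsets[[stream]]
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}

# two-group labels -> list(groups = character(2), idx = list of 2 index sets)
split_two_groups <- function(labels, samples) {
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), labels[[1]])
  }
  if (!is.null(names(labels))) labels <- labels[samples]
  labels <- as.character(labels)
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) != 2) abort("exactly two groups are required.")
  idx <- lapply(groups, function(g) which(labels == g))
  if (any(lengths(idx) < 2)) abort("each group needs at least 2 samples.")
  list(groups = groups, idx = idx)
}

# Welch t that tolerates degenerate (zero-variance) input: identical groups
# give t = 0, p = 1; otherwise falls back to stats::t.test.
welch_safe <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = sign(mean(y) - mean(x)) * Inf, p.value = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
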