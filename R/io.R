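#' Read and write SEG copy-number segment tables
#'
#' SEG is the tab-separated segmented copy-number exchange format with
#' columns `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`, `seg.mean`
#' (1-based inclusive coordinates, log2 ratio of observed over reference
#' intensity). `read_seg()` returns the internal segment tibble with columns
#' `sample`, `chrom`, `start`, `end`, `num_mark`, `log2_ratio`.
#'
#' @param path File path.
#' @return `read_seg()` a tibble of segments; `write_seg()` the path,
#'   invisibly.
#' @export
read_seg <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(raw) < 6) abort("SEG file needs 6 columns (ID, chrom, loc.start, loc.end, num.mark, seg.mean).")
  tibble::tibble(
    sample = as.character(raw[[1]]), chrom = as.character(raw[[2]]),
    start = as.integer(raw[[3]]), end = as.integer(raw[[4]]),
    num_mark = as.integer(raw[[5]]), log2_ratio = as.numeric(raw[[6]])
  )
}

#' @rdname read_seg
#' @param segments Segment tibble as returned by [read_seg()] or
#'   [simulate_copy_number()].
#' @export
write_seg <- function(segments, path) {
  out <- tibble::tibble(
    ID = segments$sample, chrom = segments$chrom,
    loc.start = segments$start, loc.end = segments$end,
    num.mark = segments$num_mark %||% NA_integer_,
    seg.mean = segments$log2_ratio
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write gene annotation as BED
#'
#' BED uses 0-based half-open coordinates; the internal gene table uses
#' 1-based inclusive `start`/`end`, so `read_gene_bed()` adds 1 to the start
#' and `write_gene_bed()` subtracts it.
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                         show_col_types = FALSE, comment = "#")
  tibble::tibble(gene = as.character(raw$gene), chrom = as.character(raw$chrom),
                 start = as.integer(raw$start) + 1L, end = as.integer(raw$end))
}

#' @rdname read_gene_bed
#' @param genes Gene annotation tibble (`gene`, `chrom`, `start`, `end`,
#'   1-based inclusive).
#' @export
write_gene_bed <- function(genes, path) {
  out <- tibble::tibble(chrom = genes$chrom, start = genes$start - 1L,
                        end = genes$end, gene = genes$gene)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write gene-by-sample count tables
#'
#' Plain TSV with genes in rows (first column `gene`) and one column per
#' sample.
#'
#' @param path File path.
#' @param transform Transform state to stamp on the returned table
#'   (`"raw"` or `"log2p1"`).
#' @return A counts tibble.
#' @export
read_counts <- function(path, transform = "raw") {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  names(raw)[1] <- "gene"
  set_transform(tibble::as_tibble(raw), transform)
}

#' @rdname read_counts
#' @param counts Counts tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated member genes.
#' Returned as a named list of character vectors; descriptions are kept in
#' the `"descriptions"` attribute.
#'
#' @param path File path.
#' @return `read_gmt()` a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                                 paste(bad, collapse = ", ")))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named descriptions; defaults to the set name.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write AIRR-style TCR clone tables
#'
#' TSV with columns `sample`, `assay` (DNA or RNA), `cdr3_nt`, `cdr3_aa`,
#' `v_gene`, `j_gene`, `count`, `productive`.
#'
#' @param path File path.
#' @return A clone tibble.
#' @export
read_clones <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "assay", "cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
            "count", "productive")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("clone table missing columns: ",
                                 paste(miss, collapse = ", ")))
  dplyr::mutate(tibble::as_tibble(raw[need]),
                count = as.integer(.data$count),
                productive = as.logical(.data$productive))
}

#' @rdname read_clones
#' @param clones Clone tibble.
#' @export
write_clones <- function(clones, path) {
  readr::write_tsv(clones, path)
  invisible(path)
}

#' Read and write generic analysis TSV tables
#'
#' Thin wrappers used for region coordinates, variant calls, methylation
#' betas and probe maps; they exist so every emitted file round-trips
#' through a package reader.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  tibble::as_tibble(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_table_tsv
#' @param x A data frame.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
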