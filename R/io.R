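#' Readers and writers for the pipeline's text dialects
#'
#' All on-disk interval formats are BED-style 0-based half-open; GTF input
#' (1-based inclusive) is converted on parse.
#'
#' @name io
NULL

#' Read transcript records from a GTF/GFF file
#'
#' Uses only rows of the requested feature type and extracts the `gene_id`
#' attribute; both quoted (`gene_id "g1";`) and unquoted (`gene_id=g1`)
#' attribute dialects are accepted. Coordinates are converted from 1-based
#' inclusive to 0-based half-open.
#'
#' @param path GTF/GFF file.
#' @param feature Feature type to keep (default `"transcript"`).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand` suitable
#'   for [merge_transcripts()].
#' @export
read_gtf_transcripts <- function(path, feature = "transcript") {
  cols <- readr::read_tsv(
    path, comment = "#", col_names = c(
      "chrom", "source", "feature", "start", "end",
      "score", "strand", "frame", "attributes"
    ),
    col_types = "cccddcccc", progress = FALSE
  )
  cols <- dplyr::filter(cols, .data$feature == !!feature)
  gid <- stringr::str_match(cols$attributes, 'gene_id[ =]+"?([^";]+)"?')[, 2]
  if (any(is.na(gid))) abort("GTF rows without a gene_id attribute")
  tibble(
    gene_id = gid, chrom = cols$chrom,
    start = cols$start - 1, end = cols$end, strand = cols$strand
  )
}

#' Read and write BED intervals
#'
#' `read_bed()` accepts BED3 or BED6 (`chrom start end [name score strand]`);
#' `write_bed()` emits BED6 with score 0 when absent. Gene models round-trip
#' through BED6 with the gene id in the name column.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `id`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(x) < 3) abort("BED needs at least 3 columns")
  out <- tibble(
    chrom = x[[1]], start = as.numeric(x[[2]]), end = as.numeric(x[[3]])
  )
  if (ncol(x) >= 4) out$id <- x[[4]]
  if (ncol(x) >= 5) out$score <- suppressWarnings(as.numeric(x[[5]]))
  if (ncol(x) >= 6) out$strand <- x[[6]]
  check_intervals(out, path)
}

#' @rdname read_bed
#' @param x Interval tibble (columns `chrom`, `start`, `end`, optional
#'   `id`/`gene_id`, `score`, `strand`).
#' @export
write_bed <- function(x, path) {
  id <- x[["id"]] %||% x[["gene_id"]] %||% paste0("iv", seq_len(nrow(x)))
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    id = id,
    score = x[["score"]] %||% 0,
    strand = x[["strand"]] %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED6
#'
#' Inverse of `write_bed()` on a gene-model tibble: restores `gene_id`,
#' `tss` and `tts` from the name and strand columns.
#' @inheritParams read_bed
#' @param genome Optional named chromosome lengths to attach.
#' @export
read_genes_bed <- function(path, genome = NULL) {
  x <- read_bed(path)
  if (is.null(x$id) || is.null(x$strand)) abort("gene BED must be BED6")
  tibble(
    gene_id = x$id, chrom = x$chrom, start = x$start, end = x$end,
    strand = x$strand,
    tss = ifelse(x$strand == "+", x$start, x$end),
    tts = ifelse(x$strand == "+", x$end, x$start)
  ) -> out
  attr(out, "genome") <- genome
  out
}

#' Read a narrowPeak file
#'
#' Column 10 (summit offset from `start`) is used when present and
#' non-negative; an offset of -1 falls back to the interval midpoint.
#' @inheritParams read_bed
#' @export
read_narrowpeak <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(x) < 3) abort("narrowPeak needs at least 3 columns")
  out <- tibble(
    chrom = x[[1]], start = as.numeric(x[[2]]), end = as.numeric(x[[3]]),
    id = if (ncol(x) >= 4) x[[4]] else paste0("peak", seq_len(nrow(x)))
  )
  if (ncol(x) >= 7) out$score <- suppressWarnings(as.numeric(x[[7]]))
  off <- if (ncol(x) >= 10) suppressWarnings(as.numeric(x[[10]])) else rep(-1, nrow(x))
  off[is.na(off)] <- -1
  out$summit <- ifelse(off >= 0, out$start + off,
                       out$start + floor((out$end - out$start) / 2))
  check_intervals(out, path)
}

#' Read an expression table
#'
#' Tab-separated with header columns `gene_id` and `tpm`; extra columns
#' are ignored.
#' @inheritParams read_bed
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(x))) {
    abort("expression TSV needs header columns gene_id, tpm")
  }
  if (any(x$tpm < 0)) abort("TPM values must be >= 0")
  tibble(gene_id = as.character(x$gene_id), tpm = as.numeric(x$tpm))
}

#' Read GMT gene sets
#'
#' One pathway per line: id, description, then tab-separated gene ids.
#' @inheritParams read_bed
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) abort("GMT lines need id, description and >= 1 gene")
  setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, "", 1L)
  )
}

#' @rdname read_gmt
#' @param pathways Named list of gene-id vectors.
#' @param descriptions Optional named descriptions.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, descriptions[[id]] %||% "na", pathways[[id]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
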