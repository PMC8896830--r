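#' Merge transcripts into one gene model per gene
#'
#' Collapses all transcripts of a gene into a single model spanning the
#' union of its transcripts: `start = min(starts)`, `end = max(ends)`.
#' The TSS/TTS columns report the biological 5'/3' ends (for minus-strand
#' genes the TSS is the `end` coordinate).
#'
#' @param transcripts Data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open coordinates).
#' @param genome Optional named vector of chromosome lengths; when given,
#'   models are checked against chromosome bounds.
#' @return Tibble of gene models (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tts`) sorted by (chrom, start), with `genome`
#'   attached as an attribute when supplied.
#' @export
merge_transcripts <- function(transcripts, genome = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) abort(paste("`transcripts` lacks:", paste(miss, collapse = ", ")))
  if (!nrow(transcripts)) {
    out <- tibble(
      gene_id = character(), chrom = character(), start = double(),
      end = double(), strand = character(), tss = double(), tts = double()
    )
    attr(out, "genome") <- genome
    return(out)
  }
  if (any(transcripts$start >= transcripts$end)) {
    abort("transcripts with start >= end")
  }
  if (!all(transcripts$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  conf <- transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_chrom > 1 | .data$n_strand > 1)
  if (nrow(conf)) {
    abort(paste0(
      "annotation conflict: transcripts of gene(s) ",
      paste(conf$gene_id, collapse = ", "),
      " span multiple chromosomes or strands"
    ))
  }
  out <- transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1], .groups = "drop"
    ) |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tts = ifelse(.data$strand == "+", .data$end, .data$start)
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!is.null(genome)) {
    check_genome(genome)
    bad <- is.na(genome[out$chrom]) | out$end > genome[out$chrom] | out$start < 0
    if (any(bad)) {
      abort(paste("gene model outside chromosome bounds:",
                  paste(out$gene_id[bad], collapse = ", ")))
    }
  }
  attr(out, "genome") <- genome
  as_tibble(out)
}

#' Flanked gene windows for peak assignment
#'
#' Extends each gene model by `upstream` bp 5' of the TSS and `downstream`
#' bp 3' of the TTS (strand-aware), clipped to chromosome bounds.
#'
#' @param genes Tibble of gene models from [merge_transcripts()].
#' @param upstream,downstream Flank sizes in bp (default 4000 each side).
#' @param genome Named vector of chromosome lengths; defaults to the
#'   `genome` attribute of `genes`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` of windows.
#' @export
gene_windows <- function(genes, upstream = 4000, downstream = 4000,
                         genome = attr(genes, "genome")) {
  if (upstream < 0 || downstream < 0) abort("flank sizes must be >= 0")
  if (is.null(genome)) abort("`genome` (chromosome lengths) is required")
  check_genome(genome)
  unknown <- setdiff(unique(genes$chrom), names(genome))
  if (length(unknown)) {
    abort(paste("unknown chromosome(s):", paste(unknown, collapse = ", ")))
  }
  plus <- genes$strand == "+"
  ws <- ifelse(plus, genes$start - upstream, genes$start - downstream)
  we <- ifelse(plus, genes$end + downstream, genes$end + upstream)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0, ws),
    end = pmin(unname(genome[genes$chrom]), we)
  )
}

#' Filter gene models to transcriptionally active genes
#'
#' Keeps genes whose TPM is strictly greater than the given percentile of
#' the TPM distribution over all genes in the set. Genes missing from the
#' expression table are treated as TPM 0 (configurable); the percentile is
#' computed with linear interpolation (type-7 quantile).
#'
#' @param genes Tibble of gene models.
#' @param tpm Data frame with columns `gene_id` and `tpm`.
#' @param percentile Percentile cutoff in `[0, 100)`; default 25.
#' @param missing_as_zero Treat genes absent from `tpm` as 0 (default
#'   TRUE); with FALSE, an empty intersection is an error and absent genes
#'   are dropped before the percentile is computed.
#' @return The retained gene models, with attributes `tpm_threshold` and
#'   `n_total`.
#' @export
filter_expressed <- function(genes, tpm, percentile = 25, missing_as_zero = TRUE) {
  if (percentile < 0 || percentile >= 100) abort("`percentile` must be in [0, 100)")
  if (!all(c("gene_id", "tpm") %in% names(tpm))) {
    abort("`tpm` needs columns gene_id, tpm")
  }
  if (any(tpm$tpm < 0)) abort("TPM values must be >= 0")
  vals <- setNames(tpm$tpm, tpm$gene_id)[genes$gene_id]
  if (!any(!is.na(vals))) abort("no gene in the set has an expression entry")
  keep_genes <- genes
  if (missing_as_zero) {
    vals[is.na(vals)] <- 0
  } else {
    keep_genes <- genes[!is.na(vals), , drop = FALSE]
    vals <- vals[!is.na(vals)]
  }
  thr <- unname(quantile(vals, percentile / 100, type = 7))
  out <- keep_genes[vals > thr, , drop = FALSE]
  attr(out, "genome") <- attr(genes, "genome")
  attr(out, "tpm_threshold") <- thr
  attr(out, "n_total") <- nrow(genes)
  out
}
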