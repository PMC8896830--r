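#' Downstream-of-TTS windows for readthrough quantification
#'
#' For each gene, the strand-aware interval starting at the TTS and
#' extending 3' for up to `window` bp, truncated at the nearest
#' downstream annotated gene boundary or the chromosome end. Genes whose
#' usable window falls below `min_window` bp get no window.
#'
#' @param genes Gene-model tibble (all annotated genes, used both as the
#'   query set and as the truncation neighbors).
#' @param window Maximum window length in bp (default 5000).
#' @param min_window Minimum usable window in bp (default 500).
#' @param genome Named chromosome lengths (defaults to the `genome`
#'   attribute of `genes`).
#' @return Tibble `gene_id`, `chrom`, `start`, `end` for genes with a
#'   usable window.
#' @export
downstream_windows <- function(genes, window = 5000, min_window = 500,
                               genome = attr(genes, "genome")) {
  if (window < 1) abort("`window` must be >= 1")
  if (is.null(genome)) abort("`genome` is required")
  check_genome(genome)
  out <- vector("list", nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    clen <- genome[[ch]]
    if (is.null(clen) || is.na(clen)) abort(paste("unknown chromosome", ch))
    starts <- sort(genes$start[gi])
    ends <- sort(genes$end[gi])
    for (i in gi) {
      if (genes$strand[i] == "+") {
        tts <- genes$end[i]
        j <- findInterval(tts - 0.5, starts) + 1L  # first start >= tts
        lim <- if (j <= length(starts)) min(starts[j], clen) else clen
        a <- tts; b <- min(tts + window, lim)
      } else {
        tts <- genes$start[i]
        j <- findInterval(tts, ends)               # last end <= tts
        lim <- if (j >= 1L) max(ends[j], 0) else 0
        a <- max(tts - window, lim); b <- tts
      }
      if (b - a >= min_window) {
        out[[i]] <- tibble(gene_id = genes$gene_id[i], chrom = ch,
                           start = a, end = b)
      }
    }
  }
  dplyr::bind_rows(out)
}

# fractional read count over a span: sum over reads of overlap / read length
.frac_reads_in <- function(r_start, r_end, a, b, run_end) {
  hi <- findInterval(b - 0.5, r_start)
  lo <- findInterval(a + 0.5, run_end) + 1L
  if (lo > hi) return(0)
  j <- lo:hi
  ov <- pmax(0, pmin(r_end[j], b) - pmax(r_start[j], a))
  sum(ov / (r_end[j] - r_start[j]))
}

#' Per-gene readthrough index
#'
#' Computes the gene-body RPKM and the downstream-window RPKM for each
#' gene with a usable window; the readthrough index is their ratio.
#' Genes with body RPKM below `min_body_rpkm` are excluded (counted in
#' `attr(, "n_excluded")`).
#'
#' @param reads Read tibble (`chrom`, `start`, `end`).
#' @param genes Gene-model tibble.
#' @param windows Downstream windows from [downstream_windows()].
#' @param min_body_rpkm Expression floor for the body density (default 1).
#' @param total_mapped Library size for RPKM (default `nrow(reads)`).
#' @param condition Condition label carried into the records.
#' @return Tibble `gene_id`, `body_rpkm`, `downstream_rpkm`, `index`,
#'   `condition`.
#' @export
readthrough_table <- function(reads, genes, windows, min_body_rpkm = 1,
                              total_mapped = nrow(reads), condition = "A") {
  check_intervals(reads, "reads")
  if (any(windows$end <= windows$start)) abort("zero-length downstream window")
  if (total_mapped <= 0) abort("`total_mapped` must be positive")
  g <- genes[match(windows$gene_id, genes$gene_id), ]
  body <- down <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    ri <- which(reads$chrom == ch)
    o <- order(reads$start[ri])
    rs <- reads$start[ri][o]; re <- reads$end[ri][o]
    run_end <- cummax(re %g0% numeric(0))
    wi <- which(windows$chrom == ch)
    for (i in wi) {
      if (!length(rs)) next
      body[i] <- .frac_reads_in(rs, re, g$start[i], g$end[i], run_end)
      down[i] <- .frac_reads_in(rs, re, windows$start[i], windows$end[i], run_end)
    }
  }
  rpkm <- function(cnt, len) cnt * 1e9 / (len * total_mapped)
  out <- tibble(
    gene_id = windows$gene_id,
    body_rpkm = rpkm(body, g$end - g$start),
    downstream_rpkm = rpkm(down, windows$end - windows$start),
    condition = condition
  )
  keep <- out$body_rpkm >= min_body_rpkm
  out$index <- ifelse(out$body_rpkm > 0, out$downstream_rpkm / out$body_rpkm, NA)
  out <- out[keep, c("gene_id", "body_rpkm", "downstream_rpkm", "index", "condition")]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Compare readthrough between two conditions
#'
#' Joins the per-gene readthrough indices of two conditions, flags genes
#' whose index increased in condition B beyond a ratio margin (and an
#' absolute floor), and tests the global index shift with a two-sided
#' rank test. Because the indices are matched per gene across the two
#' conditions, the global p-value comes from the Wilcoxon rank test on
#' the paired differences; the classical Mann-Whitney rank-sum U over
#' the two index distributions is reported alongside.
#'
#' @param condA,condB Readthrough tibbles from [readthrough_table()].
#' @param margin Minimum B/A index ratio to call a gene enriched
#'   (default 1.5).
#' @param min_index Minimum B index to call enrichment, so that genes
#'   with a zero A index are not flagged on a stray read (default 0.05).
#' @return A `readthrough_comparison` object: per-gene `table`
#'   (`gene_id`, `index_a`, `index_b`, `delta`, `ratio`, `enriched`),
#'   the `enriched` gene ids, `mw_u` (rank-sum U of B vs A), and
#'   `p_value`/`v_statistic` from the paired rank test over the `n`
#'   shared genes. Supports [tidy()] and [glance()].
#' @export
compare_readthrough <- function(condA, condB, margin = 1.5, min_index = 0.05) {
  shared <- intersect(condA$gene_id, condB$gene_id)
  if (length(shared) < 2) abort("fewer than 2 shared genes between conditions")
  ia <- condA$index[match(shared, condA$gene_id)]
  ib <- condB$index[match(shared, condB$gene_id)]
  enriched <- ib > margin * ia & ib >= min_index
  tab <- tibble(
    gene_id = shared, index_a = ia, index_b = ib,
    delta = ib - ia, ratio = ifelse(ia > 0, ib / ia, ifelse(ib > 0, Inf, 1)),
    enriched = enriched
  )
  rs <- suppressWarnings(wilcox.test(ib, ia, alternative = "two.sided"))
  pt <- if (any(ib != ia)) {
    suppressWarnings(wilcox.test(ib, ia, paired = TRUE,
                                 alternative = "two.sided"))
  } else list(statistic = c(V = 0), p.value = 1)
  structure(
    list(
      table = tab, enriched = shared[enriched],
      mw_u = unname(rs$statistic), v_statistic = unname(pt$statistic),
      p_value = pt$p.value, p_ranksum = rs$p.value, n = length(shared),
      margin = margin, min_index = min_index
    ),
    class = "readthrough_comparison"
  )
}

#' @export
print.readthrough_comparison <- function(x, ...) {
  cat(sprintf(
    "<readthrough_comparison> n = %d shared genes, %d enriched in B, U = %.1f, p = %.4g\n",
    x$n, length(x$enriched), x$mw_u, x$p_value
  ))
  invisible(x)
}

#' Readthrough metagene with fixed body scaling
#'
#' Convenience wrapper around [gene_metagene()] with the readthrough
#' convention: every gene body is rescaled to `body_target` bp and binned
#' at `bin` bp (20 body bins by default), with `flank` bp added upstream
#' of the TSS and downstream of the TTS in `bin`-bp bins.
#'
#' @inheritParams gene_metagene
#' @param body_target Virtual body length in bp (default 2000).
#' @param bin Bin width for body and flanks (default 100).
#' @param flank Flank width in bp (default 1000).
#' @export
readthrough_metagene <- function(track, genes, body_target = 2000, bin = 100,
                                 flank = 1000, min_body_length = 120) {
  if (body_target %% bin != 0) abort("`body_target` must be divisible by `bin`")
  gene_metagene(track, genes, body_bins = as.integer(body_target / bin),
                flank = flank, flank_bin = bin,
                min_body_length = min_body_length)
}
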