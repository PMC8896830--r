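#' Intersect differential-expression calls with dual-marked genes
#'
#' Computes the fractions of significantly down- and upregulated genes
#' that are dual-marked (carry overlapping 5hmC and R-loop marks), with
#' the underlying gene lists.
#'
#' @param de DE table: `gene_id`, `log_fc`, `significant` (logical).
#' @param marks A [classify_gene_marks()] table.
#' @return List with `frac_down_dual`, `frac_up_dual`, `down_dual`,
#'   `up_dual` (gene-id vectors), `n_down`, `n_up`. With no significant
#'   genes the fractions are `NA` and `empty` is TRUE.
#' @export
intersect_de_with_marks <- function(de, marks) {
  need <- c("gene_id", "log_fc", "significant")
  if (!all(need %in% names(de))) abort("`de` needs gene_id, log_fc, significant")
  dual <- marks$gene_id[marks$has_both]
  sig <- de[de$significant, , drop = FALSE]
  down <- sig$gene_id[sig$log_fc < 0]
  up <- sig$gene_id[sig$log_fc > 0]
  frac <- function(g) {
    if (!length(g)) return(NA_real_)
    mean(g %in% dual)
  }
  list(
    frac_down_dual = frac(down), frac_up_dual = frac(up),
    down_dual = intersect(down, dual), up_dual = intersect(up, dual),
    n_down = length(down), n_up = length(up),
    empty = nrow(sig) == 0
  )
}

#' Fisher's exact p-value for a 2x2 enrichment table
#'
#' The one-sided (enrichment) p-value is the hypergeometric upper tail
#' `P(X >= k)` for `k` hits when drawing `n` genes from a background of
#' `N` containing `K` pathway genes; `"two.sided"` uses the standard
#' Fisher's exact two-sided rule.
#'
#' @param k,K,n,N Table margins: hits in the gene set, pathway size,
#'   gene-set size, background size. `k` may be a vector.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @export
fisher_table_p <- function(k, K, n, N, alternative = "greater") {
  if (any(k > pmin(K, n)) || K > N || n > N || any(k < pmax(0, n + K - N))) {
    abort("inconsistent 2x2 table margins")
  }
  if (alternative == "greater") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    vapply(k, function(ki) {
      stats::fisher.test(
        matrix(c(ki, n - ki, K - ki, N - K - n + ki), 2),
        alternative = "two.sided"
      )$p.value
    }, 0)
  }
}

#' Fisher's exact pathway enrichment with BH control
#'
#' Tests each pathway for over-representation of `gene_set` against an
#' expressed-gene `background` using the one-sided Fisher's exact
#' (hypergeometric tail) test, with Benjamini-Hochberg q-values over the
#' tested pathways. Pathway genes outside the background are dropped
#' before testing; pathways left empty are not tested.
#'
#' @param gene_set Character vector of gene ids (must be a subset of
#'   `background`).
#' @param pathways Named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector of background gene ids.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @param q_cutoff Significance flag threshold on the q-value
#'   (default 0.05).
#' @return Tibble sorted by p: `pathway_id`, `k` (hits), `K` (pathway
#'   size in background), `n` (gene-set size), `N` (background size),
#'   `odds_ratio`, `p`, `fdr_q`, `significant`. The number of pathway
#'   genes dropped for being outside the background is in
#'   `attr(, "n_dropped_genes")`.
#' @export
fisher_enrichment <- function(gene_set, pathways, background,
                              alternative = c("greater", "two.sided"),
                              q_cutoff = 0.05) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!length(background)) abort("empty background")
  outside <- setdiff(gene_set, background)
  if (length(outside)) {
    abort(paste("gene_set contains genes outside the background:",
                paste(utils::head(outside, 5), collapse = ", ")))
  }
  N <- length(background)
  n <- length(gene_set)
  dropped <- 0L
  rows <- lapply(names(pathways), function(pid) {
    pw <- unique(pathways[[pid]])
    inbg <- intersect(pw, background)
    dropped <<- dropped + (length(pw) - length(inbg))
    if (!length(inbg)) return(NULL)
    K <- length(inbg)
    k <- length(intersect(inbg, gene_set))
    p <- fisher_table_p(k, K, n, N, alternative)
    or_num <- k * (N - K - n + k)
    or_den <- (n - k) * (K - k)
    tibble(
      pathway_id = pid, k = k, K = K, n = n, N = N,
      odds_ratio = if (or_den == 0) {
        if (or_num == 0) NaN else Inf
      } else or_num / or_den,
      p = p
    )
  })
  rows <- dplyr::bind_rows(rows)
  if (!nrow(rows)) abort("no pathway overlaps the background")
  rows$fdr_q <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$fdr_q < q_cutoff
  rows <- dplyr::arrange(rows, .data$p)
  attr(rows, "n_dropped_genes") <- dropped
  attr(rows, "q_cutoff") <- q_cutoff
  rows
}
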