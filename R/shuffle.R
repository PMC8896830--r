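#' Shuffle universe of annotated-gene segments
#'
#' The permutation null re-places intervals uniformly within a constrained
#' universe, by default the merged bodies of annotated genes. Overlapping
#' segments are merged so the universe is internally disjoint.
#'
#' @param segments Data frame of intervals (`chrom`, `start`, `end`),
#'   typically gene models.
#' @return Tibble of disjoint sorted segments with the total length in
#'   `attr(, "total_length")`.
#' @export
shuffle_universe <- function(segments) {
  red <- reduce_intervals(segments)
  if (!nrow(red)) abort("empty shuffle universe")
  attr(red, "total_length") <- sum(red$end - red$start)
  red
}

# place a vector of interval lengths uniformly over all valid start
# positions across segments; returns start positions and segment indices
.place_lengths <- function(lens, seg_start, seg_len, within = NULL) {
  n <- length(lens)
  start <- numeric(n); seg <- integer(n)
  idx_of <- if (is.null(within)) list(seq_along(seg_len)) else within$groups
  grp_of <- if (is.null(within)) rep(1L, n) else within$len_groups
  for (g in unique(grp_of)) {
    segs <- idx_of[[g]]
    li <- which(grp_of == g)
    for (l in unique(lens[li])) {
      vs <- pmax(seg_len[segs] - l + 1, 0)
      if (all(vs == 0)) {
        abort(sprintf("infeasible shuffle: interval of length %d fits no segment", l))
      }
      k <- li[lens[li] == l]
      pick <- if (length(segs) == 1L) rep(1L, length(k)) else {
        sample.int(length(segs), length(k), replace = TRUE, prob = vs)
      }
      off <- pmin(floor(runif(length(k)) * vs[pick]), vs[pick] - 1)
      seg[k] <- segs[pick]
      start[k] <- seg_start[segs[pick]] + off
    }
  }
  list(start = start, seg = seg)
}

#' Re-place intervals uniformly within a universe
#'
#' Produces a random interval set with exactly the multiset of source
#' lengths, each interval contained in one universe segment. Placement is
#' uniform over all valid start positions: a segment is chosen with
#' probability proportional to its number of valid starts for the length
#' being placed. Placed intervals may overlap one another.
#'
#' @param source Data frame of intervals whose lengths are preserved.
#' @param universe A [shuffle_universe()].
#' @param seed Optional integer seed; a fixed seed gives identical output.
#' @param within_chrom Keep each interval on its original chromosome
#'   (default FALSE: placement anywhere in the universe).
#' @return Tibble of placed intervals (`chrom`, `start`, `end`, `id`).
#' @export
shuffle_intervals <- function(source, universe, seed = NULL,
                              within_chrom = FALSE) {
  check_intervals(source, "source")
  run <- function() {
    lens <- source$end - source$start
    seg_len <- universe$end - universe$start
    within <- NULL
    if (within_chrom) {
      chroms <- unique(source$chrom)
      within <- list(
        groups = lapply(chroms, function(ch) which(universe$chrom == ch)),
        len_groups = match(source$chrom, chroms)
      )
      if (any(!lengths(within$groups))) {
        abort("within_chrom: a source chromosome has no universe segment")
      }
    }
    pl <- .place_lengths(lens, universe$start, seg_len, within)
    tibble(
      chrom = universe$chrom[pl$seg],
      start = pl$start, end = pl$start + lens,
      id = source[["id"]] %||% seq_len(nrow(source))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Permutation test of interval-set overlap
#'
#' Tests whether the observed number of `setA` intervals overlapping
#' `setB` exceeds what uniform placement within the universe would give.
#' Each of `n_shuffles` iterations re-places both sets (or only `setA`)
#' with lengths and counts preserved and recomputes the overlap count.
#' The empirical p-value uses the add-one rule
#' `(1 + #[null >= observed]) / (1 + N)`; the raw exceedance frequency is
#' also reported.
#'
#' @param setA,setB Non-empty interval data frames; `setA` is the query
#'   of the overlap count.
#' @param universe A [shuffle_universe()].
#' @param n_shuffles Number of shuffles N (default 1000).
#' @param seed Integer master seed (required; all iteration randomness
#'   derives from it).
#' @param shuffle_both Re-place both sets each iteration (default TRUE)
#'   or only `setA`.
#' @param alternative `"greater"` (enrichment, default), `"less"`, or
#'   `"two.sided"`.
#' @param within_chrom Passed to [shuffle_intervals()].
#' @return A `perm_test` object: `observed`, `null`, `p_value`, `p_raw`,
#'   `n_shuffles`, `seed`, `statistic_name`, plus the shared-bp observed
#'   value. Supports [tidy()], [glance()] and [autoplot()].
#' @export
permutation_overlap_test <- function(setA, setB, universe, n_shuffles = 1000,
                                     seed, shuffle_both = TRUE,
                                     alternative = c("greater", "less", "two.sided"),
                                     within_chrom = FALSE) {
  alternative <- match.arg(alternative)
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1")
  if (!nrow(setA) || !nrow(setB)) abort("both interval sets must be non-empty")
  if (missing(seed) || is.null(seed)) abort("`seed` is required for reproducibility")
  check_intervals(setA, "setA"); check_intervals(setB, "setB")
  obs <- overlap_stat(setA, setB)
  lensA <- setA$end - setA$start
  lensB <- setB$end - setB$start
  seg_start <- universe$start
  seg_len <- universe$end - universe$start
  seg_chrom <- universe$chrom
  withinA <- withinB <- NULL
  if (within_chrom) {
    mk <- function(s) {
      chroms <- unique(s$chrom)
      list(groups = lapply(chroms, function(ch) which(seg_chrom == ch)),
           len_groups = match(s$chrom, chroms))
    }
    withinA <- mk(setA); withinB <- mk(setB)
  }
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_shuffles), function(i) {
      pa <- .place_lengths(lensA, seg_start, seg_len, withinA)
      if (shuffle_both) {
        pb <- .place_lengths(lensB, seg_start, seg_len, withinB)
        .overlap_count1(seg_chrom[pa$seg], pa$start, pa$start + lensA,
                        seg_chrom[pb$seg], pb$start, pb$start + lensB)
      } else {
        .overlap_count1(seg_chrom[pa$seg], pa$start, pa$start + lensA,
                        setB$chrom, setB$start, setB$end)
      }
    }, 0L)
  })
  p_ge <- (1 + sum(null >= obs$count)) / (1 + n_shuffles)
  p_le <- (1 + sum(null <= obs$count)) / (1 + n_shuffles)
  p <- switch(alternative,
    greater = p_ge, less = p_le, two.sided = min(1, 2 * min(p_ge, p_le))
  )
  structure(
    list(
      observed = obs$count, shared_bp = obs$shared_bp, null = null,
      p_value = p, p_raw = mean(null >= obs$count),
      n_shuffles = n_shuffles, seed = as.integer(seed),
      statistic_name = "n_query_overlapping", alternative = alternative,
      shuffle_both = shuffle_both, n_query = obs$n_query
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed %s = %d (of %d), null mean %.2f [N=%d], p = %.4g (%s)\n",
    x$statistic_name, x$observed, x$n_query, mean(x$null), x$n_shuffles,
    x$p_value, x$alternative
  ))
  invisible(x)
}

#' Classify active genes by mark co-occurrence
#'
#' Labels each active gene for presence of each mark from the
#' peak-to-gene assignments and calls a gene dual-marked (`has_both`)
#' when it carries at least one assigned peak of each mark and, by
#' default, at least one 5hmC peak and one R-loop region overlap each
#' other within the gene window.
#'
#' @param active Active gene-model tibble.
#' @param hmc_assign,rloop_assign Assignment tibbles from
#'   [assign_to_genes()] (columns `gene_id`, `peak_id`) for the 5hmC and
#'   R-loop sets.
#' @param hmc_peaks,rloop_regions The peak tibbles (with `id`); required
#'   when `require_mutual_overlap` is TRUE.
#' @param windows Gene windows used for the assignment (clips the mutual
#'   overlap check); defaults to the gene bodies.
#' @param require_mutual_overlap Require a 5hmC/R-loop pair to overlap
#'   within the gene (default TRUE); FALSE counts co-assignment only.
#' @return A `gene_mark_table` tibble (`gene_id`, `has_5hmc`,
#'   `has_rloop`, `has_both`) whose [glance()] gives counts and
#'   percentages over the active-gene denominator.
#' @export
classify_gene_marks <- function(active, hmc_assign, rloop_assign,
                                hmc_peaks = NULL, rloop_regions = NULL,
                                windows = NULL,
                                require_mutual_overlap = TRUE) {
  stray <- setdiff(c(hmc_assign$gene_id, rloop_assign$gene_id), active$gene_id)
  if (length(stray)) {
    abort(paste("mark assignments refer to genes outside the active set:",
                paste(utils::head(stray, 5), collapse = ", ")))
  }
  if (require_mutual_overlap && (is.null(hmc_peaks) || is.null(rloop_regions))) {
    abort("mutual-overlap classification needs `hmc_peaks` and `rloop_regions`")
  }
  if (is.null(windows)) {
    windows <- tibble(gene_id = active$gene_id, chrom = active$chrom,
                      start = active$start, end = active$end)
  }
  has_h <- active$gene_id %in% hmc_assign$gene_id
  has_r <- active$gene_id %in% rloop_assign$gene_id
  both <- has_h & has_r
  if (require_mutual_overlap && any(both)) {
    hmap <- split(hmc_assign$peak_id, hmc_assign$gene_id)
    rmap <- split(rloop_assign$peak_id, rloop_assign$gene_id)
    wmap <- windows[match(active$gene_id, windows$gene_id), ]
    for (i in which(both)) {
      gid <- active$gene_id[i]
      hp <- hmc_peaks[hmc_peaks$id %in% hmap[[gid]], , drop = FALSE]
      rp <- rloop_regions[rloop_regions$id %in% rmap[[gid]], , drop = FALSE]
      clip <- function(p) {
        p$start <- pmax(p$start, wmap$start[i]); p$end <- pmin(p$end, wmap$end[i])
        p[p$start < p$end, , drop = FALSE]
      }
      hp <- clip(hp); rp <- clip(rp)
      both[i] <- nrow(hp) > 0 && nrow(rp) > 0 && overlap_stat(hp, rp)$count > 0
    }
  }
  out <- tibble(
    gene_id = active$gene_id,
    has_5hmc = has_h, has_rloop = has_r, has_both = both
  )
  class(out) <- c("gene_mark_table", class(out))
  out
}

#' Pearson correlation of two binned signals over active genes
#'
#' Builds the gene-body bin vector of each track over the active genes
#' (strand-oriented, `body_bins` per gene), concatenates across genes and
#' returns the Pearson product-moment correlation with its two-sided
#' p-value.
#'
#' @param trackA,trackB [coverage_track()]s with identical binning and
#'   normalization.
#' @param active Active gene-model tibble.
#' @param body_bins Bins per gene body (default 60).
#' @param drop_zero_bins Drop bins where both signals are zero (default
#'   FALSE: retained).
#' @param min_body_length Passed to the body binning (default 120).
#' @return One-row tibble `pearson_r`, `p_value`, `n_bins_used`.
#' @export
binned_signal_correlation <- function(trackA, trackB, active, body_bins = 60,
                                      drop_zero_bins = FALSE,
                                      min_body_length = 120) {
  if (trackA$bin_size != trackB$bin_size ||
      trackA$normalization != trackB$normalization) {
    abort("tracks must share bin size and normalization")
  }
  va <- vb <- numeric(0)
  for (i in seq_len(nrow(active))) {
    g <- active[i, ]
    len <- g$end - g$start
    if (len < min_body_length) next
    breaks <- g$start + (0:body_bins) * (len / body_bins)
    ra <- .step_bin_means(trackA$values[[g$chrom]], trackA$bin_size, breaks)
    rb <- .step_bin_means(trackB$values[[g$chrom]], trackB$bin_size, breaks)
    if (g$strand == "-") { ra <- rev(ra); rb <- rev(rb) }
    va <- c(va, ra); vb <- c(vb, rb)
  }
  if (drop_zero_bins) {
    keep <- va != 0 | vb != 0
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 3) abort("fewer than 3 usable bins")
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("undefined correlation: a concatenated signal vector is constant")
  }
  ct <- cor.test(va, vb, method = "pearson")
  tibble(
    pearson_r = unname(ct$estimate), p_value = ct$p.value,
    n_bins_used = length(va)
  )
}
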