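#' Interval algebra for peak and region sets
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval covers bases `start .. end - 1`.
#'
#' @name intervals
NULL

# cumulative covered-bp function of a disjoint sorted interval set;
# returns F(x) = number of covered bases in [0, x)
.coverage_fun <- function(bs, be) {
  cumlen <- cumsum(be - bs)
  function(x) {
    idx <- findInterval(x, bs)
    full <- c(0, cumlen)[idx + 1]
    over <- numeric(length(x))
    pos <- which(idx > 0)
    if (length(pos)) {
      i <- idx[pos]
      over[pos] <- pmin(pmax(0, be[i] - pmax(x[pos], bs[i])), be[i] - bs[i])
    }
    full - over
  }
}

# per-query bp shared with the union of a disjoint sorted subject set
.shared_with_union <- function(qs, qe, bs, be) {
  if (!length(bs) || !length(qs)) return(numeric(length(qs)))
  f <- .coverage_fun(bs, be)
  f(qe) - f(qs)
}

# max single-interval overlap of each query with a start-sorted subject set
.max_single_overlap <- function(qs, qe, bs, be) {
  n <- length(qs)
  out <- numeric(n)
  if (!length(bs) || !n) return(out)
  run_end <- cummax(be)
  for (i in seq_len(n)) {
    hi <- findInterval(qe[i] - 0.5, bs)
    if (hi == 0L) next
    lo <- findInterval(qs[i] + 0.5, run_end) + 1L
    if (lo > hi) next
    j <- lo:hi
    out[i] <- max(0, max(pmin(qe[i], be[j]) - pmax(qs[i], bs[j])))
  }
  out
}

#' Overlap statistic between two interval sets
#'
#' Counts the query intervals that overlap the subject set by at least
#' `min_bp` and totals the base pairs each query interval shares with the
#' union of the subject intervals. This count of overlapping regions is the
#' observed statistic of the permutation co-localization test.
#'
#' @param query,subject Data frames of intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `id`.
#' @param min_bp Minimum overlap, in bp, with a single subject interval for
#'   a query interval to count as overlapping.
#' @return A list with `count` (query intervals overlapping), `shared_bp`
#'   (summed intersection with the subject union), `ids` (ids or row
#'   indices of the overlapping query intervals) and `n_query`.
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' s <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' overlap_stat(q, s)
#' @export
overlap_stat <- function(query, subject, min_bp = 1) {
  check_intervals(query, "query")
  check_intervals(subject, "subject")
  if (min_bp < 1) abort("`min_bp` must be >= 1")
  ids <- if ("id" %in% names(query)) query[["id"]] else seq_len(nrow(query))
  if (!nrow(query)) {
    return(list(count = 0L, shared_bp = 0, ids = ids[0], n_query = 0L))
  }
  red <- reduce_intervals(subject)
  sub_sorted <- dplyr::arrange(subject, .data$chrom, .data$start)
  hit <- logical(nrow(query))
  shared <- numeric(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    qs <- query$start[qi]; qe <- query$end[qi]
    ri <- red$chrom == ch
    shared[qi] <- .shared_with_union(qs, qe, red$start[ri], red$end[ri])
    if (min_bp == 1) {
      hit[qi] <- shared[qi] > 0
    } else {
      si <- sub_sorted$chrom == ch
      mo <- .max_single_overlap(qs, qe, sub_sorted$start[si], sub_sorted$end[si])
      hit[qi] <- mo >= min_bp
    }
  }
  list(
    count = sum(hit),
    shared_bp = sum(shared),
    ids = ids[hit],
    n_query = nrow(query)
  )
}

# fast path used inside the permutation loop: count of query intervals
# overlapping >= 1 bp with the union of subject (subject need not be reduced)
.overlap_count1 <- function(q_chrom, qs, qe, s_chrom, ss, se) {
  total <- 0L
  for (ch in unique(q_chrom)) {
    si <- which(s_chrom == ch)
    if (!length(si)) next
    o <- order(ss[si])
    bs <- ss[si][o]; be <- se[si][o]
    run_end <- cummax(be)
    qi <- which(q_chrom == ch)
    # a query [a,b) overlaps the union iff some subject has bs < b and be > a
    hi <- findInterval(qe[qi] - 0.5, bs)
    lo <- findInterval(qs[qi] + 0.5, run_end) + 1L
    total <- total + sum(hi >= lo)
  }
  total
}

#' Locate peak summits
#'
#' The summit is the position of maximum signal within a peak; ties break
#' to the leftmost maximum. With no signal supplied the summit falls back
#' to the interval midpoint (floored).
#'
#' @param peaks Data frame of peak intervals (`chrom`, `start`, `end`).
#' @param track Optional [coverage_track()]; per-base signal is the value
#'   of the containing bin.
#' @param values Optional list of per-base numeric vectors, one per peak
#'   row (overrides `track`).
#' @return `peaks` with a `summit` column (0-based position,
#'   `start <= summit < end`).
#' @export
peak_summits <- function(peaks, track = NULL, values = NULL) {
  check_intervals(peaks, "peaks")
  n <- nrow(peaks)
  if (!is.null(values) && length(values) != n) {
    abort("`values` must supply one per-base vector per peak")
  }
  summit <- numeric(n)
  for (i in seq_len(n)) {
    s <- peaks$start[i]; e <- peaks$end[i]
    v <- NULL
    if (!is.null(values)) {
      v <- values[[i]]
      if (length(v) != e - s) abort("per-base values must cover the peak interval")
    } else if (!is.null(track)) {
      v <- track_values(track, peaks$chrom[i], s, e)
    }
    summit[i] <- if (is.null(v)) s + floor((e - s) / 2) else s + which.max(v) - 1
  }
  peaks$summit <- summit
  peaks
}

#' Assign peaks to flanked gene windows
#'
#' A peak is assigned to every gene whose window it overlaps by at least
#' 1 bp; a peak spanning two windows is assigned to both. Peaks hitting no
#' window are reported in the `"unassigned"` attribute.
#'
#' @param peaks Data frame of intervals with unique `id`.
#' @param windows Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (typically from [gene_windows()]).
#' @return Tibble with one row per (gene_id, peak_id) assignment; the ids
#'   of unassigned peaks are in `attr(, "unassigned")`.
#' @export
assign_to_genes <- function(peaks, windows) {
  check_intervals(peaks, "peaks", need_id = TRUE)
  check_intervals(windows, "windows")
  if (!"gene_id" %in% names(windows)) abort("`windows` needs a `gene_id` column")
  rows <- list()
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    wi <- which(windows$chrom == ch)
    if (!length(wi)) next
    o <- order(windows$start[wi])
    ws <- windows$start[wi][o]; we <- windows$end[wi][o]
    wid <- windows$gene_id[wi][o]
    run_end <- cummax(we)
    for (p in pi) {
      hi <- findInterval(peaks$end[p] - 0.5, ws)
      lo <- findInterval(peaks$start[p] + 0.5, run_end) + 1L
      if (lo > hi) next
      j <- lo:hi
      j <- j[we[j] > peaks$start[p] & ws[j] < peaks$end[p]]
      if (length(j)) {
        rows[[length(rows) + 1L]] <- tibble(gene_id = wid[j], peak_id = peaks$id[p])
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(gene_id = character(), peak_id = peaks$id[0])
  }
  attr(out, "unassigned") <- setdiff(peaks$id, out$peak_id)
  out
}
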