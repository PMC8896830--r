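#' Extend reads in the 3' direction
#'
#' Reads shorter than `target_length` are extended on their 3' side (the
#' 5' end stays fixed) to the target length, clipped at chromosome
#' bounds; longer reads are unchanged.
#'
#' @param reads Tibble `chrom`, `start`, `end`, `strand`.
#' @param target_length Target read length in bp (default 150).
#' @param genome Named chromosome lengths.
#' @return The extended reads.
#' @export
extend_reads <- function(reads, target_length = 150, genome) {
  if (target_length < 1) abort("`target_length` must be >= 1")
  check_intervals(reads, "reads")
  check_genome(genome)
  lens <- genome[reads$chrom]
  if (any(is.na(lens)) || any(reads$start < 0) || any(reads$end > lens)) {
    abort("read outside chromosome bounds")
  }
  short <- (reads$end - reads$start) < target_length
  plus <- reads$strand == "+"
  reads$end <- ifelse(short & plus,
                      pmin(reads$start + target_length, unname(lens)), reads$end)
  reads$start <- ifelse(short & !plus,
                        pmax(reads$end - target_length, 0), reads$start)
  reads
}

#' Binned read-density coverage track
#'
#' Reads are assigned to bins fractionally: a read contributes
#' `overlap_bp / read_length` to each bin it touches, so every read adds
#' exactly 1 across the genome. With `normalize = TRUE` bin values are
#' scaled to RPKM: `raw * 1e9 / (bin_size * total_mapped)`.
#'
#' @param reads Tibble `chrom`, `start`, `end` (strand ignored here).
#' @param genome Named chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param normalize Scale to RPKM (default TRUE).
#' @param total_mapped Library size used for RPKM; defaults to the number
#'   of reads.
#' @return A `coverage_track` object: per-chromosome bin-value vectors
#'   plus `bin_size`, `normalization` and `total_mapped` metadata.
#' @export
coverage_track <- function(reads, genome, bin_size = 20, normalize = TRUE,
                           total_mapped = nrow(reads)) {
  if (bin_size < 1) abort("`bin_size` must be >= 1")
  check_intervals(reads, "reads")
  check_genome(genome)
  if (normalize && total_mapped == 0) {
    abort("cannot RPKM-normalize with total_mapped = 0")
  }
  values <- lapply(names(genome), function(ch) {
    nb <- ceiling(genome[[ch]] / bin_size)
    v <- numeric(nb)
    ri <- which(reads$chrom == ch)
    if (!length(ri)) return(v)
    s <- reads$start[ri]; e <- reads$end[ri]
    if (any(s < 0) || any(e > genome[[ch]])) abort("read outside chromosome bounds")
    w <- 1 / (e - s)
    first_bin <- floor(s / bin_size)
    last_bin <- floor((e - 1) / bin_size)
    span <- max(last_bin - first_bin) + 1L
    idx_all <- integer(0); add_all <- numeric(0)
    for (j in seq_len(span) - 1L) {
      b <- first_bin + j
      live <- b <= last_bin
      if (!any(live)) break
      ov <- pmin(e[live], (b[live] + 1) * bin_size) - pmax(s[live], b[live] * bin_size)
      idx_all <- c(idx_all, b[live] + 1L)
      add_all <- c(add_all, ov * w[live])
    }
    acc <- rowsum(add_all, idx_all)
    v[as.integer(rownames(acc))] <- acc[, 1]
    v
  })
  names(values) <- names(genome)
  if (normalize) {
    values <- lapply(values, function(v) v * 1e9 / (bin_size * total_mapped))
  }
  structure(
    list(
      bin_size = bin_size, genome = genome, values = values,
      normalization = if (normalize) "RPKM" else "raw_counts",
      total_mapped = total_mapped
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %d chromosome(s), bin %d bp, %s, %s mapped reads\n",
    length(x$values), x$bin_size, x$normalization,
    format(x$total_mapped, big.mark = ",")
  ))
  invisible(x)
}

#' @method as_tibble coverage_track
#' @export
as_tibble.coverage_track <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$values), function(ch) {
    v <- x$values[[ch]]
    tibble(
      chrom = ch,
      start = (seq_along(v) - 1) * x$bin_size,
      end = pmin(seq_along(v) * x$bin_size, x$genome[[ch]]),
      value = v
    )
  }))
}

# per-base signal over [start, end); the value of a base is its bin's value
track_values <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) abort(paste("chromosome", chrom, "not in track"))
  if (start < 0 || end > track$genome[[chrom]]) {
    abort("interval outside coverage domain")
  }
  v[seq(start, end - 1) %/% track$bin_size + 1]
}

# mean of a per-base step signal (constant within bins of width `step`)
# between consecutive `breaks` (absolute bp, may be fractional)
.step_bin_means <- function(values, step, breaks) {
  nb <- length(values)
  csum <- c(0, cumsum(values)) * step
  f <- function(x) {
    k <- pmin(floor(x / step), nb - 1)
    csum[k + 1] + (x - k * step) * values[k + 1]
  }
  ints <- diff(f(breaks))
  ints / diff(breaks)
}

new_meta_profile <- function(tbl, n_regions, n_dropped, mat = NULL) {
  structure(
    tbl,
    n_regions = n_regions, n_dropped = n_dropped, profile_matrix = mat,
    class = c("meta_profile", class(tibble()))
  )
}

# column means and SEM (n-1 denominator; 0 when n == 1) of a region matrix
.profile_mean_sem <- function(mat) {
  n <- nrow(mat)
  list(
    mean = colMeans(mat),
    sem = if (n > 1) apply(mat, 2, sd) / sqrt(n) else numeric(ncol(mat))
  )
}

#' Summit-anchored metaprofile
#'
#' Averages an RPKM track over windows of `+-flank` bp centered on peak
#' summits, binned at `bin` bp; the summit sits at the left edge of the
#' center-right bin. Windows truncated by chromosome ends are dropped and
#' counted in `attr(, "n_dropped")`.
#'
#' @param track A [coverage_track()] in RPKM normalization.
#' @param summits Data frame with `chrom` and `summit` columns (e.g. from
#'   [peak_summits()]).
#' @param flank Half-window in bp (default 10000); must be divisible by `bin`.
#' @param bin Profile bin width in bp (default 200).
#' @return A `meta_profile` tibble: `bin`, `position` (bp of bin start
#'   relative to the summit), `mean`, `sem`, `n`; the per-region matrix is
#'   kept in `attr(, "profile_matrix")`.
#' @export
summit_profile <- function(track, summits, flank = 10000, bin = 200) {
  if (track$normalization != "RPKM") abort("track must be RPKM-normalized")
  if (flank %% bin != 0) abort("`flank` must be divisible by `bin`")
  if (!all(c("chrom", "summit") %in% names(summits))) {
    abort("`summits` needs chrom and summit columns")
  }
  nb <- 2L * as.integer(flank / bin)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(summits))) {
    ch <- summits$chrom[i]; sm <- summits$summit[i]
    clen <- track$genome[[ch]]
    if (is.null(clen)) abort(paste("chromosome", ch, "not in track"))
    a <- sm - flank; b <- sm + flank
    if (a < 0 || b > clen) { dropped <- dropped + 1L; next }
    breaks <- a + (0:nb) * bin
    rows[[length(rows) + 1L]] <-
      .step_bin_means(track$values[[ch]], track$bin_size, breaks)
  }
  if (!length(rows)) abort("no usable summits (all truncated or none given)")
  mat <- do.call(rbind, rows)
  ms <- .profile_mean_sem(mat)
  new_meta_profile(
    tibble(
      bin = seq_len(nb), position = (seq_len(nb) - 1L) * bin - flank,
      mean = ms$mean, sem = ms$sem, n = nrow(mat)
    ),
    n_regions = nrow(mat), n_dropped = dropped, mat = mat
  )
}

# per-gene profile breakpoints and row extraction shared by the metagenes
.gene_profile_rows <- function(track, genes, body_bins, flank, flank_bin,
                               min_body_length) {
  fb <- as.integer(flank / flank_bin)
  rows <- list(); ids <- character(0)
  dropped_end <- 0L; short <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    clen <- track$genome[[g$chrom]]
    if (is.null(clen)) abort(paste("chromosome", g$chrom, "not in track"))
    len <- g$end - g$start
    if (len < min_body_length) { short <- short + 1L; next }
    a <- g$start - flank; b <- g$end + flank
    if (a < 0 || b > clen) { dropped_end <- dropped_end + 1L; next }
    breaks <- c(
      g$start - flank + (0:(fb - 1L)) * flank_bin,
      g$start + (0:body_bins) * (len / body_bins),
      g$end + (1:fb) * flank_bin
    )
    row <- .step_bin_means(track$values[[g$chrom]], track$bin_size, breaks)
    if (g$strand == "-") row <- rev(row)
    rows[[length(rows) + 1L]] <- row
    ids <- c(ids, g$gene_id)
  }
  list(rows = rows, ids = ids, dropped_end = dropped_end, short = short)
}

#' Gene-body-scaled metagene profile
#'
#' Scales every gene body to `body_bins` equal spans with proportional
#' (fractional) signal aggregation and adds fixed-width flanks binned at
#' `flank_bin`; minus-strand genes are reversed so all rows run from TSS
#' to TTS. The profile is the across-gene mean with its standard error.
#'
#' @param track A [coverage_track()] in RPKM normalization.
#' @param genes Gene-model tibble.
#' @param body_bins Number of equal gene-body bins (default 60).
#' @param flank Flank width in bp each side (default 10000).
#' @param flank_bin Flank bin width in bp (default 200).
#' @param min_body_length Genes shorter than this are excluded (and
#'   counted in `attr(, "n_short")`); default 120 bp.
#' @return A `meta_profile` tibble with `bin`, `segment` (upstream / body
#'   / downstream), `position`, `mean`, `sem`, `n`.
#' @export
gene_metagene <- function(track, genes, body_bins = 60, flank = 10000,
                          flank_bin = 200, min_body_length = 120) {
  if (track$normalization != "RPKM") abort("track must be RPKM-normalized")
  if (flank %% flank_bin != 0) abort("`flank` must be divisible by `flank_bin`")
  gp <- .gene_profile_rows(track, genes, body_bins, flank, flank_bin,
                           min_body_length)
  if (!length(gp$rows)) abort("no eligible genes for the metagene")
  mat <- do.call(rbind, gp$rows)
  rownames(mat) <- gp$ids
  fb <- as.integer(flank / flank_bin)
  nb <- fb + body_bins + fb
  ms <- .profile_mean_sem(mat)
  out <- new_meta_profile(
    tibble(
      bin = seq_len(nb),
      segment = rep(c("upstream", "body", "downstream"), c(fb, body_bins, fb)),
      position = c(
        -flank + (seq_len(fb) - 1L) * flank_bin,
        (seq_len(body_bins) - 1L) / body_bins * (body_bins * flank_bin),
        body_bins * flank_bin + (seq_len(fb) - 1L) * flank_bin
      ),
      mean = ms$mean, sem = ms$sem, n = nrow(mat)
    ),
    n_regions = nrow(mat), n_dropped = gp$dropped_end, mat = mat
  )
  attr(out, "n_short") <- gp$short
  out
}

#' Write and read fixed-bin tracks as bedGraph
#'
#' Non-zero bins are written as `chrom start end value`; a header comment
#' records the bin size, normalization and library size so the track
#' round-trips.
#'
#' @param track A [coverage_track()].
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "#epicoloc bin_size=%d normalization=%s total_mapped=%d genome=%s",
    track$bin_size, track$normalization, track$total_mapped,
    paste(sprintf("%s:%d", names(track$genome), track$genome), collapse = ",")
  ), con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf(
      "%s\t%d\t%d\t%s", ch, (nz - 1L) * track$bin_size,
      pmin(nz * track$bin_size, track$genome[[ch]]),
      formatC(v[nz], format = "g", digits = 15)
    ), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- lines[1]
  if (!startsWith(hdr, "#epicoloc")) abort("not an epicoloc bedGraph")
  get <- function(key) stringr::str_match(hdr, paste0(key, "=([^ ]+)"))[, 2]
  bin_size <- as.integer(get("bin_size"))
  gparts <- strsplit(strsplit(get("genome"), ",")[[1]], ":")
  genome <- setNames(
    vapply(gparts, function(p) as.numeric(p[2]), 0),
    vapply(gparts, `[[`, "", 1)
  )
  values <- lapply(genome, function(l) numeric(ceiling(l / bin_size)))
  body <- lines[-1]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    ch <- parts[, 1]; s <- as.numeric(parts[, 2]); val <- as.numeric(parts[, 4])
    for (c2 in unique(ch)) {
      i <- ch == c2
      values[[c2]][s[i] / bin_size + 1] <- val[i]
    }
  }
  structure(
    list(
      bin_size = bin_size, genome = genome, values = values,
      normalization = get("normalization"),
      total_mapped = as.numeric(get("total_mapped"))
    ),
    class = "coverage_track"
  )
}
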