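# independent brute-force oracles and tiny fixture builders

# all-pairs overlap oracle: count/shared-bp/ids without any sweep machinery
brute_overlap <- function(query, subject, min_bp = 1) {
  n <- nrow(query)
  hit <- logical(n)
  shared <- numeric(n)
  for (i in seq_len(n)) {
    best <- 0
    cov <- numeric(0)
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      ov <- min(query$end[i], subject$end[j]) - max(query$start[i], subject$start[j])
      if (ov > best) best <- ov
      if (ov > 0) {
        # per-base union bookkeeping for the shared-bp part
        cov <- union(cov, seq(max(query$start[i], subject$start[j]),
                              min(query$end[i], subject$end[j]) - 1))
      }
    }
    hit[i] <- best >= min_bp
    shared[i] <- length(cov)
  }
  ids <- if ("id" %in% names(query)) query$id else seq_len(nrow(query))
  list(count = sum(hit), shared_bp = sum(shared), ids = ids[hit])
}

# per-base coverage oracle: accumulate 1/len per covered base, sum per bin
perbase_track <- function(reads, genome, bin_size, normalize = TRUE,
                          total_mapped = nrow(reads)) {
  lapply(setNames(names(genome), names(genome)), function(ch) {
    depth <- numeric(genome[[ch]])
    ri <- which(reads$chrom == ch)
    for (i in ri) {
      idx <- seq(reads$start[i] + 1, reads$end[i])
      depth[idx] <- depth[idx] + 1 / (reads$end[i] - reads$start[i])
    }
    nb <- ceiling(genome[[ch]] / bin_size)
    v <- vapply(seq_len(nb), function(b) {
      sum(depth[seq((b - 1) * bin_size + 1, min(b * bin_size, genome[[ch]]))])
    }, 0)
    if (normalize) v * 1e9 / (bin_size * total_mapped) else v
  })
}

# per-base profile oracle: mean of the base-level step signal over
# arbitrary (possibly fractional) bin edges, splitting edge bases
perbase_bin_means <- function(values, step, breaks) {
  vapply(seq_len(length(breaks) - 1), function(j) {
    a <- breaks[j]; b <- breaks[j + 1]
    tot <- 0
    for (p in floor(a):(ceiling(b) - 1)) {
      ov <- min(p + 1, b) - max(p, a)
      if (ov > 0) tot <- tot + ov * values[p %/% step + 1]
    }
    tot / (b - a)
  }, 0)
}

# per-base metagene row oracle for one gene (TSS->TTS orientation)
perbase_gene_row <- function(values, step, g, body_bins, flank, flank_bin) {
  fb <- flank / flank_bin
  len <- g$end - g$start
  breaks <- c(
    g$start - flank + (0:(fb - 1)) * flank_bin,
    g$start + (0:body_bins) * (len / body_bins),
    g$end + (1:fb) * flank_bin
  )
  row <- perbase_bin_means(values, step, breaks)
  if (g$strand == "-") rev(row) else row
}

# exhaustive rank-sum U oracle (pair counting with half-credit ties)
brute_rank_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# hypergeometric upper-tail oracle by direct enumeration
brute_hyper_tail <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

random_intervals <- function(n, chroms, chrom_len, max_len = 200) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_len - len))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    id = paste0("iv", seq_len(n))
  )
}

random_reads <- function(n, genome, len = 50) {
  ch <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n) * (genome[ch] - len))
  tibble::tibble(chrom = ch, start = start, end = start + len,
                 strand = sample(c("+", "-"), n, replace = TRUE))
}

tiny_design <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2, chrom_length = 1e6, n_genes = 80,
         n_rloops = 80, n_hmc = 120, reads_per_condition = 2e4),
    list(...)
  )
  do.call(synth_design, args)
}
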