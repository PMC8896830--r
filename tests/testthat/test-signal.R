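test_that("reads extend 3' with a fixed 5' end and clip at bounds", {
  genome <- c(chr1 = 2000, chr2 = 1100)
  reads <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 1964, 990), end = c(1036, 2000, 1026),
    strand = c("+", "-", "+")
  )
  out <- extend_reads(reads, 150, genome)
  expect_equal(out$start, c(1000, 1850, 990))
  expect_equal(out$end, c(1150, 2000, 1100))
  long <- tibble::tibble(chrom = "chr1", start = 0, end = 300, strand = "+")
  expect_identical(extend_reads(long, 150, genome), long)
  bad <- tibble::tibble(chrom = "chr1", start = 1990, end = 2010, strand = "+")
  expect_error(extend_reads(bad, 150, genome), "bounds")
})

test_that("coverage bins use fractional read assignment and RPKM scaling", {
  genome <- c(chr1 = 1000)
  one <- tibble::tibble(chrom = "chr1", start = 20, end = 170, strand = "+")
  tr <- coverage_track(one, genome, bin_size = 200, total_mapped = 1e6)
  expect_equal(tr$values$chr1[1], 5)         # 1 read / (0.2 kb * 1 M)

  split <- tibble::tibble(chrom = "chr1", start = 50, end = 200, strand = "+")
  raw <- coverage_track(split, genome, bin_size = 100, normalize = FALSE)
  expect_equal(raw$values$chr1[1:2], c(1 / 3, 2 / 3))

  expect_error(coverage_track(one[0, ], genome, 20, normalize = TRUE),
               "total_mapped")
})

test_that("random coverage tracks equal the per-base oracle and conserve reads", {
  set.seed(12)
  genome <- c(chr1 = 3000, chr2 = 2000)
  for (rep in 1:10) {
    reads <- random_reads(40, genome, len = sample(20:80, 1))
    bs <- sample(c(7, 20, 50), 1)
    got <- coverage_track(reads, genome, bs, normalize = FALSE)
    want <- perbase_track(reads, genome, bs, normalize = FALSE)
    expect_equal(got$values$chr1, want$chr1, tolerance = 1e-12)
    expect_equal(got$values$chr2, want$chr2, tolerance = 1e-12)
    expect_equal(sum(unlist(got$values)), nrow(reads), tolerance = 1e-9)
  }
})

test_that("RPKM is invariant when reads and library size double together", {
  genome <- c(chr1 = 5000)
  set.seed(2)
  reads <- random_reads(100, genome)
  t1 <- coverage_track(reads, genome, 50)
  t2 <- coverage_track(dplyr::bind_rows(reads, reads), genome, 50)
  expect_equal(t1$values$chr1, t2$values$chr1, tolerance = 1e-12)
})

test_that("summit profiles center correctly and match the per-base oracle", {
  genome <- c(chr1 = 40000)
  flat <- coverage_track(
    tibble::tibble(chrom = "chr1", start = seq(0, 39900, 100),
                   end = seq(100, 40000, 100), strand = "+"),
    genome, 100
  )
  smt <- tibble::tibble(chrom = "chr1", summit = 20000)
  prof <- summit_profile(flat, smt, flank = 2000, bin = 200)
  expect_equal(length(prof$mean), 20)
  expect_equal(diff(range(prof$mean)), 0)        # flat track -> flat profile
  expect_equal(prof$sem, rep(0, 20))

  set.seed(9)
  reads <- random_reads(400, genome)
  tr <- coverage_track(reads, genome, 20)
  smts <- tibble::tibble(chrom = "chr1",
                         summit = sample(3000:37000, 8))
  got <- summit_profile(tr, smts, flank = 2000, bin = 200)
  mat <- attr(got, "profile_matrix")
  for (i in seq_len(nrow(smts))) {
    breaks <- smts$summit[i] - 2000 + (0:20) * 200
    expect_equal(mat[i, ], perbase_bin_means(tr$values$chr1, 20, breaks),
                 tolerance = 1e-9)
  }

  # a spike of reads at a summit peaks in the center-right bin
  spike <- coverage_track(
    tibble::tibble(chrom = "chr1", start = 20000, end = 20150, strand = "+")[
      rep(1, 50), ], genome, 20)
  sp <- summit_profile(spike, smt, flank = 2000, bin = 200)
  expect_equal(which.max(sp$mean), 11)           # bin starting at the summit

  edge <- tibble::tibble(chrom = "chr1", summit = c(500, 20000))
  pe <- summit_profile(tr, edge, flank = 2000, bin = 200)
  expect_equal(attr(pe, "n_dropped"), 1L)
  expect_error(summit_profile(tr, edge[1, , drop = FALSE], flank = 2000,
                              bin = 200), "usable")
})

test_that("metagenes scale bodies, respect strand and conserve signal", {
  genome <- c(chr1 = 60000)
  set.seed(14)
  reads <- random_reads(600, genome)
  tr <- coverage_track(reads, genome, 20)

  genes <- tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    start = c(5000, 21000, 41007), end = c(11000, 30013, 52345),
    strand = c("+", "-", "+")
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  mg <- gene_metagene(tr, genes, body_bins = 60, flank = 2000, flank_bin = 200)
  expect_equal(nrow(mg), 10 + 60 + 10)
  mat <- attr(mg, "profile_matrix")
  for (i in seq_len(nrow(genes))) {
    want <- perbase_gene_row(tr$values$chr1, 20, genes[i, ], 60, 2000, 200)
    expect_equal(mat[i, ], want, tolerance = 1e-9)
  }
  # body-bin means times bin widths conserve the per-base body signal
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    body <- mat[i, 11:70]
    if (g$strand == "-") body <- rev(body)
    per_base <- sum(tr$values$chr1[(g$start:(g$end - 1)) %/% 20 + 1])
    expect_equal(sum(body * len / 60), per_base, tolerance = 1e-6)
  }

  # uniform signal across a gene gives identical body bins
  flat <- coverage_track(
    tibble::tibble(chrom = "chr1", start = seq(0, 59900, 100),
                   end = seq(100, 60000, 100), strand = "+"), genome, 100)
  mflat <- gene_metagene(flat, genes[1, ], 60, 2000, 200)
  expect_equal(diff(range(mflat$mean[mflat$segment == "body"])), 0)

  # strand symmetry: flipping strand twice reproduces the original row
  g2 <- genes; g2$strand <- c("-", "+", "-")
  g3 <- g2; g3$strand <- genes$strand
  expect_equal(attr(gene_metagene(tr, g3, 60, 2000, 200), "profile_matrix"),
               attr(gene_metagene(tr, genes, 60, 2000, 200), "profile_matrix"))
  # mirror case: a minus-strand gene whose coverage mirrors a plus gene
  gsym <- tibble::tibble(gene_id = "m", chrom = "chr1", start = 5000,
                         end = 11000, strand = "-", tss = 11000, tts = 5000)
  row_minus <- attr(gene_metagene(tr, gsym, 60, 2000, 200), "profile_matrix")[1, ]
  row_plus <- attr(gene_metagene(tr, genes[1, ], 60, 2000, 200),
                   "profile_matrix")[1, ]
  expect_equal(row_minus, rev(row_plus), tolerance = 1e-12)

  short <- tibble::tibble(gene_id = "s", chrom = "chr1", start = 5000,
                          end = 5080, strand = "+", tss = 5000, tts = 5080)
  expect_error(gene_metagene(tr, short, 60, 2000, 200), "eligible")
})

test_that("tracks round-trip through bedGraph", {
  genome <- c(chr1 = 3000, chr2 = 1000)
  set.seed(4)
  tr <- coverage_track(random_reads(60, genome), genome, 25)
  d <- withr::local_tempdir()
  f <- file.path(d, "track.bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(back$bin_size, tr$bin_size)
  expect_equal(back$normalization, tr$normalization)
  expect_equal(back$total_mapped, tr$total_mapped)
  expect_equal(back$values$chr1, tr$values$chr1, tolerance = 1e-12)
  expect_equal(back$values$chr2, tr$values$chr2, tolerance = 1e-12)
})
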