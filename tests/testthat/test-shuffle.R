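test_that("shuffling preserves length multisets and segment containment", {
  set.seed(7)
  uni <- shuffle_universe(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 5000, 100), end = c(2000, 9000, 4100)
  ))
  src <- tibble::tibble(chrom = "chr1", start = c(0, 0, 0),
                        end = c(500, 120, 1200), id = c("a", "b", "c"))
  for (i in 1:200) {
    out <- shuffle_intervals(src, uni)
    expect_setequal(out$end - out$start, c(500, 120, 1200))
    inside <- vapply(seq_len(nrow(out)), function(j) {
      any(uni$chrom == out$chrom[j] & uni$start <= out$start[j] &
            uni$end >= out$end[j])
    }, TRUE)
    expect_true(all(inside))
  }
})

test_that("a length equal to the only segment has a forced placement", {
  uni <- shuffle_universe(tibble::tibble(chrom = "chr1", start = 0, end = 1000))
  src <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  out <- shuffle_intervals(src, uni, seed = 1)
  expect_equal(c(out$start, out$end), c(0, 1000))
  too_long <- tibble::tibble(chrom = "chr1", start = 0, end = 1500)
  expect_error(shuffle_intervals(too_long, uni, seed = 1), "1500")
})

test_that("segment choice is proportional to valid starts and seed-stable", {
  # segments with 1000 and 3000 valid starts for a 100 bp interval
  uni <- shuffle_universe(tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(0, 0), end = c(1099, 3099)
  ))
  src <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  n <- 1e4
  placed <- withr::with_seed(99, {
    vapply(seq_len(n), function(i) shuffle_intervals(src, uni)$chrom, "")
  })
  p <- 3099 - 100 + 1
  frac2 <- mean(placed == "chr2")
  expect_lt(abs(frac2 - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  a <- shuffle_intervals(src, uni, seed = 123)
  b <- shuffle_intervals(src, uni, seed = 123)
  expect_identical(a, b)
})

test_that("permutation test is reproducible and uses the add-one rule", {
  uni <- shuffle_universe(tibble::tibble(chrom = "chr1", start = 0, end = 1e7))
  set.seed(21)
  a <- random_intervals(20, "chr1", 1e6, max_len = 100)
  pt <- permutation_overlap_test(a, a, uni, n_shuffles = 99, seed = 5)
  expect_equal(pt$observed, 20L)
  expect_equal(pt$p_value, (1 + sum(pt$null >= 20)) / 100)
  expect_equal(max(pt$null) < 20, pt$p_value == 1 / 100)
  expect_length(pt$null, 99)
  expect_gt(pt$p_value, 0)

  pt2 <- permutation_overlap_test(a, a, uni, n_shuffles = 99, seed = 5)
  expect_identical(pt$null, pt2$null)
  expect_identical(glance(pt), glance(pt2))

  expect_error(permutation_overlap_test(a[0, ], a, uni, 10, seed = 1), "non-empty")
  expect_error(permutation_overlap_test(a, a, uni, n_shuffles = 0, seed = 1),
               "n_shuffles")
})

test_that("null mean matches the analytic uniform-placement expectation", {
  L <- 5e4; la <- 200; lb <- 500; n_a <- 15; n_b <- 10
  uni <- shuffle_universe(tibble::tibble(chrom = "chr1", start = 0, end = L))
  mk <- function(n, l) tibble::tibble(chrom = "chr1",
                                      start = seq(0, by = l + 10, length.out = n),
                                      end = seq(0, by = l + 10, length.out = n) + l)
  # exact P(one B overlaps one A) for uniform integer starts, with edges
  sa <- 0:(L - la)
  n_pairs <- sum(pmin(sa + la - 1, L - lb) - pmax(sa - lb + 1, 0) + 1)
  p1 <- n_pairs / ((L - la + 1) * (L - lb + 1))
  expected <- n_a * (1 - (1 - p1)^n_b)
  pt <- permutation_overlap_test(mk(n_a, la), mk(n_b, lb), uni,
                                 n_shuffles = 600, seed = 17)
  se <- sd(pt$null) / sqrt(length(pt$null))
  expect_lt(abs(mean(pt$null) - expected), 3 * se + 1e-9)
})

test_that("gene mark classification matches a per-gene brute-force check", {
  genome <- c(chr1 = 1e5)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:4), chrom = "chr1",
    start = c(0, 20000, 40000, 60000), end = c(10000, 30000, 50000, 70000),
    strand = "+", tss = c(0, 20000, 40000, 60000),
    tts = c(10000, 30000, 50000, 70000)
  )
  attr(genes, "genome") <- genome
  w <- gene_windows(genes, 0, 0, genome)
  hmc <- tibble::tibble(chrom = "chr1", start = c(1000, 21000, 41000),
                        end = c(1300, 21300, 41300), id = paste0("h", 1:3))
  rlp <- tibble::tibble(chrom = "chr1", start = c(900, 25000, 41100),
                        end = c(1400, 25800, 41200), id = paste0("r", 1:3))
  ha <- assign_to_genes(hmc, w); ra <- assign_to_genes(rlp, w)
  marks <- classify_gene_marks(genes, ha, ra, hmc, rlp, w)
  # g1: overlapping pair; g2: co-assigned but not overlapping; g3: overlapping
  expect_equal(marks$has_both, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(glance(marks)$pct_both, 50)
  co_only <- classify_gene_marks(genes, ha, ra, require_mutual_overlap = FALSE)
  expect_equal(co_only$has_both, c(TRUE, TRUE, TRUE, FALSE))

  none <- classify_gene_marks(genes, ha[0, ], ra[0, ],
                              require_mutual_overlap = FALSE)
  expect_equal(glance(none)$pct_neither, 100)
  stray <- tibble::tibble(gene_id = "nope", peak_id = "h1")
  expect_error(classify_gene_marks(genes, stray, ra, hmc, rlp, w), "outside")
})

test_that("randomized classifications agree with direct per-gene re-checks", {
  set.seed(31)
  genome <- c(chr1 = 2e5)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:20), chrom = "chr1",
    start = (0:19) * 10000, end = (0:19) * 10000 + 8000,
    strand = sample(c("+", "-"), 20, TRUE)
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  attr(genes, "genome") <- genome
  w <- gene_windows(genes, 500, 500, genome)
  for (rep in 1:10) {
    hmc <- random_intervals(30, "chr1", 2e5 - 300, max_len = 300)
    rlp <- random_intervals(25, "chr1", 2e5 - 800, max_len = 800)
    rlp$id <- paste0("r", seq_len(nrow(rlp)))
    ha <- assign_to_genes(hmc, w); ra <- assign_to_genes(rlp, w)
    marks <- classify_gene_marks(genes, ha, ra, hmc, rlp, w)
    for (i in seq_len(nrow(genes))) {
      wi <- w[i, ]
      clip <- function(p) {
        p$start <- pmax(p$start, wi$start); p$end <- pmin(p$end, wi$end)
        p[p$start < p$end, ]
      }
      hp <- clip(hmc[brute_overlap(hmc, wi)$ids |>
                       (\(x) hmc$id %in% x)(), ])
      rp <- clip(rlp[rlp$id %in% brute_overlap(rlp, wi)$ids, ])
      expect_equal(marks$has_5hmc[i], nrow(hp) > 0)
      expect_equal(marks$has_rloop[i], nrow(rp) > 0)
      both_want <- nrow(hp) > 0 && nrow(rp) > 0 &&
        brute_overlap(hp, rp)$count > 0
      expect_equal(marks$has_both[i], both_want)
    }
  }
})

test_that("binned-signal correlation matches the product-moment formula", {
  genome <- c(chr1 = 6e4)
  genes <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "chr1", start = c(0, 30000),
    end = c(12000, 42000), strand = c("+", "-"),
    tss = c(0, 42000), tts = c(12000, 30000)
  )
  set.seed(8)
  ra <- random_reads(2000, genome)
  rb <- random_reads(2000, genome)
  ta <- coverage_track(ra, genome, 20)
  tb <- coverage_track(rb, genome, 20)
  got <- binned_signal_correlation(ta, tb, genes)
  va <- vb <- numeric(0)
  for (i in 1:2) {
    g <- genes[i, ]
    breaks <- g$start + (0:60) * ((g$end - g$start) / 60)
    xa <- perbase_bin_means(ta$values$chr1, 20, breaks)
    xb <- perbase_bin_means(tb$values$chr1, 20, breaks)
    if (g$strand == "-") { xa <- rev(xa); xb <- rev(xb) }
    va <- c(va, xa); vb <- c(vb, xb)
  }
  r_oracle <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(got$pearson_r, r_oracle, tolerance = 1e-9)
  expect_equal(got$n_bins_used, 120)

  expect_equal(binned_signal_correlation(ta, ta, genes)$pearson_r, 1)
  flat <- ta
  flat$values$chr1 <- rep(1, length(flat$values$chr1))
  expect_error(binned_signal_correlation(ta, flat, genes), "constant")
})
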