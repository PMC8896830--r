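mk_genes <- function(df, genome) {
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tts <- ifelse(df$strand == "+", df$end, df$start)
  attr(df, "genome") <- genome
  df
}

test_that("downstream windows truncate at neighbors and apply the floor", {
  genome <- c(chr1 = 1e6)
  g <- mk_genes(tibble::tibble(
    gene_id = c("iso", "up", "nb", "tight", "tightnb", "minus", "mnb"),
    chrom = "chr1",
    start = c(10000, 40000, 44000, 80000, 82200, 200000, 150000),
    end = c(12000, 42000, 46000, 82000, 84000, 210000, 160000),
    strand = c("+", "+", "+", "+", "+", "-", "-")
  ), genome)
  w <- downstream_windows(g, window = 5000, min_window = 500, genome = genome)
  expect_equal(unlist(w[w$gene_id == "iso", c("start", "end")], use.names = FALSE),
               c(12000, 17000))
  expect_equal(unlist(w[w$gene_id == "up", c("start", "end")], use.names = FALSE),
               c(42000, 44000))                    # truncated at neighbor start
  expect_false("tight" %in% w$gene_id)             # 200 bp gap < 500 bp floor
  # minus-strand gene: window extends left from its start (= TTS),
  # truncated at the left neighbor's end
  expect_equal(unlist(w[w$gene_id == "minus", c("start", "end")],
                      use.names = FALSE), c(195000, 200000))
})

test_that("readthrough indices are downstream/body density ratios with a floor", {
  genome <- c(chr1 = 1e5)
  g <- mk_genes(tibble::tibble(
    gene_id = c("hot", "silent", "noRT"), chrom = "chr1",
    start = c(10000, 40000, 70000), end = c(20000, 50000, 80000), strand = "+"
  ), genome)
  w <- downstream_windows(g, genome = genome)
  len <- 50
  body_hot <- tibble::tibble(chrom = "chr1",
                             start = seq(10000, 19000, length.out = 200),
                             end = seq(10000, 19000, length.out = 200) + len,
                             strand = "+")
  down_hot <- tibble::tibble(chrom = "chr1",
                             start = seq(20000, 24000, length.out = 50),
                             end = seq(20000, 24000, length.out = 50) + len,
                             strand = "+")
  body_nort <- tibble::tibble(chrom = "chr1",
                              start = seq(70000, 79000, length.out = 100),
                              end = seq(70000, 79000, length.out = 100) + len,
                              strand = "+")
  reads <- dplyr::bind_rows(body_hot, down_hot, body_nort)
  rt <- readthrough_table(reads, g, w, min_body_rpkm = 1)
  hot <- rt[rt$gene_id == "hot", ]
  # 200 body reads over 10 kb vs 50 downstream reads over 5 kb -> ratio 0.5
  expect_equal(hot$index, 0.5, tolerance = 0.02)
  expect_equal(rt$index[rt$gene_id == "noRT"], 0)
  expect_false("silent" %in% rt$gene_id)           # below the body floor
  expect_equal(attr(rt, "n_excluded"), 1L)
})

test_that("condition comparison flags shifted genes and matches the U oracle", {
  mk <- function(idx, cond) tibble::tibble(
    gene_id = paste0("g", seq_along(idx)), body_rpkm = 10,
    downstream_rpkm = idx * 10, index = idx, condition = cond
  )
  set.seed(6)
  base <- runif(40, 0, 0.2)
  same <- compare_readthrough(mk(base, "A"), mk(base, "B"))
  expect_length(same$enriched, 0)
  expect_gt(same$p_value, 0.5)

  shifted <- base
  shifted[1:10] <- pmax(base[1:10], 0.1) * 5
  cmp <- compare_readthrough(mk(base, "A"), mk(shifted, "B"))
  expect_setequal(cmp$enriched, paste0("g", 1:10))
  u_oracle <- brute_rank_u(shifted, base)
  expect_equal(cmp$mw_u, u_oracle)

  expect_error(compare_readthrough(mk(base, "A")[1, ], mk(base, "B")[2, ]),
               "shared")
})

test_that("small-vector U statistics equal the exhaustive rank-sum", {
  set.seed(19)
  for (i in 1:20) {
    x <- round(runif(sample(3:12, 1), 0, 1), 2)
    y <- round(runif(sample(3:12, 1), 0, 1), 2)
    cmpA <- tibble::tibble(gene_id = paste0("g", seq_along(y)), index = y)
    cmpB <- tibble::tibble(gene_id = paste0("g", seq_along(x)), index = x)
    n <- min(length(x), length(y))
    got <- compare_readthrough(cmpA[1:n, ], cmpB[1:n, ])
    expect_equal(got$mw_u, brute_rank_u(x[1:n], y[1:n]))
  }
})

test_that("readthrough metagenes are flat on uniform tracks and see planted signal", {
  genome <- c(chr1 = 1e5)
  flat <- coverage_track(
    tibble::tibble(chrom = "chr1", start = seq(0, 99900, 100),
                   end = seq(100, 1e5, 100), strand = "+"), genome, 100)
  g <- mk_genes(tibble::tibble(
    gene_id = c("a", "b"), chrom = "chr1", start = c(20000, 60000),
    end = c(26000, 64000), strand = c("+", "-")
  ), genome)
  mg <- readthrough_metagene(flat, g)
  expect_equal(nrow(mg), 10 + 20 + 10)
  expect_equal(diff(range(mg$mean)), 0)
  single <- readthrough_metagene(flat, g[1, ])
  expect_equal(single$sem, rep(0, 40))

  # per-base oracle agreement on a rough track
  set.seed(23)
  tr <- coverage_track(random_reads(800, genome), genome, 20)
  mg2 <- readthrough_metagene(tr, g)
  mat <- attr(mg2, "profile_matrix")
  for (i in 1:2) {
    want <- perbase_gene_row(tr$values$chr1, 20, g[i, ], 20, 1000, 100)
    expect_equal(mat[i, ], want, tolerance = 1e-9)
  }

  # planted downstream reads elevate post-TTS bins for the planted gene
  ds <- tibble::tibble(chrom = "chr1",
                       start = seq(26000, 26900, length.out = 120),
                       end = seq(26000, 26900, length.out = 120) + 50,
                       strand = "+")
  tr2 <- coverage_track(dplyr::bind_rows(random_reads(800, genome), ds),
                        genome, 20)
  mg3 <- readthrough_metagene(tr2, g)
  mat3 <- attr(mg3, "profile_matrix")
  post_tts_a <- mean(mat3[1, 31:40])
  post_tts_b <- mean(mat3[2, 31:40])
  expect_gt(post_tts_a, 3 * max(post_tts_b, 1e-9))
})
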