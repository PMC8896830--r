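#' Synthetic study design
#'
#' Collects every parameter of the synthetic-data generator: a small
#' genome of non-overlapping stranded genes with log-normal lengths and
#' TPMs, two mark sets (short, peak-like 5hmC regions and broader R-loop
#' regions) placed in active genes with a controlled co-occurrence rate
#' and a bias toward the TTS, strand-aware short reads from background,
#' gene-body and peak components, and a second condition with planted
#' downstream-of-TTS readthrough in a chosen gene subset.
#'
#' @param seed Master seed; every generator derives its stream from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 5 Mb).
#' @param n_genes Number of genes (default 400).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (default median 5 kb).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters.
#' @param n_rloops,rloop_median,rloop_shape R-loop count and
#'   gamma-distributed length (median 800 bp, broader regions).
#' @param n_hmc,hmc_median,hmc_shape 5hmC peak count and length (median
#'   300 bp, well-defined peaks).
#' @param co_occurrence_rho Probability in `[0,1]` that a 5hmC peak is
#'   co-placed inside a random R-loop region (default 0.5).
#' @param tts_bias Beta-shape bias of mark placement toward the TTS
#'   (0 = uniform over the gene body; default 2).
#' @param active_percentile TPM percentile defining active genes
#'   (default 25).
#' @param reads_per_condition,read_length Read model (default 2e5 reads
#'   of 36 bp per library).
#' @param background_fraction,peak_read_fraction Mixture weights of the
#'   uniform background and the peak-enrichment read components; the
#'   remainder is TPM-proportional gene-body signal.
#' @param readthrough_fraction Fraction of active genes planted with
#'   readthrough in the second condition (default 0.1).
#' @param readthrough_ratio Target downstream/body density ratio over the
#'   readthrough window (default 0.3).
#' @param readthrough_window Window over which the planted ratio is
#'   calibrated, matching the analysis default (5000 bp).
#' @param decay_length Mean of the truncated-exponential decay of planted
#'   downstream read positions (default 1000 bp).
#' @return A `synth_design` list.
#' @export
synth_design <- function(seed = 1L,
                         n_chroms = 2L, chrom_length = 5e6, n_genes = 400L,
                         gene_length_meanlog = log(5000), gene_length_sdlog = 0.5,
                         tpm_meanlog = 2, tpm_sdlog = 1.2,
                         n_rloops = 400L, rloop_median = 800, rloop_shape = 4,
                         n_hmc = 600L, hmc_median = 300, hmc_shape = 4,
                         co_occurrence_rho = 0.5, tts_bias = 2,
                         active_percentile = 25,
                         reads_per_condition = 2e5, read_length = 36L,
                         background_fraction = 0.05, peak_read_fraction = 0.25,
                         readthrough_fraction = 0.1, readthrough_ratio = 0.3,
                         readthrough_window = 5000, decay_length = 1000) {
  d <- as.list(environment())
  if (d$co_occurrence_rho < 0 || d$co_occurrence_rho > 1) {
    abort("`co_occurrence_rho` must be in [0, 1]")
  }
  if (d$tts_bias < 0) abort("`tts_bias` must be >= 0")
  counts <- c(d$n_chroms, d$chrom_length, d$n_genes, d$n_rloops, d$n_hmc,
              d$reads_per_condition, d$read_length)
  if (any(counts <= 0)) abort("all design counts must be positive")
  structure(d, class = "synth_design")
}

.design_genome <- function(design) {
  setNames(rep(design$chrom_length, design$n_chroms),
           paste0("chr", seq_len(design$n_chroms)))
}

#' Generate the synthetic annotation and expression table
#'
#' Places `n_genes` non-overlapping stranded genes with log-normal
#' lengths and draws log-normal TPMs. Deterministic under the design
#' seed.
#'
#' @param design A [synth_design()].
#' @param max_tries Placement retries per gene before a capacity error.
#' @return List with `genes` (gene-model tibble with the genome attached
#'   as an attribute) and `tpm` (tibble `gene_id`, `tpm`).
#' @export
make_annotation <- function(design, max_tries = 200L) {
  genome <- .design_genome(design)
  withr::with_seed(child_seed(design$seed, "annotation"), {
    lens <- pmax(200, round(rlnorm(design$n_genes, design$gene_length_meanlog,
                                   design$gene_length_sdlog)))
    chrom <- character(design$n_genes)
    start <- numeric(design$n_genes)
    placed <- lapply(names(genome), function(ch) list(s = numeric(0), e = numeric(0)))
    names(placed) <- names(genome)
    for (i in seq_len(design$n_genes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(names(genome), 1)
        s <- floor(runif(1) * (genome[[ch]] - lens[i]))
        e <- s + lens[i]
        p <- placed[[ch]]
        if (!any(s < p$e & e > p$s)) {
          placed[[ch]]$s <- c(p$s, s); placed[[ch]]$e <- c(p$e, e)
          chrom[i] <- ch; start[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("cannot place genes without overlap: genome too crowded")
    }
    genes <- tibble(
      gene_id = sprintf("g%04d", seq_len(design$n_genes)),
      chrom = chrom, start = start, end = start + lens,
      strand = sample(c("+", "-"), design$n_genes, replace = TRUE)
    ) |>
      dplyr::mutate(
        tss = ifelse(.data$strand == "+", .data$start, .data$end),
        tts = ifelse(.data$strand == "+", .data$end, .data$start)
      ) |>
      dplyr::arrange(.data$chrom, .data$start)
    tpm <- tibble(
      gene_id = genes$gene_id,
      tpm = rlnorm(design$n_genes, design$tpm_meanlog, design$tpm_sdlog)
    )
    attr(genes, "genome") <- genome
    list(genes = genes, tpm = tpm)
  })
}

# relative position within the gene body, biased toward the TTS;
# tts_bias = 0 gives a uniform position
.tts_biased_pos <- function(n, tts_bias) rbeta(n, 1 + tts_bias, 1)

#' Plant co-occurring mark sets in active genes
#'
#' R-loop regions are placed in active genes at a TTS-biased position;
#' each 5hmC peak is co-placed inside a randomly chosen R-loop region
#' with probability `co_occurrence_rho`, otherwise placed independently
#' by the same rule. The truth tables record per-gene mark status and
#' per-peak co-placement.
#'
#' @param design A [synth_design()].
#' @param genes,tpm From [make_annotation()].
#' @return List: `hmc`, `rloop` (interval tibbles with ids),
#'   `truth_genes` (`gene_id`, `has_rloop`, `has_5hmc`, `has_both`),
#'   `truth_peaks` (`id`, `gene_id`, `co_placed`, `rloop_id`), and the
#'   `tpm_threshold` defining active genes.
#' @export
plant_marks <- function(design, genes, tpm) {
  thr <- unname(quantile(tpm$tpm[match(genes$gene_id, tpm$gene_id)],
                         design$active_percentile / 100, type = 7))
  active <- genes[tpm$tpm[match(genes$gene_id, tpm$gene_id)] > thr, ]
  if (!nrow(active)) abort("no active genes to plant marks in")
  gamma_len <- function(n, median, shape) {
    pmax(50, round(rgamma(n, shape, scale = median / stats::qgamma(0.5, shape))))
  }
  withr::with_seed(child_seed(design$seed, "marks"), {
    place_in_gene <- function(gi, len) {
      g <- active[gi, ]
      glen <- g$end - g$start
      len <- pmin(len, glen)
      rel <- .tts_biased_pos(length(gi), design$tts_bias)
      rel <- ifelse(g$strand == "+", rel, 1 - rel)
      center <- g$start + rel * glen
      s <- pmin(pmax(round(center - len / 2), g$start), g$end - len)
      tibble(chrom = g$chrom, start = s, end = s + len, gene_id = g$gene_id)
    }
    # longer genes harbor proportionally more regions, so that with
    # tts_bias = 0 independent placement is uniform over gene-body bp
    glen_w <- active$end - active$start
    rl_gi <- sample.int(nrow(active), design$n_rloops, replace = TRUE,
                        prob = glen_w)
    rl <- place_in_gene(rl_gi, gamma_len(design$n_rloops, design$rloop_median,
                                         design$rloop_shape))
    rl$id <- sprintf("rloop%04d", seq_len(design$n_rloops))

    co <- runif(design$n_hmc) < design$co_occurrence_rho
    hlen <- gamma_len(design$n_hmc, design$hmc_median, design$hmc_shape)
    hm <- vector("list", design$n_hmc)
    host_rl <- rep(NA_character_, design$n_hmc)
    host_gene <- character(design$n_hmc)
    for (i in seq_len(design$n_hmc)) {
      if (co[i]) {
        j <- sample.int(nrow(rl), 1)
        rlen <- rl$end[j] - rl$start[j]
        s <- if (hlen[i] <= rlen) {
          rl$start[j] + floor(runif(1) * (rlen - hlen[i] + 1))
        } else {
          # peak longer than region: center it over the region
          max(0, round(rl$start[j] - (hlen[i] - rlen) / 2))
        }
        host_rl[i] <- rl$id[j]
        host_gene[i] <- rl$gene_id[j]
        hm[[i]] <- tibble(chrom = rl$chrom[j], start = s, end = s + hlen[i])
      } else {
        gi <- sample.int(nrow(active), 1, prob = glen_w)
        p <- place_in_gene(gi, hlen[i])
        host_gene[i] <- p$gene_id
        hm[[i]] <- p[c("chrom", "start", "end")]
      }
    }
    hmc <- dplyr::bind_rows(hm)
    hmc$id <- sprintf("hmc%04d", seq_len(design$n_hmc))

    co_genes <- unique(host_gene[co])
    truth_genes <- tibble(
      gene_id = genes$gene_id,
      has_rloop = genes$gene_id %in% rl$gene_id,
      has_5hmc = genes$gene_id %in% host_gene,
      has_both = genes$gene_id %in% co_genes
    )
    list(
      hmc = hmc[c("chrom", "start", "end", "id")],
      rloop = rl[c("chrom", "start", "end", "id", "gene_id")],
      truth_genes = truth_genes,
      truth_peaks = tibble(id = hmc$id, gene_id = host_gene,
                           co_placed = co, rloop_id = host_rl),
      tpm_threshold = thr
    )
  })
}

#' Sample strand-aware reads for one condition
#'
#' Read positions come from a mixture of uniform genome-wide background,
#' TPM-proportional gene-body signal and (when peaks are supplied)
#' peak-concentrated enrichment. Genes in `planted_genes` additionally
#' emit downstream-of-TTS reads calibrated so the downstream/body density
#' ratio over the design's readthrough window equals
#' `readthrough_ratio`, with truncated-exponential positional decay.
#'
#' @param design A [synth_design()].
#' @param genes,tpm From [make_annotation()].
#' @param peaks Optional interval tibble of enrichment regions.
#' @param condition Condition label (also salts the random stream).
#' @param planted_genes Gene ids planted with readthrough (default none).
#' @return Read tibble `chrom`, `start`, `end`, `strand`.
#' @export
sample_reads <- function(design, genes, tpm, peaks = NULL, condition = "A",
                         planted_genes = character(0)) {
  genome <- .design_genome(design)
  rl <- design$read_length
  total <- design$reads_per_condition
  if (total < 1) abort("zero total read budget")
  withr::with_seed(child_seed(design$seed, paste0("reads-", condition)), {
    n_bg <- round(total * design$background_fraction)
    n_pk <- if (is.null(peaks) || !nrow(peaks)) 0L else {
      round(total * design$peak_read_fraction)
    }
    n_body <- total - n_bg - n_pk

    parts <- list()
    if (n_bg > 0) {
      ch <- sample(names(genome), n_bg, replace = TRUE,
                   prob = unname(genome) / sum(genome))
      s <- floor(runif(n_bg) * (genome[ch] - rl))
      parts$bg <- tibble(chrom = ch, start = s, end = s + rl,
                         strand = sample(c("+", "-"), n_bg, replace = TRUE))
    }
    w <- tpm$tpm[match(genes$gene_id, tpm$gene_id)]
    w[is.na(w)] <- 0
    if (n_body > 0) {
      gi <- sample.int(nrow(genes), n_body, replace = TRUE, prob = w)
      glen <- genes$end[gi] - genes$start[gi]
      s <- genes$start[gi] + floor(runif(n_body) * pmax(glen - rl, 1))
      parts$body <- tibble(chrom = genes$chrom[gi], start = s,
                           end = pmin(s + rl, genome[genes$chrom[gi]]),
                           strand = genes$strand[gi])
    }
    if (n_pk > 0) {
      plen <- peaks$end - peaks$start
      pi <- sample.int(nrow(peaks), n_pk, replace = TRUE, prob = plen)
      s <- peaks$start[pi] + floor(runif(n_pk) * pmax(plen[pi] - rl, 1))
      parts$peak <- tibble(chrom = peaks$chrom[pi], start = s,
                           end = pmin(s + rl, genome[peaks$chrom[pi]]),
                           strand = sample(c("+", "-"), n_pk, replace = TRUE))
    }
    if (length(planted_genes)) {
      W <- design$readthrough_window
      lam <- design$decay_length
      pg <- genes[genes$gene_id %in% planted_genes, ]
      p_gene <- w[match(pg$gene_id, genes$gene_id)] / sum(w)
      exp_body <- n_body * p_gene
      n_down <- vapply(
        exp_body * design$readthrough_ratio * W / (pg$end - pg$start),
        function(mu) stats::rpois(1, mu), 0L
      )
      for (i in seq_len(nrow(pg))) {
        if (n_down[i] == 0) next
        u <- runif(n_down[i])
        off <- -lam * log(1 - u * (1 - exp(-W / lam)))
        clen <- genome[[pg$chrom[i]]]
        if (pg$strand[i] == "+") {
          s <- pmin(floor(pg$end[i] + off), clen - rl)
          e <- s + rl
        } else {
          e <- pmax(ceiling(pg$start[i] - off), rl)
          s <- e - rl
        }
        parts[[paste0("rt", i)]] <- tibble(chrom = pg$chrom[i], start = s,
                                           end = e, strand = pg$strand[i])
      }
    }
    dplyr::bind_rows(parts)
  })
}

#' Stub differential-expression table on synthetic genes
#'
#' Marks genes significant with elevated probability for truth-table
#' dual-marked genes and draws log-fold-changes with a configurable
#' down-bias among dual-marked significant genes. Provided only so the
#' enrichment stage can be exercised end-to-end on synthetic data.
#'
#' @param design A [synth_design()].
#' @param genes Gene models.
#' @param truth_genes Truth table from [plant_marks()].
#' @param p_sig_dual,p_sig_other Significance probabilities.
#' @param p_down_dual Probability a significant dual-marked gene is
#'   downregulated (default 0.64).
#' @return Tibble `gene_id`, `log_fc`, `significant`.
#' @export
make_de_table <- function(design, genes, truth_genes,
                          p_sig_dual = 0.5, p_sig_other = 0.1,
                          p_down_dual = 0.64) {
  withr::with_seed(child_seed(design$seed, "de"), {
    dual <- truth_genes$has_both[match(genes$gene_id, truth_genes$gene_id)]
    sig <- runif(nrow(genes)) < ifelse(dual, p_sig_dual, p_sig_other)
    down <- runif(nrow(genes)) < ifelse(dual, p_down_dual, 0.5)
    mag <- abs(stats::rnorm(nrow(genes), 0, 1)) + ifelse(sig, 1, 0)
    tibble(
      gene_id = genes$gene_id,
      log_fc = ifelse(down, -mag, mag),
      significant = sig
    )
  })
}

#' Random pathway collection with one planted dual-marked pathway
#'
#' Builds GMT-style gene sets by uniform sampling, plus one pathway
#' drawn mostly from dual-marked genes so enrichment recovery can be
#' tested.
#'
#' @param design A [synth_design()].
#' @param genes Gene models.
#' @param truth_genes Truth table from [plant_marks()].
#' @param n_pathways Number of random pathways (default 15).
#' @param size_range Pathway size bounds.
#' @return Named list of gene-id vectors; the planted set is
#'   `"PLANTED_DUAL"`.
#' @export
make_pathways <- function(design, genes, truth_genes, n_pathways = 15,
                          size_range = c(10, 40)) {
  withr::with_seed(child_seed(design$seed, "pathways"), {
    ids <- genes$gene_id
    dual <- truth_genes$gene_id[truth_genes$has_both]
    pw <- lapply(seq_len(n_pathways), function(i) {
      sample(ids, sample(seq(size_range[1], size_range[2]), 1))
    })
    names(pw) <- sprintf("RANDOM_%02d", seq_len(n_pathways))
    k <- min(length(dual), 25)
    if (k >= 5) {
      pw$PLANTED_DUAL <- unique(c(sample(dual, k), sample(ids, 5)))
    }
    pw
  })
}

#' Simulate a complete two-condition study
#'
#' Runs the full generator: annotation and TPMs, planted mark sets, one
#' read library per mark, and two expression-condition libraries where
#' condition B carries planted readthrough in a random subset of active
#' genes.
#'
#' @param design A [synth_design()].
#' @return List with `design`, `genes`, `tpm`, `marks` (from
#'   [plant_marks()]), `reads_hmc`, `reads_rloop`, `reads_rna_a`,
#'   `reads_rna_b`, and `planted_genes`.
#' @export
simulate_study <- function(design = synth_design()) {
  ann <- make_annotation(design)
  marks <- plant_marks(design, ann$genes, ann$tpm)
  active_ids <- ann$genes$gene_id[
    ann$tpm$tpm[match(ann$genes$gene_id, ann$tpm$gene_id)] > marks$tpm_threshold
  ]
  planted <- withr::with_seed(child_seed(design$seed, "planted"), {
    sample(active_ids, round(design$readthrough_fraction * length(active_ids)))
  })
  list(
    design = design, genes = ann$genes, tpm = ann$tpm, marks = marks,
    reads_hmc = sample_reads(design, ann$genes, ann$tpm, marks$hmc, "hmc"),
    reads_rloop = sample_reads(design, ann$genes, ann$tpm, marks$rloop, "rloop"),
    reads_rna_a = sample_reads(design, ann$genes, ann$tpm, NULL, "rnaA"),
    reads_rna_b = sample_reads(design, ann$genes, ann$tpm, NULL, "rnaB",
                               planted_genes = planted),
    planted_genes = planted
  )
}

#' Write synthetic fixtures and a regeneration manifest
#'
#' Emits the dialects the pipeline reads (BED6, TSV) plus a JSON manifest
#' holding the full design (including the seed) and an md5 checksum per
#' file, sufficient to regenerate everything.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixtures <- function(study, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) abort(paste("cannot write to", dir))
  fp <- function(f) file.path(dir, f)
  write_bed(study$genes, fp("genes.bed"))
  readr::write_tsv(study$tpm, fp("tpm.tsv"), progress = FALSE)
  write_bed(study$marks$hmc, fp("hmc_peaks.bed"))
  write_bed(study$marks$rloop[c("chrom", "start", "end", "id")],
            fp("rloop_regions.bed"))
  readr::write_tsv(study$marks$truth_genes, fp("truth_genes.tsv"), progress = FALSE)
  readr::write_tsv(study$marks$truth_peaks, fp("truth_peaks.tsv"), progress = FALSE)
  for (nm in c("reads_hmc", "reads_rloop", "reads_rna_a", "reads_rna_b")) {
    write_bed(study[[nm]], fp(paste0(nm, ".bed")))
  }
  readr::write_lines(study$planted_genes, fp("planted_genes.txt"))
  files <- list.files(dir)
  manifest <- list(
    design = unclass(study$design),
    files = as.list(setNames(unname(tools::md5sum(file.path(dir, files))), files))
  )
  jsonlite::write_json(manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
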