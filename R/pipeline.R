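#' Run the full co-localization pipeline
#'
#' Chains every stage on synthetic fixtures (or a pre-simulated study):
#' annotation and active-gene filtering, peak-to-gene assignment, mark
#' classification, the permutation overlap test, binned-signal
#' correlation, two-condition readthrough comparison, and pathway
#' enrichment of dual-marked differentially expressed genes. All result
#' tables are written as TSV together with a JSON manifest carrying the
#' resolved configuration, seed and per-file checksums, so a run is
#' reproducible from its manifest alone.
#'
#' @param out_dir Output directory.
#' @param design A [synth_design()]; its seed drives all randomness.
#' @param study Optional pre-built [simulate_study()] result (overrides
#'   `design`).
#' @param n_shuffles Permutation-test shuffles (default 1000).
#' @param percentile Active-gene TPM percentile (default 25).
#' @param upstream,downstream Gene-window flanks in bp (default 4000).
#' @param bin_size Coverage-track bin in bp (default 20).
#' @param write_fixture_files Also write the raw synthetic fixtures
#'   (default FALSE).
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(out_dir, design = synth_design(), study = NULL,
                         n_shuffles = 1000, percentile = 25,
                         upstream = 4000, downstream = 4000, bin_size = 20,
                         write_fixture_files = FALSE) {
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) abort(paste("cannot create", out_dir))
  if (is.null(study)) study <- simulate_study(design)
  design <- study$design
  genome <- attr(study$genes, "genome") %||% .design_genome(design)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  active <- filter_expressed(study$genes, study$tpm, percentile = percentile)
  say("genes: %d annotated, %d active (TPM > %.3f at percentile %g)",
      nrow(study$genes), nrow(active), attr(active, "tpm_threshold"), percentile)

  windows <- gene_windows(active, upstream, downstream, genome)
  hmc_assign <- assign_to_genes(study$marks$hmc, windows)
  rloop_assign <- assign_to_genes(study$marks$rloop, windows)
  say("peaks assigned: %d 5hmC (%d unassigned), %d R-loop (%d unassigned)",
      length(unique(hmc_assign$peak_id)), length(attr(hmc_assign, "unassigned")),
      length(unique(rloop_assign$peak_id)), length(attr(rloop_assign, "unassigned")))

  marks <- classify_gene_marks(
    active, hmc_assign, rloop_assign,
    hmc_peaks = study$marks$hmc, rloop_regions = study$marks$rloop,
    windows = windows
  )
  mark_summary <- glance(marks)

  universe <- shuffle_universe(active[c("chrom", "start", "end")])
  perm <- permutation_overlap_test(
    study$marks$hmc, study$marks$rloop, universe,
    n_shuffles = n_shuffles, seed = child_seed(design$seed, "permtest")
  )

  track_hmc <- coverage_track(study$reads_hmc, genome, bin_size)
  track_rloop <- coverage_track(study$reads_rloop, genome, bin_size)
  corr <- binned_signal_correlation(track_hmc, track_rloop, active)

  dwin <- downstream_windows(study$genes, genome = genome)
  rt_a <- readthrough_table(study$reads_rna_a, study$genes, dwin, condition = "A")
  rt_b <- readthrough_table(study$reads_rna_b, study$genes, dwin, condition = "B")
  rt_cmp <- compare_readthrough(rt_a, rt_b)
  say("readthrough: %d windows, %d/%d records kept (A/B), %d enriched in B",
      nrow(dwin), nrow(rt_a), nrow(rt_b), length(rt_cmp$enriched))

  de <- make_de_table(design, study$genes, study$marks$truth_genes)
  de_marks <- intersect_de_with_marks(
    de, classify_gene_marks(study$genes, hmc_assign, rloop_assign,
                            hmc_peaks = study$marks$hmc,
                            rloop_regions = study$marks$rloop,
                            windows = windows)
  )
  pathways <- make_pathways(design, study$genes, study$marks$truth_genes)
  dual_sig <- union(de_marks$down_dual, de_marks$up_dual)
  enr <- if (length(dual_sig)) {
    fisher_enrichment(dual_sig, pathways, active$gene_id[
      active$gene_id %in% study$genes$gene_id])
  } else NULL

  fp <- function(f) file.path(out_dir, f)
  readr::write_tsv(as_tibble(marks), fp("gene_marks.tsv"), progress = FALSE)
  readr::write_tsv(mark_summary, fp("mark_summary.tsv"), progress = FALSE)
  readr::write_tsv(glance(perm), fp("permutation_test.tsv"), progress = FALSE)
  readr::write_tsv(tidy(perm), fp("permutation_null.tsv"), progress = FALSE)
  readr::write_tsv(corr, fp("signal_correlation.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(rt_a, rt_b), fp("readthrough.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(rt_cmp), fp("readthrough_comparison.tsv"),
                   progress = FALSE)
  readr::write_tsv(glance(rt_cmp), fp("readthrough_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(de, fp("de_table.tsv"), progress = FALSE)
  if (!is.null(enr)) {
    readr::write_tsv(enr, fp("pathway_enrichment.tsv"), progress = FALSE)
  }
  if (write_fixture_files) write_fixtures(study, file.path(out_dir, "fixtures"))

  files <- setdiff(list.files(out_dir), c("manifest.json", "fixtures"))
  manifest <- list(
    tool = "epicoloc", version = as.character(utils::packageVersion("epicoloc")),
    seed = design$seed,
    config = list(
      design = unclass(design), n_shuffles = n_shuffles,
      percentile = percentile, upstream = upstream, downstream = downstream,
      bin_size = bin_size
    ),
    log = log,
    files = as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))),
                             files))
  )
  jsonlite::write_json(manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    active = active, marks = marks, mark_summary = mark_summary, perm = perm,
    correlation = corr, readthrough = list(a = rt_a, b = rt_b, cmp = rt_cmp),
    de = de, de_marks = de_marks, enrichment = enr, manifest = manifest
  ))
}
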