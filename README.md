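# epicoloc

Genome-wide co-localization analysis of epigenomic marks — built for the
question of whether 5-hydroxymethylcytosine (5hmC, mapped by hMeDIP-seq)
and R-loops (DNA:RNA hybrids, mapped by DRIP-seq) occupy the same active
genes, and what that co-occupancy does to transcription termination and
gene expression. The package is aimed at computational genomicists who
have peak calls (BED), mapped read positions (BED), expression tables
(TPM TSV) and differential-expression calls, and who want a tested,
reproducible implementation of the full analysis rather than a pile of
one-off scripts.

## What it computes

* **Gene models and active genes.** Transcripts are merged into one model
  per gene (union span; TSS/TTS are the biological 5'/3' ends).
  Active genes are those with TPM strictly above a percentile of the
  per-gene TPM distribution (default: the 25th percentile, linear
  interpolation, absent genes counted as 0).
* **Peak-to-gene assignment.** Enriched regions are assigned to every
  gene whose window — gene body plus 4 kb upstream of the TSS and 4 kb
  downstream of the TTS — they overlap by at least 1 bp.
* **Coverage and profiles.** Reads are 3'-extended to 150 nt, binned
  (20 bp default) with fractional assignment, and RPKM-normalized:
  `RPKM = count * 1e9 / (bin_size * total_mapped)`. From the track the
  package builds summit-anchored metaprofiles (±10 kb, 200 bp bins) and
  gene-body metagenes (body scaled to 60 bins, ±10 kb flanks in 200 bp
  bins), both as mean ± SEM across regions.
* **The permutation co-localization test.** The observed statistic is
  the number of query regions (5hmC by default) overlapping the subject
  set (R-loops) by ≥ 1 bp. The null re-places both sets uniformly within
  the merged active-gene bodies, preserving region counts and lengths,
  `N` times (default 1000). The empirical p-value is the add-one rule

  `p = (1 + #[null >= observed]) / (1 + N)`

  with the raw exceedance frequency reported alongside.
* **Per-gene mark classification.** Each active gene is labeled
  5hmC-only / R-loop-only / dual-marked ("both": at least one 5hmC peak
  and one R-loop region overlapping each other within the gene window) /
  neither, with percentages over the active-gene denominator, plus the
  Pearson correlation of the two binned signals over gene bodies.
* **Transcription readthrough.** Per gene, the RPKM downstream of the
  TTS (up to 5 kb, truncated at the next gene) over the body RPKM; a
  two-condition comparison flags enriched genes (ratio ≥ 1.5) and tests
  the global shift with a paired rank test (the unpaired Mann–Whitney U
  is reported too).
* **Enrichment.** Fractions of significantly down-/up-regulated genes
  that are dual-marked, and one-sided Fisher's exact pathway enrichment
  against the expressed-gene background with Benjamini–Hochberg control.
* **Synthetic data.** A full generator with planted structure —
  co-occurrence rate, TTS bias, planted readthrough — so every statistic
  above can be validated by parameter recovery.

## Worked example

```r
library(epicoloc)

design <- synth_design(seed = 7)          # 400 genes, 2 x 5 Mb, rho = 0.5
res <- run_pipeline("results", design = design, n_shuffles = 200)

glance(res$marks)[c("n_active", "n_both", "pct_both")]
#>   n_active n_both pct_both
#> 1      300    160     53.3

glance(res$perm)[c("observed", "null_mean", "p_value")]
#>   observed null_mean  p_value
#> 1      396    156.27 0.004975

res$correlation
#>   pearson_r p_value n_bins_used
#> 1     0.881       0       18000
```

300 of 400 synthetic genes pass the activity filter; 160 of them (53.3%)
carry mutually overlapping 5hmC and R-loop marks. The observed overlap
(396 of 600 5hmC peaks touching an R-loop) far exceeds the shuffle null
(mean 156), giving the smallest p reachable at N = 200 shuffles, and the
two binned signals correlate strongly across active gene bodies — the
expected outcome for a generator planting 50% co-occurrence.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/epicoloc.R all --seed 7 --out results/
```

Every run writes its result TSVs plus a `manifest.json` with the
resolved configuration, seed and per-file checksums; the same seed and
config reproduce byte-identical outputs.

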