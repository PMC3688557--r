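# chromintegrate

Integrated chromatin and expression analysis of differentiation time
courses, for epigenomics researchers who profile a cell-state transition
with both expression arrays (or any intensity matrix) and histone-mark
ChIP-seq and want the two layers combined into testable statements about
regulation.

The package covers the full analysis arc of a two-endpoint differentiation
study (day 0 cells becoming day 8 cells in culture, sampled at five time
points with three donors):

* **Moderated differential expression.** Raw intensities are calibrated and
  glog-transformed, `glog(x) = asinh((x − a_s)/(b_s c)) / ln 2`, then a
  group-means model over the time course yields the D8 − D0 contrast with an
  empirical-Bayes moderated t: variances shrink toward a moment-matched
  prior, `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, with BH control of the FDR
  and a most-significant-probe collapse to genes. Ward clustering,
  silhouettes and PCA provide sample QC.
* **Cross-species overlap.** Two species' gene-level results are reduced to
  one-to-one ortholog pairs and the overlap k of their significant sets is
  tested with the one-sided hypergeometric upper tail P(X ≥ k | N, |A|, |B|)
  (Fisher's exact two-sided p alongside), with a concordant/discordant
  direction partition.
* **Island calling.** A window/gap caller for broad histone-mark domains:
  600-bp windows, Poisson background λ = reads·w/(f·G), eligible windows
  (tail < p₀) merged across ≤600-bp gaps, islands scored by Σ −ln P(count|λ)
  and tested against flank-smoothed, library-scaled input chromatin at a BH
  q-value. Differential occupancy (shared vs day-specific at ≥1-bp overlap),
  saturation curves, 2-Mb genome bins and inter-mark correlation included.
* **Motif enrichment and the signed dual-mark statistic.** PWMs scanned as
  log2-odds on both strands; per-motif exact hypergeometric enrichment of
  one day's islands against the opposite day's as background; per motif the
  pair (x, y) of signed −log10 best p for the two marks (negative = day 0,
  positive = day 8), whose negative correlation across motifs quantifies the
  acetylation/trimethylation antagonism.
* **16-state integration.** Day-specific islands annotate to the nearest
  TSS; each gene gets four binary chromatin-change flags (2⁴ = 16 states)
  joined to its expression direction, plus a generic hypergeometric gene-set
  enrichment for follow-up.
* **Synthetic data with recorded truth.** Generators for expression
  matrices, genomes, read piles, motif plantings and state–direction
  couplings, so every stage is tested against planted ground truth without
  any downloads.

## Worked example

Simulate a study at the default conditions, run the expression arm, call
islands for the acetylation mark at both days, and classify occupancy:

```r
library(chromintegrate)

cfg  <- sim_config(seed = 42)
sim  <- simulate_expression(cfg)
norm <- glog_normalize(sim$matrix)
fit  <- fit_moderated_ttest(norm$matrix)          # D8 - D0, BH at 0.05
genes <- collapse_probes_to_genes(fit$table, sim$probe_map)
sum(fit$table$p_adj <= 0.05)                      # 280 significant probes
table(genes$direction)[c("up", "down")]           # 133 up, 112 down genes

chip <- simulate_chip(cfg)
isl0 <- call_islands(chip$reads$ac_d0, chip$reads$input, island_config())
isl8 <- call_islands(chip$reads$ac_d8, chip$reads$input, island_config())
differential_occupancy(isl0, isl8)
#> DifferentialOccupancy: 45 D0-specific, 43 D8-specific, 28/28 shared
#>   (union fraction 0.39)
```

280 probes (245 genes) pass BH 0.05; against the planted truth that is 94%
recall at 3.7% false discovery. The occupancy summary says 45 acetylation
islands are specific to day 0, 43 to day 8, and 39% of the union is shared
between the days — the kind of partial chromatin turnover expected of two
related cell states.

The overlap statistic works directly from printed marginal counts too. For a
universe of 13,173 genes with 3,662 and 3,973 significant genes in the two
species and 1,514 shared:

```r
overlap_test(list(N = 13173, n_a = 3662, n_b = 3973, k = 1514))
#> OverlapResult: N=13173 |A|=3662 |B|=3973 overlap=1514 (expected 1104.5)
#>   hypergeometric upper-tail p = 1.6e-65 (log10 = -64.8); Fisher p = 2.87e-65
```

The observed sharing exceeds the 1,104 expected by chance with p ≈ 10⁻⁶⁵ —
far below any conventional reporting floor.

`run_pipeline(pipeline_config(seed = 7))` chains all stages (simulate →
expression → islands → motifs → integration → overlap) and emits a JSON
report plus per-stage TSV/BED outputs; a command-line front end lives at
`inst/cli/chromintegrate.R` (`run-all`, `call-islands`, `simulate`,
`validate`).

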