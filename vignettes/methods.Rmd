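---
title: "Methods: integrating histone-mark islands with expression time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating histone-mark islands with expression time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromintegrate implements a complete differentiation-epigenomics analysis:
moderated differential expression over a cultured-cell time course (day 0 to
day 8), cross-species comparison of the resulting gene sets, broad-domain
histone-mark island calling from ChIP-seq reads with an input-chromatin
background, motif enrichment within day-specific islands, a signed dual-mark
motif statistic, and a 16-state integration of chromatin change with
expression direction. This vignette records the models, the tunable
parameters, and the design decisions behind each stage, in the order the
pipeline runs them.

## Expression: glog calibration

Bead-array fluorescence intensities are non-negative, heteroskedastic, and
offset by optical background. We calibrate each sample affinely and apply a
generalized log transform,

$$\mathrm{glog}(x) = \frac{\operatorname{asinh}\!\big((x - a_s)/(b_s c)\big)}{\ln 2},$$

which behaves like $\log_2$ for bright probes (one doubling adds one unit)
while remaining defined and variance-stabilizing at background. The offset
$a_s$ is the median of a *dim-probe reference stratum* — the 10% of probes
with the lowest overall mean intensity — standing in for the optical
background of sample $s$. The scale $b_s$ is a median-of-ratios factor
against a pseudo-reference sample (the row-wise median of offset-corrected
intensities), the same estimator DESeq-style size factors use; it matches
per-sample distributions without letting a handful of bright probes dominate.
The cofactor $c$ defaults to the pooled median absolute deviation of the dim
stratum, i.e. the background noise scale, which places the linear-to-log
transition of the transform at the noise floor. A sample whose scale estimate
is non-positive (an all-constant column) is rejected rather than silently
passed through.

This is deliberately not a full maximum-likelihood variance-stabilizing fit:
the downstream statistics depend only on the properties the calibration
guarantees — strict monotonicity per sample, matched medians, asymptotic
log2-linearity — and each of those is directly testable, which a black-box
likelihood fit is not.

## Expression: moderated t between the first and last day

A group-means linear model with day as a factor is fit to all time points at
once by ordinary least squares; technical replicates are removed beforehand
(they would otherwise deflate residual variance). The contrast of interest is
the simple difference day 8 minus day 0. With only a few biological donors
per day, per-probe variances $s^2_g$ are unstable, so they are shrunk toward
a prior by empirical Bayes:

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
\tilde t_g = \frac{\widehat{\Delta}_g}{\tilde s_g \sqrt{v}},$$

referred to a t distribution on $d_0 + d_g$ degrees of freedom. The
hyperparameters $(s_0^2, d_0)$ are estimated by moment matching of
$\log s^2_g$ under the scaled-F model — closed-form, deterministic, and
checkable against an independent implementation (the test suite verifies
equality with limma's `squeezeVar` hyperparameters and recovery of known
$(s_0^2, d_0)$ from simulated variances). Two limits anchor the statistic:
at $d_0 = 0$ it is exactly the ordinary pooled t, and as $d_0 \to \infty$ it
becomes a common-variance z-like statistic; both are asserted numerically.
When the moment estimate of $d_0$ is not finite the fit falls back to
$d_0 = 0$ (no moderation) with a warning — the conservative direction, since
unmoderated t-statistics never overstate the information in the prior.

Significance is Benjamini–Hochberg adjusted at $\alpha = 0.05$. Probes
collapse to genes by the most-significant-probe rule: a gene is significant
if any probe is, inherits that probe's statistics, and is flagged
*bidirectional* when its significant probes disagree in sign (arrays carry
multiple probes per gene in different gene regions, and a handful genuinely
move in opposite directions). Ties are broken by raw p, then absolute effect,
then probe id, so the collapse is deterministic.

Sample-level QC mirrors standard array practice: the top 5% most variant
probes (ties broken lexicographically) feed Ward clustering on Euclidean
distances (`ward.D2`, the squared-distance-correct form) with silhouette
widths, and a centered PCA whose component signs are fixed by forcing the
largest-magnitude loading positive.

## Cross-species overlap

Human and rat gene-level results are reduced to one-to-one ortholog pairs
measured on both platforms; many-to-many pairs are dropped and counted
rather than resolved by best-hit, since no defensible resolution rule exists
without sequence data. On the common universe of $N$ genes the overlap $k$
of the two significant sets (sizes $|A|$, $|B|$) is tested with the
one-sided hypergeometric upper tail $P(X \ge k)$; the two-sided Fisher exact
p of the implied 2×2 table is reported alongside, because published overlap
statements at the conventional `2.2e-16` floor do not identify which test
produced them. Overlap is defined on significance regardless of direction —
the discordant genes are real and are reported separately as the
concordant-up / concordant-down / discordant partition.

## Island calling

Broad histone-mark domains (H3K9/14 acetylation, H3K27 trimethylation) are
called with a window/gap model. The genome is tiled into non-overlapping
$w$-bp windows ($w = 600$); a read contributes its 5′ position (no fragment
extension — none is identifiable from the data, and 5′ counting is exactly
reproducible). Under a background rate
$\lambda = N_{\mathrm{reads}} \, w / (f G)$ (effective genome fraction
$f = 0.8$), a window is *eligible* when its count has Poisson upper-tail
probability below $p_0 = 0.2$. Eligible windows separated by at most $g$ bp
of ineligible windows ($g = 600$, rounded up to whole windows) merge into an
island scored by $\sum -\ln P(X = n_i \mid \lambda)$ over its eligible
members. Islands therefore always start and end on eligible windows and
align to window boundaries.

Each candidate island is then tested against input chromatin: its read count
is compared to a Poisson mean given by the library-scaled input. A raw
per-island input count spans only a few windows and is far too noisy to be a
rate estimate, so the local input rate is estimated over the island plus
5 kb flanks and rescaled to the island width — the local-lambda idea
familiar from narrow-peak callers — floored at the genome-uniform
expectation so the mean is positive even where input coverage is locally
zero (and as the sole background, with a warning, when no input library is
given). Island p-values are BH-adjusted and kept at $q \le 0.01$. Window
eligibility $p_0$, the island FDR $q$, and $f$ are defaults in the caller
configuration, flagged as assumptions; only window and gap are fixed by the
upstream protocol.

Downstream conveniences follow table-browser conventions: two days' islands
are *shared* on any $\ge$1-bp overlap, otherwise day-specific (shared
fractions are reported per day and on the union, since either denominator is
defensible); saturation curves re-call islands on seeded subsamples of the
read library; genome-wide densities count features into half-open 2-Mb bins
by midpoint (a midpoint exactly on a boundary belongs to the higher bin);
and inter-mark similarity is reported both as the Pearson correlation of
binary window-occupancy vectors and as the Jaccard index of covered base
pairs, with the correlation withheld when a vector has zero variance.

## Motif enrichment and the signed dual-mark statistic

Motifs are position probability matrices with a pseudocount, scored as log2
odds against a uniform background on both strands; a window is a hit at 80%
of the motif's maximal score (configurable per motif). Scanning skips
windows containing N and reports 0-based forward-strand offsets. Enrichment
of one day's mark-specific islands uses the *opposite* day's islands as
background — a condition-swap design that cancels sequence-composition
biases shared by both days. Each island is truncated to ±500 bp around its
midpoint before scanning so that island-length differences cannot masquerade
as enrichment, and the per-motif statistic is the exact hypergeometric upper
tail on presence/absence counts, BH-adjusted across motifs. This replaces a
ZOOPS binomial with an exact test on the same sufficient statistic
(islands-with-hit), which an exhaustive enumeration oracle can verify.

For each motif the stronger of its two acetylation enrichments sets
$x = \pm(-\log_{10} p_{\min})$ — negative when day 0 wins, positive for
day 8 — and $y$ does the same for the repressive mark. A motif with equal p
at both days scores exactly 0, which makes the statistic antisymmetric under
swapping the day labels, a property the tests assert. The Pearson and
Spearman correlations of $(x, y)$ across motifs summarize the
activation/repression antagonism: motifs enriched where acetylation is
gained tend to be enriched where trimethylation is lost, producing a strong
negative correlation.

The shipped motif library (`inst/extdata/motifs_synthetic_jaspar.txt`) is a
synthetic, hand-written set of 21 JASPAR-format matrices — six with
consensus sequences resembling well-known transcription-factor families
(nuclear-receptor direct repeat, forkhead, TATA, CEBP, TCF, zinc-finger) and
fifteen randomized decoys. It exists to exercise and test the machinery;
real analyses should supply a curated library via `load_pwms()`.

## 16-state integration

Day-specific islands (shared islands deliberately set no flag — a domain
present at both days is not a chromatin *change*) are annotated to the
nearest transcription start site by island midpoint, with exact-distance
ties broken by the smaller gene id and signed distances negative upstream of
the TSS relative to gene strand. Midpoints, not edges, anchor the distance
because a single point is stable under the window-quantized boundary jitter
of the caller. No distance cap is applied by default (`max_distance` exists
and its effect is reported), since the appropriate cap depends on genome
compactness.

Each gene in the universe (the genes measured on the expression platform)
then carries four binary flags — acetylation day-0-specific,
day-8-specific, trimethylation day-0-specific, day-8-specific — encoded as
state $= \mathrm{ac}_{d0} + 2\,\mathrm{ac}_{d8} + 4\,\mathrm{me3}_{d0} +
8\,\mathrm{me3}_{d8} \in \{0, \dots, 15\}$. State 0 is "no chromatin change
near the gene"; state 6 ($\mathrm{ac}_{d8} + \mathrm{me3}_{d0}$) is the
fully activating gain-acetylation / loss-trimethylation combination. The
integration summary tallies up/down/unchanged expression per state and the
fraction of significant genes carrying at least one flag. A generic
hypergeometric gene-set enrichment is provided for pathway-style follow-up
of any state's gene list.

## Synthetic data and what passing tests mean

Every stage is exercised on generated data with recorded truth, so the
generators' defaults are part of the method's documentation:

* **Expression** — 2000 probes over 1667 genes (some genes carry two
  probes), days 0/2/4/6/8, three donors, technical duplicates of day 0 and
  day 4; per-probe variances from a scaled inverse-chi-square with
  $s_0^2 = 0.04$, $d_0 = 4$; 15% of genes planted with a ±1.5 log2 effect
  reached linearly at day 8; donor offsets (SD 0.15 log2); intensities
  exponentiated and given additive background (mean 30, SD 5) so the glog
  calibration is genuinely exercised.
* **ChIP** — a 10 Mb, four-chromosome genome (enough for >16,000 windows at
  600 bp while staying desk-scale); background reads uniform at
  $\lambda = 0.25$ per window in chip and matched input; planted islands of
  3–8 windows at 10-fold enrichment, placed disjointly with a two-window
  buffer (re-drawn up to a retry cap, exact feasibility sampling when
  dense); 36-bp reads, as in single-end GAII-era sequencing, with the 5′
  position placed so window counts are exactly the drawn Poisson counts.
  Sequences are i.i.d. uniform ACGT; motif consensus instances are written
  into day-specific island centers with per-class probabilities.
* **Coupling** — per-gene expression direction drawn with
  $P(\mathrm{up} \mid \mathrm{state})$, default 0.3 baseline and 0.8 for
  state 6, either on states derived geometrically from a ChIP truth or on
  directly specified per-state gene counts.

The generators are pure functions of their configuration (every test and
the acceptance script reruns them byte-identically from a seed). They
emulate the *structure* of real data, not its pathologies: no GC or
mappability structure, no bead-array spatial artifacts, no fragment-length
effects, uniform base composition. Passing recovery tests therefore
demonstrates that the algorithms are correct and calibrated under their
stated models — not that real tissue data will be as clean. Problem sizes
in the routine test runs (10 Mb genomes, 2000 probes, 20–50 replicates per
property) were chosen as the smallest scales at which the planted effects
are statistically unambiguous.

## Numerical and interface decisions

* Coordinates are BED-convention 0-based half-open on disk and in every
  user-facing table; GRanges's 1-based closed convention is internal only.
* All tie-breaks (variance ranking, probe collapse, nearest-TSS, PWM
  ranking) are deterministic, by id where no better key exists.
* The trigamma inversion in the variance-prior estimate uses the standard
  Newton iteration with asymptotic guards at both ends.
* Hypergeometric tails come from `phyper` (with `log.p` for reporting
  p-values beyond double underflow), Fisher tests from `fisher.test`, BH
  from `p.adjust`; none of these are reimplemented.
* The command-line front end (`inst/cli/chromintegrate.R`) exposes
  `run-all`, `call-islands`, `simulate`, and `validate`. Per-stage shell
  wrappers were considered and dropped: each stage is an exported,
  documented R function, and `run-all` chains them; duplicating every stage
  as argument-parsing shims would double the surface without adding
  capability.

## Known limitations

* The island caller assumes reads are independent draws; PCR duplicates are
  not collapsed by default and would inflate scores.
* The per-island input test conditions on the smoothed local input rate as
  if it were known; for very deep input libraries this is accurate, for
  shallow ones it is mildly anti-conservative.
* Nearest-TSS annotation is a proximity heuristic; it cannot represent
  enhancer–gene skipping, and with no distance cap every island is assigned
  to some gene.
* The expression model treats donors as independent noise; persistent donor
  batch effects beyond an offset are not modeled.
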