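---
title: "Methods: cross-study consensus analysis of offspring liver transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study consensus analysis of offspring liver transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepmeta)
```

## The scientific problem

Maternal obesity raises the offspring's risk of chronic liver disease, but
individual transcriptome studies of offspring liver are small, heterogeneous
(microarray and RNA-seq, different ages, sexes and diet protocols), and each
underpowered to pin down the genes involved. The strategy this package
implements is integrative: analyze each two-group comparison (offspring of
obese vs. lean mothers) separately, then ask which genes and which pathways
are dysregulated *consistently* across comparisons drawn from independent
studies. The package also carries the small quantitative methods that such a
murine study uses around the transcriptomics: area-fraction quantification
of steatosis and fibrosis on histology images, qPCR reference-gene
normalization, OGTT areas under the curve, and Mann-Whitney group
comparisons.

Everything is verifiable without external downloads because the package
ships a synthetic-data generator that plants known consensus genes, known
pathway enrichments, and histology slides with known vacuole and fibrosis
area fractions.

## Differential expression: the moderated t model

For one comparison with groups A and B (sizes $n_A$, $n_B$) on log2-scale
expression, each gene $g$ gets

$$\mathrm{logFC}_g = \bar{x}_{B,g} - \bar{x}_{A,g}, \qquad
s^2_g = \frac{\sum_A (x - \bar{x}_A)^2 + \sum_B (x - \bar{x}_B)^2}{d},
\quad d = n_A + n_B - 2 .$$

Gene-wise variances are unstable at these sample sizes (3-9 per group), so
they are shrunk toward a prior estimated across all genes. The model is the
standard empirical-Bayes one: $\sigma^2_g$ follows a scaled
inverse-chi-squared prior with parameters $(d_0, s_0^2)$, which makes the
marginal distribution of the sample variances $s^2_g / s_0^2 \sim F(d, d_0)$.
The prior is estimated by matching the mean and variance of $\log s^2_g$ to
their theoretical values (digamma/trigamma moments of the log-F
distribution), with $d_0$ clamped to $[0.1, 10^6]$ — a deterministic,
closed-form procedure. The posterior variance and moderated statistic are

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
t_g = \frac{\mathrm{logFC}_g}{\sqrt{\tilde{s}^2_g (1/n_A + 1/n_B)}}
\;\sim\; t_{d_0 + d} \ \text{under } H_0,$$

with two-sided p-values and 95% confidence intervals on $d_0 + d$ degrees
of freedom. Setting `d0 = 0` in `fit_comparison()` disables moderation and
reduces every gene exactly to the pooled two-sample t-test — the test suite
exploits this as an equivalence oracle, and separately cross-checks the
moderated path against limma's independent implementation of the same
model. No multiple-testing adjustment feeds the downstream rules: the
consensus criteria consume raw p-values by design (a BH-adjusted column is
emitted for information only). Each comparison is fitted separately rather
than as one model per study with contrasts; with two disjoint sample groups
per comparison the two parameterizations coincide, and the separate fit is
the simpler contract.

Genes with missing values among a comparison's samples are dropped from
that comparison only. Probe-level arrays are collapsed to genes beforehand
by keeping the probe with the highest mean expression (ties to the
lexicographically smallest probe id) — the dominant convention, chosen
because it is deterministic.

## Consensus genes

A gene *qualifies* in a comparison when $p < 0.05$ and
$|\mathrm{logFC}| > 0.1$ (directionally: `n_up` counts
$\mathrm{logFC} > 0.1$, `n_down` counts $\mathrm{logFC} < -0.1$). A gene is
a **consensus gene** when it qualifies in at least 3 comparisons, *or* in
comparisons from at least 2 independent studies (distinct series
accessions). Both clauses are alternatives ("or"), the more inclusive
reading of the selection rule. Records are ranked by three keys,
descending: number of qualifying comparisons, median $|\mathrm{logFC}|$
over qualifying comparisons, and Fisher's combined p-value (ascending);
residual ties break by gene id so the ordering is total and reproducible.

Two deliberate choices here:

* the median is taken of the *absolute* logFC over *qualifying* comparisons
  only — a gene qualifying only downward still shows a positive median
  effect size, and the key stays aligned with the evidence that was
  counted;
* Fisher's combination $X = -2\sum \ln p_i \sim \chi^2_{2k}$ uses the
  gene's p-values from **all** comparisons where it is measured, not only
  qualifying ones, because the classical method presumes no selection.
  Genes absent from a platform simply contribute fewer p-values; they are
  never imputed.

Direction conflicts (up in some comparisons, down in others) are allowed
and reported in both counts — real cross-sex comparisons show exactly this
pattern. No minimal-expression filter is applied before the consensus
stage.

A genes-of-interest list can be validated against the same records:
per listed gene the counts, median $|\mathrm{logFC}|$, combined p, and a
flag for qualification in $\geq 3$ comparisons; genes never measured are
reported as `absent`, not as zero counts.

## Pathway enrichment and pathway consensus

Per comparison, the universe is the set of annotated genes (present in the
gene-set collection's universe) measured in that comparison. Among those,
genes with $p \le 0.05$ are ranked by signed logFC and up to 250 with
positive logFC (descending) form the up-selection, up to 250 with negative
logFC (ascending) the down-selection — "most up-regulated" is read as
signed logFC within direction, which keeps the two sets disjoint by
construction. Each pathway is tested in each direction with the upper-tail
hypergeometric test, inclusive of the observed overlap:
$p = P(X \geq k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. No across-pathway
correction is applied; the replication requirement is the error control: a
pathway is **consensus-dysregulated** when it is significant at $p < 0.01$
in at least 3 comparisons (per comparison, one direction call; if both
directions reach the threshold the smaller p wins, so the heatmap has a
single signed entry per cell).

The per-comparison universe (rather than a fixed global one) accommodates
platforms that measure different gene sets; with the synthetic generator
the two coincide.

## Histology quantification

*Tissue detection.* Background pixels are near-white (all channels above
0.9, channel spread below 0.08); everything else is tissue, cleaned by a
3-px morphological opening and hole filling — so enclosed unstained
vacuoles count as tissue area, which makes the denominator stable.

*Steatosis.* Candidate vacuoles are near-white connected components inside
tissue, filtered by equivalent radius $\sqrt{A/\pi} \in [4, 40]$ px and
circularity $4\pi A / P^2 \geq 0.6$ (excludes vessels, tears and stripes).
The steatosis fraction is retained vacuole area over tissue area. The
whole-image denominator — the published formulation, "area of vacuoles over
total slide area" — is selectable with `denominator = "image"`; the
tissue-area default is robust to how much empty background a scan happens
to include. Dark nuclei are counted as a QC signal only.

*Fibrosis.* Fibrosis pixels are tissue pixels whose blue-dominance
$B - \max(R, G)$ exceeds 0.2. This replaces an interactively trained
classifier with a deterministic, parametric operator; the manual clean-up
steps of a pathology workflow have no computational analogue here and QC
overlays (the returned masks) stand in for visual validation.

All filter parameters are exposed as arguments since no reference values
exist for them; the defaults are tuned to the generator's geometry (vacuole
radii 5-30 px at the generated scale).

## The synthetic-data generator

The generator emulates the structure the analysis needs and nothing more:

* **Expression**: per study, gene baselines $\sim N(7, 1)$ on log2 scale;
  gene-wise residual SDs drawn from the scaled inverse-chi-squared prior
  with defaults $d_0 = 16$, $s_0^2 = 0.0025$ (residual SD $\approx 0.05$
  log2 units, i.e. a well-replicated normalized array where the 0.1 logFC
  gate sits $\geq 3$ standard errors above noise at $n = 8$/group — the
  regime in which an effect-size gate is meaningful at all); planted genes
  add their stated log2 fold change to group B in exactly the stated number
  of comparisons. Five studies contributing two comparisons each, in the
  CC/CO/OC/OO diet coding, mirror the real design. The default effect size
  for planted consensus genes is 0.5 in 4 of 10 comparisons at
  $n = 8$/group.
* **Pathways**: planted pathways perturb $\lceil f \cdot |S| \rceil$ of
  their members (default fraction 0.5, magnitude 1.0 log2 units, 4
  comparisons) in a fixed direction; background pathways are random draws.
* **Slides**: an elliptical pink tissue region on white background,
  non-overlapping near-white elliptical vacuoles (radius 5-30 px, axis
  ratio 0.7-1) placed until the target fraction of tissue area is reached
  within 1% absolute, blue elliptical fibrosis patches likewise, and small
  dark nuclei. Pixel noise SD 0.012.

Everything is a pure function of `(design, seed)`; each artifact draws from
a named substream of the seed so expression, gene sets, and slides can be
regenerated independently, and the planted truth is resolved in its own
substream so all artifacts agree on it.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: probe-level artifacts, batch effects, count
overdispersion in RNA-seq, correlated genes, staining variability, uneven
illumination, or sectioning artifacts. Recovery results on synthetic data
certify the pipeline's logic and calibration, not its robustness to those
real-world failure modes.

The variance structure of the original public datasets is not documented;
the inverse-chi-squared choice is the modelling convenience that matches
the moderated-t working model, and the noise level is this package's own
study condition, fixed once (see above) and used unchanged by all recovery
tests.

## Physiology utilities

qPCR relative quantities use the averaged-reference $\Delta C_t$ form,
$RQ = 2^{\overline{C_t}^{\mathrm{ref}} - C_t^{\mathrm{gene}}}$ with
references Eef1, Hprt and Gapdh — arithmetic averaging on the $C_t$ scale
equals geometric averaging of linear quantities under the assumed perfect
efficiency. No $\Delta\Delta C_t$ calibrator is applied because group
medians are compared downstream, where a common calibrator cancels. OGTT
AUC is the trapezoidal integral of raw glucose over the sampled window
(total, not incremental, AUC); it is additive over contiguous
sub-intervals, so the full 0-120 min window is a documented convention
rather than a hard precondition. Group comparisons use the Mann-Whitney
U-test — the appropriate test for independent groups, even where such
figure legends sometimes say "Wilcoxon" — exact by enumeration for untied
samples up to combined $n = 20$, otherwise the tie-corrected normal
approximation with continuity correction.

## Numerical and design choices worth knowing

* `trigamma_inverse` uses a guarded Newton iteration; degenerate
  log-variance spreads fall back to $d_0 = 10^6$ (near-complete pooling).
* Zero-variance genes: excluded from prior estimation; an all-zero-variance
  comparison is a processing error.
* p-values are clamped into $(0, 1]$; survival functions are used directly
  rather than `1 - cdf` to preserve small tails.
* Tie-breaks everywhere are lexicographic by identifier, making every
  ranking and selection deterministic.
* TSV writers use fixed options so repeated runs are byte-identical; the
  run manifest records a config hash, row counts per output, and — in
  synthetic mode — recall/precision of the consensus stage against the
  planted truth.

## Problem sizes used in the verification suite

The recovery tests run at the generator defaults (5 studies x 2
comparisons, 2000 genes, n = 8/group, 20 planted genes at logFC 0.5 in 4
comparisons; one planted 30-gene pathway at fraction 0.5) with 20
replicate seeds; null calibration uses 10,000 genes; distribution oracles
enumerate all hypergeometric instances with $N \le 12$ and all untied
Mann-Whitney configurations up to 7 per group; slides are 320 x 320 px.
These sizes were chosen as the smallest at which the Monte-Carlo bounds in
the tests are meaningful.

## Known limitations

* The consensus criteria are the published ones (raw p gates plus
  replication); they control errors through replication, not FDR, and the
  flagged-gene count on null data scales with the per-comparison joint
  pass rate (see the binomial null-control test).
* Effect sizes are not pooled across studies (no random-effects
  meta-analysis); the ranking keys are counts and medians.
* The histology operators assume reasonably clean RGB stains; they do not
  perform stain deconvolution and will miscount if vacuole-like bright
  regions touch the section boundary.
* Reproducing any specific published gene list would additionally require
  the original accessions' matrices, their probe annotations and the
  matching pathway-annotation release, none of which ship here.
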