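---
title: "Three-strain compensation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-strain compensation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comprev)
```

## The question the pipeline answers

The package analyses bulk RNA-seq from a three-group strain design: a
progenitor outbred strain (role `W`), a strain derived from it by long
selection for a phenotype (role `KM`), and a strain back-selected from
derived-by-progenitor hybrids for *absence* of that phenotype (role
`ZERO`). If the phenotype is driven by expression changes acquired during
selection, back-selection should *revert* those changes toward the
progenitor state. The pipeline quantifies this reversion per gene and
genome-wide:

1. Which genes differ between derived and progenitor (`KM` vs `W`), and
   between back-selected and derived (`ZERO` vs `KM`)?
2. For each derived-vs-progenitor DEG, how far back toward the progenitor
   did the back-selected strain move?
3. Do the two contrasts' fold changes run in opposite directions overall?
4. Which gene sets are enriched among up- and downregulated DEGs?

## Differential expression model

Counts are modelled as negative binomial, \(y_{gs} \sim
\mathrm{NB}(\mu_{gs}, \phi_g)\) with \(\mathrm{var} = \mu + \phi\mu^2\)
(\(\phi = 1/\text{size}\); this parameterization is used everywhere in the
package). The mean follows a log-linear model
\(\log \mu_{gs} = \beta_{g,\mathrm{group}(s)} + o_s\), with offsets
\(o_s\) the log effective library sizes from TMM normalization.

The test is a quasi-likelihood F-test built from scratch:

* **Dispersion**: per gene, \(\phi_g\) maximizes the Cox-Reid adjusted
  profile likelihood (profile log-likelihood minus half the log
  determinant of the mean-parameter information) on a 41-point log-spaced
  grid over \([10^{-4}, 10]\), with quadratic interpolation at the peak. A
  loess trend of \(\log\phi\) on average logCPM captures the
  mean-dispersion relationship; per-gene values are squeezed toward the
  trend with a moment-matched prior df (log-scale digamma/trigamma
  matching, the same machinery used for the QL variances).
* **Fits**: the GLM fits use the *trended* dispersion. Gene-specific
  departures from the trend are deliberately left to the QL dispersion
  below. We measured both options on pure-null simulations: fitting at the
  tagwise squeezed dispersion gave empirical type-I error 0.015/0.054/0.107
  at nominal 0.01/0.05/0.10, while trend-dispersion fits gave
  0.008/0.044/0.098. For a two-group design each fit reduces to one
  intercept per group, solved by Fisher scoring on the NB score equation
  (the exported `fit_nb_glm()` runs full IRLS for arbitrary designs).
* **Test**: with \(D_g\) the full-vs-reduced deviance difference and
  \(s^2_g\) the residual deviance over its df, \(s^2_g\) is moderated by an
  inverse-chi-square prior (prior df by moment matching) and
  \(F_g = D_g / s^2_{g,\mathrm{post}}\) is referred to
  \(F(1, \mathrm{df_{resid}} + \mathrm{df_{prior}})\). Benjamini-Hochberg
  FDR is computed across tested genes; headline DEG lists use raw p
  (the analysis convention this package follows), with FDR carried in
  every output.

Genes must reach CPM ≥ 1 in at least `min(group size)` samples to be
tested; untested genes keep `NA` statistics and are excluded from BH.
Zero-deviance genes have \(s^2\) floored at `1e-8`.

## Normalization

TMM factors are computed from the definition: the reference sample is the
one whose upper-quartile count fraction is closest to the mean; each
sample's factor is the inverse-variance-weighted mean of gene-wise log2
ratios after two-sided trimming of 30% of M-values and 5% of A-values,
excluding genes zero in either sample, rescaled to geometric mean 1.
logCPM uses a library-size-scaled prior count:

\[ \mathrm{logCPM}_{gs} = \log_2\!\frac{(y_{gs} + p_s)\,10^6}{L_s + 2p_s},
\qquad p_s = 0.5\,\frac{L_s}{\bar L}, \]

with \(L_s\) the effective library size. Trim fractions and the prior are
conventional defaults; nothing in the analysed design is sensitive to them
at the second decimal.

## The compensation coefficient

For each gene the three group means of logCPM give

\[ c_g = 100 \cdot \frac{\overline{\mathrm{KM}}_g - \overline{0}_g}
                        {\overline{\mathrm{KM}}_g - \overline{W}_g}. \]

100% means the back-selected strain returned exactly to the progenitor
level; 0 means it stayed at the derived level; values above 100 are
overcompensation, at or below 0 no compensation. Classification uses
`(0, 100]` for "compensated"; the headline fraction is also reported for a
literal `(1, 100]` reading (`lower = 1`), which differs only by the
0–1% sliver. The coefficient is undefined when
\(|\overline{\mathrm{KM}} - \overline{W}| \le \varepsilon\) with
\(\varepsilon = 10^{-6}\) logCPM — a pure guard against division noise; at
any realistic effect size the denominator for a DEG is orders of magnitude
larger. The statistic is location-invariant (adding a constant to all
three means cancels), which the suite asserts numerically.

Group means are computed for **all** genes and restricted to DEGs at
analysis time, so the same table serves every threshold.

The coefficient distribution over p < 0.01 DEGs is summarized by a
Gaussian kernel density (Silverman bandwidth, grid spanning the data ±3
bandwidths, `stats::density`); degenerate all-equal inputs fall back to a
bandwidth of `1e-6` times the range (floored at `1e-6`) rather than
erroring. Concordance between the contrasts is the Spearman correlation
(average ranks) of the two logFC vectors over genes significant at
p < 0.01 in *either* contrast — the scatter in the source analysis plots
genes from both contrasts, and the union is the least arbitrary reading;
the subset rule is an explicit argument so callers can restrict it. The
opposite-direction fraction counts strict sign disagreements; exact-zero
logFCs count as non-opposite (a measure-zero event).

For the heat-map layout, DEGs are split at a coefficient cutoff (default
50%), the 50 most significant genes kept on each side, ordered from
highest p at the top to lowest at the bottom, and expression rows
Z-transformed with the sample (n−1) standard deviation; constant rows
become zeros and are flagged.

## Gene-set analysis

Over-representation uses Fisher's exact test computed by direct
hypergeometric summation. The default is two-sided by the
point-probability rule (sum of table probabilities not exceeding the
observed one) with the universe defaulting to all tested genes. The
DEG-restricted variant (`deg_gsea_lite()`) — universe = DEGs at p < 0.05,
up and down lists partitioning it — **must** use one-sided tails: the two
direction tables are complementary there, so their two-sided p-values are
mathematically identical and carry no direction information. BH is applied
across sets within each direction; per-set members are returned sorted by
decreasing logFC for display. Venn partitions of two or three DEG lists
are exact set algebra. Classical weighted running-sum GSEA is out of
scope; the set-level analysis here is the thresholded Fisher form.

## The synthetic-data generator

`simulate_counts()` emulates the study design so every downstream stage
can be validated against known truth:

| parameter | default | why |
|---|---|---|
| `n_genes` | 20000 | transcriptome-scale gene count |
| `replicates` | W=4, KM=3, ZERO=4 | the study's group sizes |
| `lib_size_range` | 15–22 million | the study's sequencing depth |
| `baseline_logmean_range` | [1, 10] (natural log) | ~4 orders of magnitude of relative abundance, typical of bulk tissue |
| `dispersion_params` | \(\phi_g = 0.05 + 1/e^{b_g}\) | BCV ≈ 0.22 asymptotically, rising at low abundance — conventional bulk values; the source data report no dispersion summaries |
| `de_fraction` | 0.10 | a minority of genes DE between derived strain and progenitor |
| `effect_size_logfc` | 2 | clear 4-fold effects; signs Rademacher since both directions occur |
| `class_proportions` | 0.7 / 0.2 / 0.1 | compensated majority with uncompensated and overcompensated minorities |

Per-gene effects: \(\beta_g\) (KM vs W, log2) has fixed magnitude and
random sign; \(\delta_g\) (ZERO vs W) is drawn per class as
\(u\beta_g, u \sim U[0, 0.3)\) (compensated — true coefficients span
(70, 100] rather than sitting at 100), \(v\beta_g, v \sim U[1, 1.5]\)
(uncompensated) or \(-w\beta_g, w \sim U(0, 0.5]\) (overcompensated).
Expected expression proportions are renormalised per sample before
scaling by library size, so DE genes induce the same mild composition
effects TMM faces in real data. Counts are NB draws (Poisson when
\(\phi = 0\)); everything is reproducible from the config seed, and a
truth table with per-gene baseline, dispersion, effects, class and true
coefficient accompanies every dataset. An optional truth override supports
controlled experiments such as exact full compensation (\(\delta = 0\)).

What the generator does **not** emulate: GC/length biases, batch effects,
correlated genes, outlier samples, or read-level artefacts. Tests passing
on this generator therefore validate the statistical machinery, not
robustness to those real-data complications.

## Problem sizes and numerical choices

The demonstration configuration (`default_pipeline_config()`) and the
analysis scripts use 2,000 genes with library sizes scaled down tenfold
(1.5–2.2 million reads): a desk-scale dataset that preserves per-gene
counts and hence the statistical regime of the full design while keeping
whole-pipeline runs in seconds. Validation experiments in the test suite
use 2,000–5,000 genes and up to 50 replicates per group where moment or
dispersion recovery needs them.

Numerical details fixed once and used everywhere: NB parameterization
\(\mathrm{var} = \mu + \phi\mu^2\); dispersion grid \([10^{-4}, 10]\), 41
points, quadratic peak interpolation clipped to the bracketing interval;
Fisher-scoring steps clamped to ±5 with all-zero groups pinned at
\(\eta = -30\); IRLS convergence at relative deviance change below
\(10^{-8}\) (100 iterations max, non-converged genes flagged);
trigamma-inverse by Newton iteration; prior df infinite when the observed
log-variance is below the expected measurement variance.

## Known limitations

* The fraction-compensated estimator is biased toward the middle at small
  replicate numbers: coefficient noise (sd ≈ 15–20 percentage points at
  n = 4 under the default dispersion) leaks boundary-hugging classes
  across the 0 and 100 boundaries, and null false positives — selected for
  large \(|\overline{\mathrm{KM}} - \overline{W}|\) while \(\overline{0}\)
  regresses to the middle — land mostly in (0, 100]. In simulations with
  true compensated fractions 0.3/0.5/0.7 the estimates centre near
  0.40/0.50/0.64. Fractions near one half are recovered accurately;
  extreme fractions are compressed. Interpreting the headline fraction
  therefore warrants replicate numbers above 4, or a bias correction that
  is out of scope here.
* The QL machinery is a self-contained rendition of the named workflow;
  it tracks edgeR closely on shared input (logFC correlation > 0.99,
  p-value rank correlation > 0.9 in the suite) but exact numerical
  agreement is a non-goal — calibration and power are the contract.
* Two-group contrasts only; multi-factor designs, robust dispersion
  options and gene-length normalization are out of scope.
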