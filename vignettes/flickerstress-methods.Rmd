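---
title: "Methods: composite stress scoring, cell-type differential expression, and flicker-reversal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite stress scoring, cell-type differential expression, and flicker-reversal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerstress)
```

`flickerstress` implements the quantitative analysis pipeline of chronic
unpredictable stress (CUS) experiments combined with audiovisual (AV) flicker
neurostimulation at 10/20/40 Hz: behavioral phenotyping by a composite
z-score, cell-type bulk RNA-seq differential expression, the
"modifiable marker" reversal statistic, gene-set enrichment, and 3D
morphometry of neurons and glia. This vignette records the statistical models,
the defaults and why they were chosen, and the numerical decisions a
maintainer would otherwise have to reverse-engineer.

## Composite stress-susceptibility score

Each behavioral assay value $X_{\mathrm{exp}}$ is standardized against the
sex-matched stress-naive control group:

$$Z = \frac{X_{\mathrm{exp}} - \mu_{\mathrm{ctrl}}}{\sigma_{\mathrm{exp}}}$$

where $\mu_{\mathrm{ctrl}}$ is the control mean and $\sigma_{\mathrm{exp}}$
the sample SD (n−1) of the animal's *own experimental group*. The
experimental-group denominator is deliberate — it standardizes the deviation
from control by within-group variability — and `build_reference(...,
sigma_source = "control")` exposes the conventional control-SD variant, since
the two differ and the choice materially affects small groups.

Every assay carries an orientation sign (`default_assay_directions()`) so
that higher oriented z always means more resilient: stress lowers body
weight, sucrose consumption, open-arm time, center time and discrimination
indices (+1), and raises forced-swim immobility and locomotor distance (−1).
The composite is the unweighted mean of oriented z-scores over the assays
actually measured (equal weights; a sum would confound missingness with
magnitude, so missing assays reduce `n_assays_used` instead). Locomotion is
included by default with orientation −1 but is excludable by passing an
edited direction table, because it doubles as a confound screen. Females are
scored on an additional social-interaction discrimination index in place of
the novel-object index used for males.

A small-sample caveat worth knowing: with $n$ animals per group,
$E[1/S] > 1/\sigma$ (about 1.13 at $n = 8$), so group-mean composites
computed with the experimental-group SD overshoot the true shift by roughly
12–13% at the study-scale group size. Parameter-recovery checks in this
package therefore use cohorts of 200 animals per group, where the inflation
is ~0.4% and Monte-Carlo error is small; the estimator itself is exactly the
one defined above.

## Differential expression

Analysis runs separately per cell type (neurons, astrocytes, microglia) and
sex. Pre-filters: a gene is dropped when fewer than 50 raw counts are seen in
at least 75% of samples (the 75% boundary is inclusive — exactly 3 of 4 low
samples excludes) or when its biotype is not protein-coding.

Normalization is median-of-ratios: sample $j$'s size factor is the median
over all-positive genes of $c_{gj} / (\prod_j c_{gj})^{1/m}$, rescaled to
geometric mean 1 (the rescaling cancels in any contrast). A
pseudo-reference fallback over zero-containing genes is available by flag for
sparse matrices.

Per gene, a negative-binomial model with log link and log size-factor
offsets is fitted to one two-level contrast — stress vs control among
unstimulated animals, or one flicker frequency vs no-stim within stressed
animals. The dispersion $\alpha$ is a per-gene method-of-moments estimate on
normalized counts ($\mathrm{Var}(y/s) = \mu \overline{1/s} + \alpha\mu^2$),
pooled within groups and floored at $10^{-8}$; there is no empirical-Bayes
shrinkage, no outlier handling, no independent filtering and no fold-change
shrinkage. Group means are profiled by Newton iteration on the NB score
equation and the Wald statistic is $\log_2\!\mathrm{FC} / \mathrm{SE}$ with
the SE from expected Fisher information.

**Reference distribution.** The Wald statistic is referred to Student t with
residual degrees of freedom ($N - 2$), not the standard normal. With 3
samples per group the dispersion is estimated from 4 residual df; plugging
such a noisy estimate into a normal-reference Wald test is markedly
anticonservative (empirically ~0.125 at nominal 0.05 on a 20,000-gene null),
while the t reference restores the nominal level (~0.05) and converges to
the normal reference as $n$ grows. This mirrors quasi-likelihood practice
for small-replicate RNA-seq.

DEGs are genes with $|\log_2\mathrm{FC}| \ge 1$ (inclusive — the boundary
value 1.0 counts) and unadjusted Wald $p < 0.05$. BH-adjusted p-values are
reported but not used for calling, matching the convention of reporting raw
Wald significance for these contrasts. `call_degs()` is a pure function of
the result table, so re-thresholding is idempotent.

## Modifiable markers

A gene is a *modifiable marker* for a flicker contrast when it is a DEG in
both the stress contrast and the flicker contrast with opposite-signed fold
changes (up under stress, down under flicker, or vice versa). Sign only is
compared, never magnitude, and the strict both-contrasts-DEG reading is
used. A gene significant in both contrasts with the *same* sign counts as
non-modifiable but stays in the denominators.

Two percentages are reported because both denominators are in common use:

* `percent_modifiable` = 100 x modifiable / flicker-contrast DEGs (the
  frequency-specific formula);
* `percent_of_stress_degs` = 100 x modifiable / stress-contrast DEGs (the
  share of stress DEGs normalized by flicker).

For recovery of a *planted* reversal fraction the second quantity is the
estimator: in the synthetic generator the only flicker effect is the
reversal itself, so essentially every flicker-contrast DEG is a reversed
gene and the first percentage sits near 100 regardless of the planted
fraction, whereas modifiable/stress-DEGs estimates it directly. Both numbers
are returned rounded and at full precision. `overlap_sets()` provides the
exact Venn algebra used for cross-frequency comparisons, and
`direction_fractions()` the up/down split (exact rationals summing to 100).

## Enrichment

`fisher_overrepresentation()` is the one-sided (upper-tail) hypergeometric
test of a DEG list against gene sets, with the post-filter gene universe as
background. A DEG absent from the background is an error, not a silent drop
— in practice that is always an identifier mismatch. BH FDR across terms is
applied when requested; the convention supported here is FDR-adjusted for
flicker-vs-stress contrasts and unadjusted for stress-vs-control (chosen for
inclusiveness in that screen). Identifier handling is exact match after
whitespace stripping; no symbol aliasing.

`gsva_scores()` is a deliberately simplified single-sample enrichment score:
per sample, genes are ranked by expression, set members add $1/n_{set}$ and
non-members subtract $1/(N - n_{set})$ along the ranking, and the score is
the signed maximum deviation of that walk, in $[-1, 1]$. It is rank-based and
hence invariant to monotone transforms of a sample's expression. It is *not*
the kernel-CDF pipeline of the published GSVA package; it supports the same
qualitative per-sample trend reading at a fraction of the machinery.

## Morphometry

Skeletons are standard 7-column SWC in micrometres, validated to be
single-rooted trees. Sholl crossings are computed *exactly*: each
parent-child segment is intersected with the sphere of radius $r$ centred on
the soma by solving the quadratic $|P_0 + t(P_1 - P_0)|^2 = r^2$; roots with
$t \in (0, 1]$ count, so a node lying exactly on a sphere is counted once
(on its incoming edge) and a tangent touch (zero discriminant) counts once.
Default radii are 5 um steps to the maximal radial extent with 10 and 20 um
always included, the two distances conventionally reported for microglia.
Arborization is the sum of Euclidean edge lengths; the convex hull is
computed over all node coordinates (no resampling) by an incremental 3D hull
with a relative tolerance of $10^{-10}$ on visibility tests, and
coplanar/collinear point sets return volume 0 with a `degenerate` flag
rather than an error.

Spines are classified from (length, head diameter, neck width) by a
precedence-ordered rule table — mushroom (head >= 0.6 um and head/neck >=
1.1), filopodia (length >= 2 um and head/neck < 1.1), stubby (length/neck <=
1), long thin otherwise. The published analyses used a proprietary
machine-learning classifier whose thresholds are not public; these defaults
follow common literature conventions and every threshold is exposed in
`default_spine_rules()`, because reproducibility demands explicit numbers.
Mushroom + stubby are the mature/stable classes. Spine density is spines per
micron of segment. Group-level statistics aggregate across cells/segments
within a group, not per animal, matching how such morphology data are
typically pooled.

## Inferential battery

`one_way_anova()` (classical F), `two_way_anova()` (Type II sums of squares,
equal to Type I/III on balanced designs; the interaction is the headline
result), `kruskal_wallis()` (tie-corrected H) and `posthoc_pairwise()` with
the three procedures used downstream: pooled-variance t with Bonferroni,
Dunn's rank z with tie correction (Bonferroni-adjusted by default,
configurable), and uncorrected Fisher's LSD. Normality is never auto-tested;
the caller chooses the parametric or rank test to avoid silent branching.
Degenerate inputs (all values tied, zero within-group variance) raise typed
errors rather than returning NaN.

## Synthetic data: what it emulates, and what it does not

The generator plants known, recoverable structure under one fixed seed
(byte-identical outputs):

* **Behavior** — per-assay unit-SD Gaussians around nominal baselines;
  group effects are specified in control-SD units on the *oriented* scale,
  so a planted −4 means four SDs toward susceptibility whatever the assay's
  native direction. Defaults mirror the study conditions: five groups
  (control, stress, stress+10/20/40 Hz), both sexes, a −4 SD stress effect
  in males and −1 in females, strongest rescue at 10 Hz in males and 40 Hz
  in females, 8 animals per group.
* **Counts** — NB($\mu s_j$, $\alpha$) draws for 3 samples per sex and
  condition (the study's pooled-pair layout; pooling itself is not
  simulated — samples are independent), log-normal true size factors
  (sdlog 0.15), a planted stress-responsive gene fraction with
  ±`planted_lfc` shifts in all stressed groups, and per-frequency reversal:
  a configured fraction of planted genes returns to the control mean in the
  matching stress+flicker group (`reversal_strength < 1` gives partial
  reversal). Non-coding genes (10% by default) are never planted, so the
  biotype filter is exercised.
* **Morphology** — star/tree skeletons (straight or kinked processes) and
  spine triples drawn from truncated normals centred inside the default
  classifier's decision regions, with the true class recorded.

What it does **not** emulate: assay-specific distributions (everything is
Gaussian on the raw scale), between-animal correlation across assays,
library-size-dependent mean-dispersion trends, batch effects, subject-level
pooling correlation, or realistic neuronal branching statistics. Passing the
recovery tests therefore demonstrates that the estimators recover what was
planted under the stated noise model — not that the pipeline is robust to
every artefact of real colony data.

## Problem sizes and reproducibility

The default seed is 20250712 and every generator accepts a seed. The
acceptance script (`scripts/acceptance.R`) recomputes, from scratch at a
user-supplied seed: composite recovery (200 animals/group), DE type-I error
(5,000-gene null, 3 vs 3), fold-change recovery (2,000 genes, 15% planted at
±2), end-to-end reversal recovery (30% planted), Sholl and hull agreement
against brute-force oracles (100 random trees / point sets), exhaustive
hypergeometric agreement for all background sizes ≤ 30, and affine
invariance of the composite. These sizes keep Monte-Carlo error well inside
the assertion bands while the whole battery runs in about two minutes on one
CPU.

## Known limitations

* The NB test is a desk-scale two-group engine: no multi-factor designs, no
  dispersion moderation, and no claim of numerical parity with any DESeq2
  release (one test cross-checks fold changes against DESeq2 on a strong
  signal fixture, where they agree closely).
* The spine rule table is a declared convention, not an inferred model of
  the proprietary classifier it replaces.
* The composite score inherits the small-n inflation of its published
  definition (experimental-group SD in the denominator), documented above.
* The single-sample enrichment score is a simplified KS walk, suitable for
  qualitative trends only.
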