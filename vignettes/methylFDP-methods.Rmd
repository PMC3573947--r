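---
title: "Methods: exact per-CpG testing and permutation FDP control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact per-CpG testing and permutation FDP control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylFDP)
```

## The problem

A small rare-disease methylation study compares a handful of mutation
carriers against a few dozen controls on a beta-value array (here modelled
on the 27K design: ~24,000 retained CpG probes after filtering, 10 cases
from 5 families, 19 controls of whom 3 are unaffected relatives, plus 2
carriers of a variant of unknown significance). Two statistical
difficulties dominate at this scale. First, per-probe parametric tests are
unreliable for n = 10 vs 19 with bounded, skewed beta values; the package
therefore uses the exact Mann–Whitney U test throughout. Second, with
~24,000 simultaneous discrete tests whose p-values have an attainable
floor, familiar FDR machinery is poorly matched to the question "which
probes can we report with essentially no false positives?"; the package
answers it with a permutation procedure that controls the false discovery
proportion (FDP) at a limit γ with confidence 1 − α.

## The per-probe scan

For each probe, the two-sided Mann–Whitney p-value between cases and
controls is computed exactly whenever the smaller group has at most 25
observations and the pooled values contain no ties: the null distribution
of U is built by the count recurrence
c(u; n, m) = c(u − m; n − 1, m) + c(u; n, m − 1), and the two-sided p is
twice the smaller tail, capped at 1. Counts stay exact in doubles up to
C(n+m, n) < 2^53, far beyond any design this package targets. With ties,
or larger groups, a tie-corrected normal approximation (no continuity
correction by default) takes over. Exact mode must be the default for the
10-vs-19 design because the reportable floor — complete separation —
equals 2/C(29,10) = 9.985e-08, and any approximation distorts exactly the
tail that matters.

Effect sizes accompany each p-value: delta beta = mean(case) −
mean(control) (arithmetic means; negative = loss of methylation in cases),
and delta Z, defined here as the difference of group means after
z-standardizing the probe's case+control values — equivalently
(mean(control) − mean(case)) / sd(pooled) — so it is positive for loss.
This definition reproduces the familiar magnitude of ≈1.8–2.0 for a
completely separated 10-vs-19 split. Samples labelled `vus` are excluded
from all testing but their group mean is carried in the output, since the
scientific question for such samples is whether they track the controls.

Missing betas are dropped pairwise per probe; a probe left with fewer than
two values in either group is flagged `testable = FALSE` rather than
silently removed, so the output always has one row per input probe.

## The permutation FDP procedure

`build_null()` permutes the case/control labels among the case+control
samples only (vus samples never enter the null), preserving the 10/19
sizes, and recomputes every probe's p-value per permutation; each
permutation's p-vector is stored sorted ascending. Sampling mode draws B
label assignments uniformly at random under a seed; the observed labelling
is not counted among the B. Exhaustive mode enumerates every distinct
assignment exactly once (the observed one included by construction) and is
therefore seed-invariant; a sampling request with B at or above the number
of distinct assignments is switched to exhaustive with a warning — at that
point sampling with replacement cannot cover the space, and the switch
makes "sampling with B = all assignments" coincide exactly with the
enumerated null.

For γ = 0 the cutoff is the ⌈αB⌉-th smallest of the per-permutation
minimum ("best") p-values; probes with observed p strictly below it are
declared significant. The guarantee is direct: under the complete null,
the chance that any probe beats the cutoff is at most α, so with
confidence 1 − α the declared set contains no false positive. The strict
inequality at the cutoff is deliberate (conservative, and consistent with
reporting "p < cutoff"). The order-statistic convention ⌈αB⌉, rather than
interpolation, keeps the rule exact and reproducible at small B; it also
fixes the minimum feasible α at 1/B, and `fdp_cutoff()` refuses smaller α
naming that bound.

For γ > 0 the stepwise rank-substitution generalization applies: find the
largest s such that the s-th smallest observed p lies strictly below the
⌈αB⌉-th smallest of the per-permutation (⌊γs⌋+1)-th order statistics, and
declare the top s probes. With γ = 0 the substituted order statistic is
always the minimum, so the rule reduces exactly to the percentile rule
above. Counts are monotone nondecreasing in both α and γ by construction,
which the test suite checks as a property.

## Family-aware robustness

With familial cases, any single strong family could drive the discovery
set. `subset_robustness()` enumerates the Cartesian product of (one case
per family) × (one relative-slot control), runs the scan per combination,
and intersects the significant sets. With family sizes (3, 2, 2, 2, 1) and
3 eligible relatives this yields 3·2·2·2·1·3 = 72 combinations of 5 cases
vs 17 controls. Both interpretations of the relative slot — enumerate the
choice, or fix one random relative — are supported, since enumeration with
one relative choice degenerates to the fixed case.

## Structure: clustering and ordination

`hclust_cosine_complete()` clusters samples by complete-linkage
agglomeration of cosine distances d = 1 − x·y/(‖x‖‖y‖) on raw beta values
(the natural choice when the visual reference is a beta-scaled heatmap).
Samples are sorted lexicographically before clustering so tied merges
resolve deterministically. `pca_median_knn()` imputes missing values from
the 10 nearest probes (Euclidean over shared samples, neighbours are
probes — the transcriptomics convention; a sample-wise mode is a matter of
transposing the input), centres each probe at its median, and projects
samples onto principal components with the sign of each component fixed by
its largest-magnitude loading. K-means and k-medians sit behind the same
`cluster_samples()` interface with a fixed seed and default k = 2.

## Island asymmetry and global shifts

`direction_tally()` crosses the island flag with the direction of
delta beta among significant probes (zeros excluded and counted
separately); `asymmetry_test()` applies Fisher's exact test to the 2×2
table, or the exact binomial sign test to a single loss/gain tally — 53
losses and 0 gains give the closed form 2·2⁻⁵³ ≈ 2.22e-16.
`mean_methylation_compare()` averages probes per sample within island and
non-island strata and compares groups per stratum by Mann–Whitney; a
handful of strong island spikes produces the characteristic dilution-scale
(<1%) island-restricted global loss (50 spikes of 0.4 among ~12,000 island
probes shift the island mean by ≈ 50·0.4/12,000 ≈ 0.0017). The stratum
test is Mann–Whitney by assumption; the package records this as a design
choice since a global mean comparison admits several reasonable tests.

## Cohort comparisons

Sex scans use the same Mann–Whitney machinery per probe with
Benjamini–Hochberg q-values (`p.adjust(method = "BH")`); BH is the
package's interpretation of "q-value" and is documented as such.
`dosage_trend()` reports the Spearman correlation between per-sample
methylation and effective demethylase dose plus a Jonckheere–Terpstra
trend test whose p-value is a seeded permutation tail. Effective dose is
kdm5c_copies + w·kdm5d_copies with w ∈ (0,1) configurable and 0.5 by
default: the Y-linked homologue contributes, but not enough to compensate
for a missing KDM5C copy, and every w in (0,1) preserves the ordering
properties. Female mutation carriers with skewed X-inactivation are
encoded with one functional KDM5C copy. The outlier screen flags a query
sample at a probe when its beta falls below the reference minimum minus a
margin (default 0), with a robust alternative (median − 5·MAD); the strict
minimum rule necessarily lets the single boundary sample of the reference
flag itself in a leave-one-out screen, so the MAD rule is the one with a
clean self-consistency property, and the rule name is recorded in the
output.

## The synthetic cohort generator

The generator is first-class, tested code: it produces the statistical
structure the analysis assumes, with ground truth, so every downstream
stage is verifiable without any external download.

- **Baselines.** Probe baselines are logit-normal and bimodal: island
  probes centre near beta 0.2 (sd 1.2 on the logit scale), non-island
  probes near 0.8 (sd 0.9) — the familiar island-low / non-island-high
  27K pattern.
- **Spikes.** `n_spiked` island probes receive a case-specific loss
  `spike_delta` (the generator models loss only, matching the discovery
  setting); they are drawn from island probes whose baseline leaves room
  for the loss (baseline + spike_delta ≥ 0.02). In very small fixtures
  with too few eligible island probes, the chosen probes' baselines are
  redrawn from the island distribution truncated to the eligible range, so
  the feasibility invariant always holds.
- **Noise.** Per-observation noise is logit-normal (dispersion 0.25 by
  default, giving per-probe beta-scale sds of roughly 0.04–0.06 at
  intermediate baselines — the scale of between-individual blood
  variation), with a second-order mean correction so each cell's expected
  beta equals its target; spiked-probe delta-beta estimates are unbiased
  to well within ±0.02.
- **Latent structure.** Four label-independent latent factors, each
  loading on a random 30% of non-spiked probes (loadings N(0,1), logit
  scale 0.8), model inter-individual variation — age, genotype, cell
  composition. This is the feature that makes genome-wide ordination
  uninformative about case status in real cohorts: without it, even 50
  spikes among 24,000 probes form a detectable principal component in
  clean i.i.d. noise, which real data do not show. Spiked probes carry
  measurement noise only: they model loci tightly controlled by
  demethylase dose, which is also what makes complete case/control
  separation at top loci attainable, as observed in this design's
  reference study. Consequently, passing structure tests demonstrate the
  contrast between targeted and genome-wide views under these assumptions;
  they do not show robustness to batch effects or cell-composition
  confounding, which the generator deliberately does not simulate.
- **Intensities.** Total signal S is log-normal around `intensity_scale`;
  M = β(S+100), U = (1−β)(S+100) − 100, so the beta formula inverts
  exactly wherever U ≥ 0 (essentially everywhere at realistic S), and the
  preprocessing path is exercised nontrivially. Detection p-values are
  near 0 except for a `detection_fail_rate` fraction drawn uniform on
  [0,1].
- **Families.** Cases carry family labels (default sizes 3, 2, 2, 2, 1);
  an optional shared per-family logit intercept exists but defaults to
  off, since the reference design treats relatedness by subset enumeration
  rather than by a variance component.

The dosage generator produces a seven-group karyotype design
(47,XXX; 47,XXY; 46,XX; 46,XY; 45,X; carrier; mutation male — sample
counts 3/3/16/19/11/4/10) with a saturating dose response
base + gain·d/(d + d₀). Defaults (base 0.35, gain 0.5, d₀ = 2, noise sd
0.03) are set by an identifiability calculation: the smallest adjacent
group-mean gap among distinct doses (≈0.022, between 47,XXY and 47,XXX)
is about 2.5 times the largest group-mean standard error (≈0.017 for the
n = 3 groups), so the generating ordering is recoverable in a typical
draw, while the 45,X and carrier groups share a dose and may land in
either order — mirroring a design in which groups missing a functional
copy separate strongly and high-dose groups differ subtly.

## Numerical choices and degenerate inputs

- Exact-U counts are cached per group-size pair; the permutation null
  evaluates all permutations in one rank-matrix multiplication, with tied
  probes routed through a precomputed tie-corrected variance.
- All-tied probes give p = 1 (zero-variance guard), delta Z = 0.
- Beta of exactly 1 is unreachable from intensities (the +100 offset);
  imported external matrices may contain 1.0 and are accepted as-is.
- The detection-p probe filter defaults to excluding a probe failing in
  any sample (whole-probe removal before testing); a masking mode NAs
  individual observations instead and removes only probes failing
  everywhere. Exclusion lists may overlap, so the filter report always
  states the union explicitly rather than assuming disjointness.
- `fdp_cutoff` refuses α < 1/B naming the minimum feasible α; the
  pipeline driver drops unresolvable α levels with a warning.
- Cosine distance is undefined for zero-norm vectors (error), clamped to
  [0, 2] against rounding.

## Problem sizes used in the test suite

Simulation-backed checks run at 2,000 probes for calibration properties
(200 replicate null cohorts for the FDP confidence bound; 20 seeds for
spike recovery at B = 1000) and at the full 24,000-probe scale for the
single structure contrast (clustering on spiked probes vs PCA on all
probes). These sizes give stable Monte-Carlo margins for every asserted
bound while keeping a full run inside a few minutes; all statistical
behaviour checked is scale-free in the probe count except where the spike
fraction matters, and there the array-scale fraction (50/24,000) is used.

## Known limitations

- The permutation null assumes exchangeability of samples under the null;
  family structure is addressed by enumeration, not by a clustered
  permutation scheme.
- The generator does not simulate batch effects, cell-type composition,
  age trends, or array-segment artefacts; conclusions from passing tests
  are about the statistical machinery, not about robustness to those
  real-data complications.
- The γ > 0 FDP rule is the standard stepwise construction consistent with
  the γ = 0 percentile rule; other generalizations exist and would differ
  in edge cases at very small B.
- Covariate-adjusted models, paired designs and region-level statistics
  are out of scope.
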