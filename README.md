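# methylFDP

Differential DNA-methylation discovery for small two-group array studies,
with exact nonparametric per-probe testing and permutation-based control of
the false discovery proportion (FDP).

The package targets the kind of design that is common in rare-disease
epigenomics: a handful of mutation carriers (here, males carrying loss-of-
function mutations in the X-linked H3K4 demethylase gene *KDM5C*) against a
few dozen controls, profiled on an Illumina 27K-style beta-value array.
At these sample sizes parametric per-probe tests are fragile and
Benjamini–Hochberg control of the FDR in expectation is loose; the methods
here instead use:

- the **exact Mann–Whitney U test** per CpG probe, two-sided, computed from
  the full null distribution of U (the count recurrence), so the attainable
  p-value floor is known exactly — for complete separation of 10 cases vs
  19 controls it is `2 / C(29,10) = 9.985e-08`;
- a **multivariate permutation procedure**: group labels are permuted
  (preserving 10 vs 19), all probe p-values are recomputed per permutation
  and sorted, and the distribution of the per-permutation "best" (smallest)
  p-value calibrates a cutoff such that, with confidence `1 − α`, the set
  of probes below the cutoff contains no false positive (FDP limit
  `γ = 0`); a stepwise rank-substitution rule generalises this to `γ > 0`;
- effect sizes as **delta beta** (case mean − control mean; negative =
  methylation loss) and **delta Z** (standardized group separation,
  positive for loss).

Around that core the package implements the full study workflow: beta
computation `Max(M,0)/(Max(M,0)+Max(U,0)+100)` from intensity pairs, sample
QC gates and probe filtering (detection p-value, cross-reactive and
SNP-overlapping probes), family-aware subset-robustness enumeration,
complete-linkage/cosine-distance clustering and median-centred
kNN-imputed PCA, CpG-island loss/gain asymmetry tests, sex-difference
scans with BH q-values, sex-chromosome-dosage trend tests
(Spearman + Jonckheere–Terpstra), a population-reference outlier screen,
and a synthetic cohort generator that emulates the whole design with known
ground truth.

## Worked example

```r
library(methylFDP)

sim <- simulate_cohort(cohort_config(n_probes = 2000, n_spiked = 50,
                                     spike_delta = -0.4, seed = 7))
fit <- methyl_diff(sim$beta, sim$sheet, B = 1000, seed = 7,
                   annotation = sim$annotation)
fit
```

```
Differential methylation fit (Mann-Whitney scan + permutation FDP)
  2000 probes, 10 cases vs 19 controls, 1000 permutations
Significant probe counts (rows = FDP limit, cols = alpha):
           alpha_0.005 alpha_0.01 alpha_0.05
gamma_0             50         50         50
gamma_0.05          50         50         52
gamma_0.1           50         51         53
gamma_0.2           51         51         53
```

All 50 spiked probes — and nothing else — are declared significant at
FDP = 0 with 99.5% confidence. The summary shows the calibrated cutoff and
the per-probe table:

```r
summary(fit, gamma = 0, alpha = 0.005, n_top = 3)
```

```
FDP <= 0 with confidence 99.5%: 50 significant probes (p < 1.39E-05)
  direction: 50 loss / 0 gain
Top probes by methylation loss:
   probe_id n_case n_control mean_case mean_control mean_vus  p_value
 cg00001109     10        19    0.0654        0.502    0.518 9.99E-08
 cg00001826     10        19    0.0821        0.514    0.516 9.99E-08
 cg00001228     10        19    0.4622        0.893    0.862 9.99E-08
 delta_beta delta_z testable gene_symbol distance_to_tss cpg_island
     -0.436    2.03     TRUE   GENE01109            -881       TRUE
     -0.432    2.03     TRUE   GENE01826           -1255       TRUE
     -0.430    2.01     TRUE   GENE01228           -1413       TRUE
```

Each significant probe sits at the exact Mann–Whitney floor
(`9.985e-08`, printed `9.99E-08`): the ten case values lie entirely below
the nineteen control values. `delta_z` around 2 is the typical
standardized separation at complete separation of this design. The
`mean_vus` column tracks the two variant-of-unknown-significance samples,
which are excluded from the test; with a benign variant their means follow
the controls, as seen above. `plot(fit)` draws the volcano
(delta beta vs −log10 p) with the calibrated cutoffs;
`run_pipeline(list(seed = 7, simulate = list(...)))` executes the full
simulate/QC/filter/scan/FDP/cluster/asymmetry/dosage chain and returns a
JSON-ready report.

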