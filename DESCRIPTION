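Package: methylFDP
Title: Differential DNA Methylation Discovery with Permutation False
    Discovery Proportion Control
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-group differential DNA-methylation analysis on
    Illumina-style beta-value matrices: beta computation from
    methylated/unmethylated intensity pairs, sample quality control and
    probe filtering (detection p-value, cross-reactive and SNP-overlapping
    probes), an exact nonparametric Mann-Whitney per-CpG scan with effect
    sizes, a multivariate permutation procedure controlling the false
    discovery proportion at a chosen confidence level, family-aware
    subset-robustness enumeration, cosine-distance hierarchical clustering
    and median-centred kNN-imputed principal component analysis,
    CpG-island loss/gain asymmetry tests, sex and sex-chromosome-dosage
    comparisons, a population-reference outlier screen, and a synthetic
    cohort generator emulating a small case/control X-linked intellectual
    disability study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    cluster,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
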