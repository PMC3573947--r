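#' Configuration for the synthetic case/control methylation cohort
#'
#' Builds and validates the configuration of \code{\link{simulate_cohort}}.
#' Defaults emulate the study design the package was validated against:
#' 10 affected males from 5 families (sizes 3, 2, 2, 2, 1), 19 controls of
#' whom 3 are unaffected relatives eligible for the family-control slot,
#' and 2 carriers of a variant of unknown significance (VUS), profiled on a
#' 27K-style array. Spiked probes model case-specific loss of methylation
#' concentrated at CpG-island probes.
#'
#' @param n_probes Number of probes.
#' @param n_cases,n_controls,n_vus Sample counts per group.
#' @param family_sizes Integer vector of cases per family; must sum to
#'   \code{n_cases}.
#' @param n_relative_controls Number of controls flagged as unaffected
#'   relatives (the \code{relative_pool} of \code{\link{subset_robustness}}).
#' @param frac_island Fraction of probes flagged as CpG-island probes.
#' @param n_spiked Number of probes given a case-specific methylation shift.
#' @param spike_delta Expected case-minus-control beta shift at spiked
#'   probes; must be in [-1, 0] (the generator models loss only).
#' @param baseline_dispersion Standard deviation of the per-observation
#'   logit-normal noise around the probe baseline.
#' @param family_effect_sd Standard deviation of an optional shared logit
#'   intercept per case family; default 0 (off).
#' @param n_latent Number of label-independent latent factors modelling
#'   inter-individual variation (age, genotype, cell composition); these
#'   dominate genome-wide ordination in real cohorts.
#' @param latent_sd Logit-scale standard deviation of the latent-factor
#'   contribution at a loaded probe.
#' @param latent_frac Fraction of probes each factor loads on. Factors
#'   load only on non-spiked probes: the spiked targets are modelled as
#'   tightly dose-controlled loci carrying measurement noise only.
#' @param intensity_scale Median total fluorescence per probe observation.
#' @param detection_fail_rate Fraction of observations whose detection
#'   p-value is drawn uniform on [0, 1] instead of near 0.
#' @param frac_cross_reactive,frac_snp Fractions of probes flagged
#'   cross-reactive / SNP-overlapping in the annotation.
#' @param seed Integer seed; the output is a pure function of the config.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_probes = 24000L,
                          n_cases = 10L,
                          n_controls = 19L,
                          n_vus = 2L,
                          family_sizes = c(3L, 2L, 2L, 2L, 1L),
                          n_relative_controls = 3L,
                          frac_island = 0.5,
                          n_spiked = 50L,
                          spike_delta = -0.4,
                          baseline_dispersion = 0.25,
                          family_effect_sd = 0,
                          n_latent = 4L,
                          latent_sd = 0.8,
                          latent_frac = 0.3,
                          intensity_scale = 10000,
                          detection_fail_rate = 0.002,
                          frac_cross_reactive = 0.1,
                          frac_snp = 0.03,
                          seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls), n_vus = as.integer(n_vus),
              family_sizes = as.integer(family_sizes),
              n_relative_controls = as.integer(n_relative_controls),
              frac_island = frac_island, n_spiked = as.integer(n_spiked),
              spike_delta = spike_delta,
              baseline_dispersion = baseline_dispersion,
              family_effect_sd = family_effect_sd,
              n_latent = as.integer(n_latent), latent_sd = latent_sd,
              latent_frac = latent_frac,
              intensity_scale = intensity_scale,
              detection_fail_rate = detection_fail_rate,
              frac_cross_reactive = frac_cross_reactive,
              frac_snp = frac_snp, seed = as.integer(seed))
  if (sum(cfg$family_sizes) != cfg$n_cases)
    stop("cohort_config: family_sizes must sum to n_cases")
  if (cfg$n_spiked > cfg$n_probes)
    stop("cohort_config: n_spiked exceeds n_probes")
  if (cfg$spike_delta > 0)
    stop("cohort_config: spike_delta must be <= 0 (loss-only generator)")
  if (cfg$spike_delta < -1)
    stop("cohort_config: spike_delta must be >= -1")
  if (cfg$n_relative_controls > cfg$n_controls)
    stop("cohort_config: n_relative_controls exceeds n_controls")
  if (cfg$baseline_dispersion <= 0)
    stop("cohort_config: baseline_dispersion must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate an intensity-level case/control methylation cohort
#'
#' Generates methylated/unmethylated intensity pairs with per-observation
#' detection p-values, a sample sheet, a probe annotation table and a
#' ground-truth table. Probe baselines are bimodal: island probes skew
#' low/intermediate, non-island probes skew high. Case samples at spiked
#' probes have expected beta \code{baseline + spike_delta}; per-observation
#' noise is logit-normal around the target mean so all betas stay in (0, 1).
#' Intensities are synthesised so that
#' \code{Max(M,0)/(Max(M,0)+Max(U,0)+100)} recovers the simulated beta
#' whenever the unmethylated signal is nonnegative.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A list with elements \code{intensities} (list of matrices
#'   \code{M}, \code{U}, \code{detection_p}, plus
#'   \code{bisulfite_control} per sample), \code{beta} (the noiseless-free
#'   observed beta matrix, probes x samples), \code{sheet} (sample sheet
#'   data frame), \code{annotation} (probe annotation data frame) and
#'   \code{truth} (probe_id, is_spiked, true_delta).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  K <- config$n_probes
  probe_id <- sprintf("cg%08d", seq_len(K))

  n_total <- config$n_cases + config$n_controls + config$n_vus
  sheet <- .cohort_sheet(config)

  island <- rep(FALSE, K)
  island[seq_len(round(config$frac_island * K))] <- TRUE
  island <- sample(island)
  # bimodal baselines on the logit scale
  base_logit <- ifelse(island, stats::rnorm(K, qlogis(0.2), 1.2),
                       stats::rnorm(K, qlogis(0.8), 0.9))
  baseline <- stats::plogis(base_logit)

  # spikes sit at island probes with baseline high enough that the loss
  # stays in [0,1]; prefer already-eligible probes, otherwise redraw the
  # chosen probes' baselines from the island distribution truncated to the
  # eligible range
  min_base <- 0.02 - config$spike_delta
  eligible <- which(island & baseline >= min_base)
  spiked <- integer(0)
  if (config$n_spiked > 0L) {
    if (length(eligible) >= config$n_spiked) {
      spiked <- sort(sample(eligible, config$n_spiked))
    } else {
      isl_idx <- which(island)
      if (length(isl_idx) < config$n_spiked)
        stop("simulate_cohort: fewer island probes than n_spiked")
      spiked <- sort(sample(isl_idx, config$n_spiked))
      lift <- spiked[baseline[spiked] < min_base]
      p_lo <- stats::pnorm(stats::qlogis(min_base), qlogis(0.2), 1.2)
      baseline[lift] <- stats::plogis(stats::qnorm(
        stats::runif(length(lift), p_lo, 1), qlogis(0.2), 1.2))
    }
  }
  is_spiked <- seq_len(K) %in% spiked

  # target mean per probe x sample (cases shifted at spiked probes)
  mu <- matrix(baseline, nrow = K, ncol = n_total)
  case_cols <- which(sheet$group == "case")
  mu[spiked, case_cols] <- mu[spiked, case_cols] + config$spike_delta

  eta <- qlogis(pmin(pmax(mu, 1e-6), 1 - 1e-6))
  # label-independent latent factors: shared inter-individual variation at
  # a random subset of non-spiked probes per factor; these, not the disease
  # signal, carry the leading genome-wide principal components
  if (config$n_latent > 0 && config$latent_sd > 0) {
    loadable <- setdiff(seq_len(K), spiked)
    loadings <- matrix(0, K, config$n_latent)
    for (f in seq_len(config$n_latent)) {
      hit <- sample(loadable, round(config$latent_frac * length(loadable)))
      loadings[hit, f] <- stats::rnorm(length(hit))
    }
    scores <- matrix(stats::rnorm(n_total * config$n_latent),
                     nrow = config$n_latent)
    eta <- eta + config$latent_sd * (loadings %*% scores)
  }
  if (config$family_effect_sd > 0) {
    fams <- unique(sheet$family_id[case_cols])
    fx <- stats::rnorm(length(fams), 0, config$family_effect_sd)
    names(fx) <- fams
    for (j in case_cols)
      eta[, j] <- eta[, j] + fx[[sheet$family_id[j]]]
  }
  beta <- stats::plogis(eta + matrix(stats::rnorm(K * n_total, 0,
                                                  config$baseline_dispersion),
                                     nrow = K))
  # second-order correction for the logit-normal mean bias, so per-cell
  # E[beta] stays at mu: E[plogis(eta + e)] ~ mu + s^2/2 * mu(1-mu)(1-2mu)
  bias <- config$baseline_dispersion^2 / 2 * mu * (1 - mu) * (1 - 2 * mu)
  beta <- beta - bias
  beta <- pmin(pmax(beta, 0), 1 - 1e-9)
  dimnames(beta) <- list(probe_id, sheet$sample_id)

  # intensities: total signal lognormal around intensity_scale; exact
  # inversion M = beta*(S+100), U = (1-beta)*(S+100) - 100
  S <- matrix(stats::rlnorm(K * n_total, log(config$intensity_scale), 0.3),
              nrow = K)
  M <- beta * (S + 100)
  U <- (1 - beta) * (S + 100) - 100
  dimnames(M) <- dimnames(U) <- dimnames(beta)

  fail <- matrix(stats::runif(K * n_total) < config$detection_fail_rate,
                 nrow = K)
  det_p <- matrix(stats::runif(K * n_total, 0, 1e-4), nrow = K)
  det_p[fail] <- stats::runif(sum(fail))
  dimnames(det_p) <- dimnames(beta)

  annotation <- data.frame(
    probe_id = probe_id,
    gene_symbol = sprintf("GENE%05d", seq_len(K)),
    chromosome = sample(c(as.character(1:22), "X"), K, replace = TRUE),
    distance_to_tss = -as.integer(round(stats::runif(K, 0, 1500))),
    cpg_island = island,
    cross_reactive = stats::runif(K) < config$frac_cross_reactive,
    snp_overlap = stats::runif(K) < config$frac_snp,
    stringsAsFactors = FALSE)
  # spiked probes stay analysable: never flagged for exclusion
  annotation$cross_reactive[is_spiked] <- FALSE
  annotation$snp_overlap[is_spiked] <- FALSE

  truth <- data.frame(probe_id = probe_id, is_spiked = is_spiked,
                      true_delta = ifelse(is_spiked, config$spike_delta, 0),
                      stringsAsFactors = FALSE)

  list(intensities = list(M = M, U = U, detection_p = det_p,
                          bisulfite_control = stats::setNames(
                            stats::rlnorm(n_total, log(8000), 0.2),
                            sheet$sample_id)),
       beta = beta, sheet = sheet, annotation = annotation, truth = truth)
}

.cohort_sheet <- function(config) {
  fam <- rep(sprintf("F%d", seq_along(config$family_sizes)),
             config$family_sizes)
  n_rel <- config$n_relative_controls
  data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(config$n_cases)),
                  sprintf("control_%02d", seq_len(config$n_controls)),
                  if (config$n_vus > 0) sprintf("vus_%02d", seq_len(config$n_vus))),
    group = c(rep("case", config$n_cases), rep("control", config$n_controls),
              rep("vus", config$n_vus)),
    family_id = c(fam, rep(NA_character_, config$n_controls + config$n_vus)),
    relative_pool = c(rep(FALSE, config$n_cases),
                      rep(c(TRUE, FALSE), c(n_rel, config$n_controls - n_rel)),
                      rep(FALSE, config$n_vus)),
    sex = "M",
    karyotype = "46,XY",
    kdm5c_copies = c(rep(0L, config$n_cases),
                     rep(1L, config$n_controls + config$n_vus)),
    kdm5d_copies = 1L,
    stringsAsFactors = FALSE)
}

#' Configuration for the sex-chromosome-dosage cohort
#'
#' The default seven groups span the karyotypes used to probe demethylase
#' dosage: 47,XXX; 47,XXY; 46,XX; 46,XY; 45,X; female mutation carriers with
#' skewed X-inactivation (one functional copy); and mutation males (none).
#' Effective dose is \code{kdm5c_copies + kdm5d_weight * kdm5d_copies}; the
#' Y-linked homologue is down-weighted because it does not fully compensate.
#'
#' @param group_spec Data frame with columns \code{label},
#'   \code{kdm5c_copies}, \code{kdm5d_copies}, \code{n_samples}.
#' @param kdm5d_weight Weight of a KDM5D copy relative to KDM5C, in (0, 1).
#' @param saturation_dose Dose at which half the maximal methylation gain is
#'   reached (Michaelis-Menten-shaped dose response).
#' @param base_beta Methylation at zero dose.
#' @param max_beta_gain Asymptotic methylation gain at high dose.
#' @param noise_sd Gaussian noise on the beta scale, truncated to [0, 1].
#' @param seed Integer seed.
#' @return A list of class \code{"dosage_config"}.
#' @export
dosage_config <- function(group_spec = default_dosage_groups(),
                          kdm5d_weight = 0.5,
                          saturation_dose = 2,
                          base_beta = 0.35,
                          max_beta_gain = 0.5,
                          noise_sd = 0.03,
                          seed = 1L) {
  stopifnot(is.data.frame(group_spec), nrow(group_spec) >= 1,
            all(c("label", "kdm5c_copies", "kdm5d_copies", "n_samples")
                %in% names(group_spec)))
  if (any(group_spec$kdm5c_copies < 0) || any(group_spec$kdm5d_copies < 0))
    stop("dosage_config: copy counts must be nonnegative")
  if (kdm5d_weight < 0 || kdm5d_weight > 1)
    stop("dosage_config: kdm5d_weight must be in [0, 1]")
  if (saturation_dose <= 0)
    stop("dosage_config: saturation_dose must be positive")
  cfg <- list(group_spec = group_spec, kdm5d_weight = kdm5d_weight,
              saturation_dose = saturation_dose, base_beta = base_beta,
              max_beta_gain = max_beta_gain, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "dosage_config"
  cfg
}

#' Default seven-group dosage design
#'
#' Sample counts follow the validated study design: 3 47,XXX females,
#' 3 47,XXY males, 16 46,XX females, 19 46,XY males, 11 45,X females,
#' 4 female mutation carriers and 10 mutation males. Carriers are encoded
#' with one functional KDM5C copy (skewed X-inactivation keeps the wild-type
#' allele active).
#'
#' @return A data frame usable as \code{group_spec} in
#'   \code{\link{dosage_config}}.
#' @export
default_dosage_groups <- function() {
  data.frame(
    label = c("47,XXX", "47,XXY", "46,XX", "46,XY", "45,X",
              "carrier", "mutation_male"),
    kdm5c_copies = c(3L, 2L, 2L, 1L, 1L, 1L, 0L),
    kdm5d_copies = c(0L, 1L, 0L, 1L, 0L, 0L, 1L),
    n_samples = c(3L, 3L, 16L, 19L, 11L, 4L, 10L),
    sex = c("F", "M", "F", "M", "F", "F", "M"),
    stringsAsFactors = FALSE)
}

#' Effective demethylase dose of a dosage group
#' @param kdm5c_copies,kdm5d_copies Functional copy numbers.
#' @param kdm5d_weight Relative weight of a KDM5D copy.
#' @return Numeric effective dose.
#' @export
effective_dose <- function(kdm5c_copies, kdm5d_copies, kdm5d_weight = 0.5) {
  kdm5c_copies + kdm5d_weight * kdm5d_copies
}

#' Expected group mean beta under the dose-response model
#' @param dose Effective dose.
#' @param config A \code{\link{dosage_config}}.
#' @return Expected beta.
#' @export
dosage_expected_beta <- function(dose, config) {
  config$base_beta + config$max_beta_gain * dose / (dose + config$saturation_dose)
}

#' Simulate a sex-chromosome-dosage cohort at a single locus
#'
#' Per-sample methylation follows a saturating dose response in the
#' effective demethylase dose, plus truncated Gaussian noise. Group means
#' implied by the dose response are nondecreasing in effective dose by
#' construction.
#'
#' @param config A \code{\link{dosage_config}}.
#' @param n_probes Number of probes sharing the dose response (default 1).
#' @return A list with \code{beta} (probes x samples matrix) and
#'   \code{sheet} (sample sheet with karyotype, copies, effective dose).
#' @export
simulate_dosage_cohort <- function(config = dosage_config(), n_probes = 1L) {
  stopifnot(inherits(config, "dosage_config"))
  set.seed(config$seed)
  gs <- config$group_spec
  dose <- effective_dose(gs$kdm5c_copies, gs$kdm5d_copies, config$kdm5d_weight)
  sheet <- data.frame(
    sample_id = unlist(lapply(seq_len(nrow(gs)), function(i)
      sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", gs$label[i]),
              seq_len(gs$n_samples[i])))),
    group = rep(gs$label, gs$n_samples),
    sex = if ("sex" %in% names(gs)) rep(gs$sex, gs$n_samples) else NA,
    karyotype = rep(gs$label, gs$n_samples),
    kdm5c_copies = rep(gs$kdm5c_copies, gs$n_samples),
    kdm5d_copies = rep(gs$kdm5d_copies, gs$n_samples),
    effective_dose = rep(dose, gs$n_samples),
    stringsAsFactors = FALSE)
  mu <- dosage_expected_beta(sheet$effective_dose, config)
  n <- nrow(sheet)
  beta <- matrix(stats::rnorm(n_probes * n, rep(mu, each = n_probes),
                              config$noise_sd), nrow = n_probes)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(sprintf("locus_%02d", seq_len(n_probes)),
                         sheet$sample_id)
  list(beta = beta, sheet = sheet)
}
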