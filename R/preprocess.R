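#' Beta value from methylated/unmethylated intensities
#'
#' The Illumina 27K convention: beta = Max(M,0) / (Max(M,0) + Max(U,0) + 100).
#' Negative (background-subtracted) intensities are clamped to zero; the
#' +100 offset keeps the value strictly below 1 and stabilises low-intensity
#' probes. Vectorised and recycling like base arithmetic.
#'
#' @param M,U Methylated / unmethylated fluorescence intensities; may be
#'   negative.
#' @return Methylation fraction(s) in [0, 1).
#' @examples
#' compute_beta(100, 0)   # 0.5
#' compute_beta(-50, 100) # 0
#' @export
compute_beta <- function(M, U) {
  if (any(!is.finite(M)) || any(!is.finite(U)))
    stop("compute_beta: intensities must be finite")
  Mc <- pmax(M, 0)
  Uc <- pmax(U, 0)
  Mc / (Mc + Uc + 100)
}

#' Pyrosequencing methylation fraction
#'
#' Percent methylation from a bisulfite pyrosequencing assay, quantified as
#' the ratio of the cytosine signal to the combined C + T signal.
#'
#' @param C_signal,T_signal Nonnegative peak signals; not both zero.
#' @return C / (C + T).
#' @export
pyro_fraction <- function(C_signal, T_signal) {
  if (any(C_signal < 0) || any(T_signal < 0))
    stop("pyro_fraction: signals must be nonnegative")
  tot <- C_signal + T_signal
  if (any(tot == 0))
    stop("pyro_fraction: C + T is zero, fraction undefined")
  C_signal / tot
}

#' Sample quality-control policies
#'
#' The strict preset requires bisulfite-conversion control intensity above
#' 4000 (green channel) and at least 99% of probes detected at p < 0.01;
#' the relaxed preset (used for external datasets) requires the same control
#' intensity and at least 95% of probes detected at p < 0.05.
#'
#' @param preset \code{"strict"} or \code{"relaxed"}, or \code{NULL} to set
#'   thresholds directly.
#' @param min_bs_control Bisulfite control intensity must exceed this
#'   (strict inequality).
#' @param min_detected_fraction Minimum fraction of probes detected.
#' @param detection_alpha Detection p-value threshold defining "detected".
#' @return A list of class \code{"qc_policy"}.
#' @export
qc_policy <- function(preset = c("strict", "relaxed"),
                      min_bs_control = NULL, min_detected_fraction = NULL,
                      detection_alpha = NULL) {
  if (is.null(min_bs_control)) {
    preset <- match.arg(preset)
    pol <- switch(preset,
                  strict = list(min_bs_control = 4000,
                                min_detected_fraction = 0.99,
                                detection_alpha = 0.01),
                  relaxed = list(min_bs_control = 4000,
                                 min_detected_fraction = 0.95,
                                 detection_alpha = 0.05))
  } else {
    pol <- list(min_bs_control = min_bs_control,
                min_detected_fraction = min_detected_fraction,
                detection_alpha = detection_alpha)
  }
  if (any(unlist(pol) <= 0)) stop("qc_policy: thresholds must be positive")
  class(pol) <- "qc_policy"
  pol
}

#' Per-sample quality control
#'
#' A sample passes when its bisulfite-conversion control intensity strictly
#' exceeds the policy threshold and the fraction of probes with detection
#' p-value below \code{detection_alpha} is at least
#' \code{min_detected_fraction}.
#'
#' @param intensities List as produced by \code{\link{simulate_cohort}}:
#'   matrices \code{detection_p} (probes x samples) and named vector
#'   \code{bisulfite_control}.
#' @param policy A \code{\link{qc_policy}}.
#' @return Data frame with one row per sample: \code{sample_id},
#'   \code{bs_control}, \code{detected_fraction}, \code{pass}, and a
#'   semicolon-separated \code{reasons} column for failures.
#' @export
sample_qc <- function(intensities, policy = qc_policy("strict")) {
  dp <- intensities$detection_p
  if (is.null(dp) || length(dp) == 0) stop("sample_qc: empty intensity matrix")
  bs <- intensities$bisulfite_control[colnames(dp)]
  det_frac <- colMeans(dp < policy$detection_alpha)
  bs_ok <- bs > policy$min_bs_control
  det_ok <- det_frac >= policy$min_detected_fraction
  reasons <- character(ncol(dp))
  reasons[!bs_ok] <- "low_bisulfite_control"
  reasons[!det_ok] <- paste0(ifelse(nzchar(reasons[!det_ok]),
                                    paste0(reasons[!det_ok], ";"), ""),
                             "low_detection_fraction")
  data.frame(sample_id = colnames(dp), bs_control = unname(bs),
             detected_fraction = unname(det_frac),
             pass = unname(bs_ok & det_ok), reasons = reasons,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Probe filtering: detection failures, cross-reactive and SNP probes
#'
#' Removes the union of (a) probes failing the detection rule, (b) probes
#' flagged cross-reactive, (c) probes overlapping a SNP in the queried CpG.
#' The default detection rule excludes a probe whose detection p-value is
#' >= \code{detection_alpha} in any sample (mode \code{"any"});
#' \code{detection_mode = "mask"} instead masks individual failing
#' observations as NA and drops only probes failing in every sample.
#'
#' @param beta Probes x samples beta matrix (rownames = probe ids).
#' @param ann Probe annotation data frame covering all probes, with logical
#'   columns \code{cross_reactive} and \code{snp_overlap}.
#' @param detection_p Optional probes x samples matrix of detection
#'   p-values aligned with \code{beta}.
#' @param detection_alpha Detection p-value threshold (default 0.01).
#' @param detection_mode \code{"any"} (drop the whole probe) or
#'   \code{"mask"} (NA individual observations).
#' @return A list with \code{beta} (filtered matrix) and \code{report}: the
#'   count removed per reason and the size of their union (exclusion lists
#'   may overlap, so the union is reported explicitly and is at most the sum
#'   of the per-reason counts).
#' @export
filter_probes <- function(beta, ann, detection_p = NULL,
                          detection_alpha = 0.01,
                          detection_mode = c("any", "mask")) {
  detection_mode <- match.arg(detection_mode)
  probes <- rownames(beta)
  if (is.null(probes)) stop("filter_probes: beta must have probe rownames")
  missing_ann <- setdiff(probes, ann$probe_id)
  if (length(missing_ann) > 0)
    stop("filter_probes: probes absent from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  ann <- ann[match(probes, ann$probe_id), ]

  det_fail <- rep(FALSE, length(probes))
  if (!is.null(detection_p)) {
    dp <- detection_p[probes, colnames(beta), drop = FALSE]
    if (detection_mode == "any") {
      det_fail <- apply(dp >= detection_alpha, 1, any)
    } else {
      beta[dp >= detection_alpha] <- NA
      det_fail <- apply(dp >= detection_alpha, 1, all)
    }
  }
  cross <- as.logical(ann$cross_reactive)
  snp <- as.logical(ann$snp_overlap)
  drop <- det_fail | cross | snp
  report <- list(n_input = length(probes),
                 n_detection = sum(det_fail),
                 n_cross_reactive = sum(cross),
                 n_snp_overlap = sum(snp),
                 n_removed_union = sum(drop),
                 n_retained = sum(!drop))
  list(beta = beta[!drop, , drop = FALSE], report = report)
}

#' Squared Pearson correlation between two methylation platforms
#'
#' Concordance between paired methylation fractions measured on two
#' platforms (e.g. array beta versus pyrosequencing C/(C+T)).
#'
#' @param x,y Paired numeric vectors of length >= 3.
#' @return R-squared in [0, 1].
#' @export
platform_concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("platform_concordance: need >= 3 pairs of equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("platform_concordance: inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("platform_concordance: zero variance, R^2 undefined")
  stats::cor(x, y)^2
}
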