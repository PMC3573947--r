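#' Loss/gain direction tally stratified by CpG-island context
#'
#' Counts significant probes (p strictly below the threshold) by direction
#' of the methylation change (loss: delta beta < 0; gain: > 0) within
#' island and non-island strata. Probes with delta beta exactly zero are
#' excluded from the 2x2 table and reported separately.
#'
#' @param diff A \code{\link{probe_scan}} table.
#' @param ann Probe annotation with \code{probe_id} and \code{cpg_island}.
#' @param p_threshold Significance threshold (strict \code{<}).
#' @return List with \code{table} (2x2 matrix island/non_island x
#'   loss/gain), \code{n_zero_delta}, \code{p_threshold}.
#' @export
direction_tally <- function(diff, ann, p_threshold = 0.05) {
  m <- if ("cpg_island" %in% names(diff)) diff
       else merge(diff, ann[, c("probe_id", "cpg_island")], by = "probe_id")
  sig <- m[!is.na(m$p_value) & m$p_value < p_threshold, ]
  nz <- sig[sig$delta_beta != 0, ]
  tab <- matrix(0L, 2, 2, dimnames = list(c("island", "non_island"),
                                          c("loss", "gain")))
  tab["island", "loss"] <- sum(nz$cpg_island & nz$delta_beta < 0)
  tab["island", "gain"] <- sum(nz$cpg_island & nz$delta_beta > 0)
  tab["non_island", "loss"] <- sum(!nz$cpg_island & nz$delta_beta < 0)
  tab["non_island", "gain"] <- sum(!nz$cpg_island & nz$delta_beta > 0)
  list(table = tab, n_zero_delta = nrow(sig) - nrow(nz),
       p_threshold = p_threshold)
}

#' Tests of loss/gain asymmetry
#'
#' For a 2x2 contingency table (e.g. island context x direction), Fisher's
#' exact test of association. For a single loss/gain tally, the exact
#' two-sided sign test of direction against an even split: 53 losses and
#' 0 gains give p = 2 * 2^-53, about 2.22e-16.
#'
#' @param counts Either a 2x2 matrix/table, or a length-2 vector
#'   \code{c(loss, gain)}.
#' @return For a 2x2 table, the Fisher exact p-value; for a tally, the
#'   exact binomial sign-test p-value.
#' @export
asymmetry_test <- function(counts) {
  if (is.matrix(counts) || is.table(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts)))
      stop("asymmetry_test: counts must be nonnegative integers")
    if (sum(counts) == 0) stop("asymmetry_test: all-zero table")
    return(stats::fisher.test(counts)$p.value)
  }
  if (length(counts) != 2)
    stop("asymmetry_test: expected a 2x2 table or a c(loss, gain) tally")
  if (sum(counts) == 0) stop("asymmetry_test: all-zero tally")
  stats::binom.test(counts[1], sum(counts), p = 0.5)$p.value
}

#' Genome-wide mean methylation comparison by island stratum
#'
#' Averages betas per sample within the island and non-island strata and
#' compares cases to controls per stratum by the Mann-Whitney test. Detects
#' the dilution-scale global shifts that a handful of strong spikes produce
#' (e.g. 50 losses of 0.4 among 12,000 island probes shift the island mean
#' by about 0.0017).
#'
#' @param beta Probes x samples matrix.
#' @param ann Probe annotation with \code{cpg_island}.
#' @param sheet Sample sheet with \code{group}.
#' @return Data frame per stratum: mean per group, difference
#'   (case - control) and Mann-Whitney p. Empty strata are skipped with a
#'   warning.
#' @export
mean_methylation_compare <- function(beta, ann, sheet) {
  ann <- ann[match(rownames(beta), ann$probe_id), ]
  idx <- .match_sheet(beta, sheet)
  strata <- list(island = ann$cpg_island, non_island = !ann$cpg_island)
  rows <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    if (sum(sel) == 0) {
      warning("mean_methylation_compare: empty stratum ", s, ", skipped")
      next
    }
    per_sample <- colMeans(beta[sel, , drop = FALSE], na.rm = TRUE)
    a <- per_sample[idx$case]; b <- per_sample[idx$control]
    rows[[s]] <- data.frame(
      stratum = s, n_probes = sum(sel),
      mean_case = mean(a), mean_control = mean(b),
      difference = mean(a) - mean(b),
      p_value = mwu_exact_p(a, b), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano-plot export
#'
#' The per-probe table behind a volcano plot: delta beta, -log10 p and the
#' island flag, ready for plotting or writing.
#'
#' @param diff A \code{\link{probe_scan}} table.
#' @param ann Probe annotation with \code{cpg_island}.
#' @return Data frame with \code{probe_id}, \code{delta_beta},
#'   \code{neg_log10_p}, \code{cpg_island}.
#' @export
volcano_data <- function(diff, ann) {
  m <- merge(diff[, c("probe_id", "delta_beta", "p_value")],
             ann[, c("probe_id", "cpg_island")], by = "probe_id")
  data.frame(probe_id = m$probe_id, delta_beta = m$delta_beta,
             neg_log10_p = -log10(m$p_value), cpg_island = m$cpg_island,
             stringsAsFactors = FALSE)
}
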