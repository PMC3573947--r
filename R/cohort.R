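#' Kruskal-Wallis test across two or more groups
#'
#' Tie-corrected H statistic with the chi-square p-value on groups - 1
#' degrees of freedom (via \code{stats::kruskal.test}); optionally an exact
#' permutation p by full enumeration of group-label assignments for small
#' totals.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups).
#' @param exact Compute the exact permutation p-value (total n <= 10).
#' @return List with \code{H}, \code{df}, \code{p_value}, and
#'   \code{p_exact} when requested.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis: need a list of >= 2 groups")
  if (any(lengths(groups) == 0)) stop("kruskal_wallis: empty group")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value)
  if (is.nan(out$H)) { out$H <- 0; out$p_value <- 1 }  # all values tied
  if (exact) {
    n <- length(x)
    if (n > 10) stop("kruskal_wallis: exact enumeration limited to n <= 10")
    out$p_exact <- .kw_exact_p(x, lengths(groups), out$H)
  }
  out
}

# Exact Kruskal-Wallis p by enumerating all assignments of the pooled values
# to groups of the given sizes. H recomputed per assignment (tie-corrected).
.kw_exact_p <- function(x, sizes, h_obs) {
  n <- length(x)
  kw_h <- function(idx_list) {
    g <- integer(n)
    for (j in seq_along(idx_list)) g[idx_list[[j]]] <- j
    st <- stats::kruskal.test(x, factor(g))$statistic
    if (is.nan(st)) 0 else unname(st)
  }
  assignments <- .partitions(seq_len(n), sizes)
  hs <- vapply(assignments, kw_h, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# All ways of splitting `items` into ordered groups of the given sizes.
.partitions <- function(items, sizes) {
  if (length(sizes) == 1) return(list(list(items)))
  first <- utils::combn(items, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- .partitions(setdiff(items, f), sizes[-1])
    for (r in rest) out[[length(out) + 1L]] <- c(list(f), r)
  }
  out
}

#' Per-probe sex comparison with BH q-values
#'
#' Mann-Whitney test of each probe between females and males, with
#' Benjamini-Hochberg q-values. Positive delta beta means higher
#' methylation in females.
#'
#' @param beta Probes x samples matrix.
#' @param sheet Sample sheet with \code{sample_id} and \code{sex}
#'   (\code{"F"}/\code{"M"}).
#' @param probes Optional subset of probe ids to test (default all).
#' @return Data frame: \code{probe_id}, \code{mean_female},
#'   \code{mean_male}, \code{delta_beta}, \code{p_value}, \code{q_value}.
#' @export
sex_scan <- function(beta, sheet, probes = rownames(beta)) {
  sex <- sheet$sex[match(colnames(beta), sheet$sample_id)]
  f_cols <- which(sex == "F"); m_cols <- which(sex == "M")
  if (length(f_cols) == 0 || length(m_cols) == 0)
    stop("sex_scan: both sexes must be present")
  probes <- intersect(probes, rownames(beta))
  res <- data.frame(probe_id = probes, mean_female = NA_real_,
                    mean_male = NA_real_, delta_beta = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(probes)) {
    a <- beta[probes[i], f_cols]; a <- a[!is.na(a)]
    b <- beta[probes[i], m_cols]; b <- b[!is.na(b)]
    res$mean_female[i] <- mean(a); res$mean_male[i] <- mean(b)
    res$delta_beta[i] <- mean(a) - mean(b)
    res$p_value[i] <- mwu_exact_p(a, b)
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Dose-response trend of methylation across karyotype groups
#'
#' Spearman correlation between per-sample methylation and effective
#' demethylase dose, plus a Jonckheere-Terpstra trend test across the
#' dose-ordered groups with a seeded permutation p-value.
#'
#' @param beta Numeric vector of per-sample betas at one locus (or a
#'   one-row matrix).
#' @param sheet Sample sheet with \code{effective_dose} aligned to
#'   \code{beta} (by \code{sample_id} when \code{beta} is named).
#' @param n_perm Number of permutations for the JT p-value.
#' @param seed Seed for the permutation p-value.
#' @param alternative \code{"increasing"}, \code{"decreasing"} or
#'   \code{"two.sided"}.
#' @return List with \code{rho}, \code{jt_statistic}, \code{jt_p},
#'   \code{group_means} (named by label, ordered by dose).
#' @export
dosage_trend <- function(beta, sheet, n_perm = 2000L, seed = 1L,
                         alternative = c("increasing", "decreasing",
                                         "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.matrix(beta)) beta <- beta[1, ]
  if (!is.null(names(beta)))
    beta <- beta[sheet$sample_id]
  dose <- sheet$effective_dose
  if (length(unique(dose)) < 2)
    stop("dosage_trend: constant dose, trend undefined")
  if (length(unique(dose)) < 3)
    stop("dosage_trend: need >= 3 dose groups")
  rho <- stats::cor(beta, dose, method = "spearman")
  jt_obs <- .jt_stat(beta, dose)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) .jt_stat(sample(beta), dose), numeric(1))
  jt_p <- switch(alternative,
    increasing = (sum(perm >= jt_obs) + 1) / (n_perm + 1),
    decreasing = (sum(perm <= jt_obs) + 1) / (n_perm + 1),
    two.sided = (sum(abs(perm - mean(perm)) >= abs(jt_obs - mean(perm))) + 1) /
      (n_perm + 1))
  gm <- tapply(beta, sheet$group, mean)
  gd <- tapply(dose, sheet$group, unique)
  gm <- gm[order(unlist(gd))]
  list(rho = rho, jt_statistic = jt_obs, jt_p = jt_p, group_means = gm)
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs i < j of the
# Mann-Whitney count #{x_i < x_j} + 0.5 #{x_i == x_j}.
.jt_stat <- function(x, dose) {
  lev <- sort(unique(dose))
  jt <- 0
  for (i in seq_along(lev)[-length(lev)]) {
    xi <- x[dose == lev[i]]
    for (j in (i + 1):length(lev)) {
      xj <- x[dose == lev[j]]
      cmp <- outer(xi, xj, `<`)
      eqs <- outer(xi, xj, `==`)
      jt <- jt + sum(cmp) + 0.5 * sum(eqs)
    }
  }
  jt
}

#' Population-reference outlier screen
#'
#' Flags query samples whose methylation at a probe falls below the
#' reference distribution: under the default \code{"minimum"} rule, below
#' the reference minimum minus a margin; under the robust \code{"mad"}
#' rule, below the reference median minus 5 MAD. Emits a warning (but still
#' screens) when the reference has fewer than \code{min_reference} samples.
#'
#' @param query Numeric vector (one probe) or probes x samples matrix of
#'   query betas.
#' @param reference Same shape: reference betas per probe.
#' @param rule \code{"minimum"} or \code{"mad"}.
#' @param margin Margin below the reference minimum (default 0).
#' @param n_mad MAD multiplier for the robust rule (default 5).
#' @param min_reference Reference size below which a warning is issued.
#' @return List with \code{flags} (logical, per query sample per probe),
#'   \code{rule}, \code{threshold} (per probe) and \code{n_flagged}.
#' @export
population_outlier_screen <- function(query, reference,
                                      rule = c("minimum", "mad"),
                                      margin = 0, n_mad = 5,
                                      min_reference = 30L) {
  rule <- match.arg(rule)
  if (!is.matrix(query)) query <- matrix(query, nrow = 1)
  if (!is.matrix(reference)) reference <- matrix(reference, nrow = 1)
  if (nrow(query) != nrow(reference))
    stop("population_outlier_screen: probe dimension mismatch")
  if (ncol(reference) < min_reference)
    warning("population_outlier_screen: reference has only ",
            ncol(reference), " samples")
  thr <- switch(rule,
    minimum = apply(reference, 1, min, na.rm = TRUE) - margin,
    mad = apply(reference, 1, stats::median, na.rm = TRUE) -
      n_mad * apply(reference, 1, stats::mad, na.rm = TRUE))
  flags <- sweep(query, 1, thr, `<`)
  list(flags = flags, rule = rule, threshold = thr,
       n_flagged = sum(colSums(flags, na.rm = TRUE) > 0))
}
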