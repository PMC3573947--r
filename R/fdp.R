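#' Build a permutation null for the per-probe scan
#'
#' Reassigns case/control labels among the case + control samples (vus
#' samples never enter the null), preserving group sizes; recomputes every
#' probe's two-sided Mann-Whitney p-value under each permuted labelling and
#' stores them sorted ascending (one row per permutation). In sampling mode
#' label assignments are drawn uniformly at random with the given seed; the
#' observed labelling is not counted as one of the B permutations. In
#' exhaustive mode every distinct assignment is enumerated exactly once
#' (including the observed one), so the null is seed-invariant. If a
#' sampling request asks for at least as many permutations as there are
#' distinct assignments, the builder warns and switches to exhaustive mode.
#'
#' For speed the per-probe ranks are computed once; each permutation then
#' reduces to a rank-sum per probe and the exact p is a table lookup
#' (probes with tied values fall back to the tie-corrected normal
#' approximation, whose tie term is precomputed per probe).
#'
#' @param beta Probes x samples beta matrix.
#' @param sheet Sample sheet with \code{sample_id}, \code{group}.
#' @param B Number of permutations (sampling mode).
#' @param seed Integer seed for sampling mode.
#' @param exhaustive Enumerate all distinct label assignments.
#' @param exhaustive_cap Refuse exhaustive enumeration beyond this many
#'   assignments (default 1e5).
#' @param exact_threshold Passed to the Mann-Whitney machinery.
#' @return An object of class \code{"permutation_null"}: list with
#'   \code{sorted_p} (B x K matrix, rows ascending), \code{B}, \code{K},
#'   \code{probe_ids}, \code{n_case}, \code{n_control}, \code{exhaustive},
#'   \code{seed}.
#' @export
build_null <- function(beta, sheet, B = 1000L, seed = 1L,
                       exhaustive = FALSE, exhaustive_cap = 1e5,
                       exact_threshold = 25L) {
  idx <- .match_sheet(beta, sheet)
  test_cols <- sort(c(idx$case, idx$control))
  n_a <- length(idx$case); n_b <- length(idx$control)
  if (n_a == 0 || n_b == 0) stop("build_null: two nonempty groups required")
  n_assign <- choose(n_a + n_b, n_a)
  if (!exhaustive && B >= n_assign) {
    warning("build_null: B >= number of distinct label assignments (",
            n_assign, "); switching to exhaustive enumeration")
    exhaustive <- TRUE
  }
  if (exhaustive) {
    if (n_assign > exhaustive_cap)
      stop("build_null: ", n_assign, " assignments exceed exhaustive_cap")
    case_sets <- utils::combn(test_cols, n_a, simplify = FALSE)
  } else {
    set.seed(seed)
    case_sets <- lapply(seq_len(B), function(i) sample(test_cols, n_a))
  }
  B_eff <- length(case_sets)

  sub <- beta[, test_cols, drop = FALSE]
  if (anyNA(sub))
    stop("build_null: missing betas are not supported in the permutation null")
  ranks <- t(apply(sub, 1, rank))
  col_of <- integer(max(test_cols)); col_of[test_cols] <- seq_along(test_cols)

  # probes without ties use the exact p lookup; tied probes the normal branch
  has_ties <- apply(sub, 1, anyDuplicated) > 0L
  use_exact <- !has_ties & min(n_a, n_b) <= exact_threshold
  ptab <- mwu_p_table(n_a, n_b)
  N <- n_a + n_b
  mu_u <- n_a * n_b / 2
  tie_sigma <- apply(sub, 1, function(x) {
    tt <- table(x)
    s2 <- n_a * n_b / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (s2 > 0) sqrt(s2) else NA_real_
  })

  # all permutations at once: U = ranks %*% case-indicator, one BLAS call
  ind <- matrix(0, nrow = ncol(sub), ncol = B_eff)
  for (b in seq_len(B_eff)) ind[col_of[case_sets[[b]]], b] <- 1
  u_mat <- ranks %*% ind - n_a * (n_a + 1) / 2   # K x B
  p_mat <- matrix(NA_real_, nrow = nrow(sub), ncol = B_eff)
  if (any(use_exact))
    p_mat[use_exact, ] <- ptab[u_mat[use_exact, , drop = FALSE] + 1]
  if (any(!use_exact)) {
    z <- (u_mat[!use_exact, , drop = FALSE] - mu_u) / tie_sigma[!use_exact]
    pn <- pmin(1, 2 * stats::pnorm(-abs(z)))
    pn[is.na(z)] <- 1  # zero variance: all values tied
    p_mat[!use_exact, ] <- pn
  }
  sorted_p <- t(apply(p_mat, 2, sort))
  if (B_eff == 1L) sorted_p <- matrix(sorted_p, nrow = 1)
  structure(list(sorted_p = sorted_p, B = B_eff, K = nrow(sub),
                 probe_ids = rownames(sub), n_case = n_a, n_control = n_b,
                 exhaustive = exhaustive, seed = seed),
            class = "permutation_null")
}

#' False-discovery-proportion cutoff from a permutation null
#'
#' For FDP limit gamma = 0 the cutoff is the ceiling(alpha * B)-th smallest
#' value of the per-permutation minimum ("best") p-value: with confidence
#' 1 - alpha, no null probe attains a p-value below it. For gamma > 0 the
#' stepwise rank-substitution generalization applies and the observed
#' p-values are required: find the largest s such that the s-th smallest
#' observed p lies strictly below the ceiling(alpha * B)-th smallest value
#' of the per-permutation (floor(gamma * s) + 1)-th order statistic; the
#' returned cutoff is that critical value at s (declaring the top s probes
#' keeps the FDP at most gamma with confidence 1 - alpha). gamma = 0
#' reduces exactly to the "best"-p percentile rule.
#'
#' @param null A \code{\link{build_null}} object.
#' @param gamma FDP limit in [0, 1).
#' @param alpha One minus the confidence level, in (0, 1).
#' @param observed_p Observed per-probe p-values; required when
#'   \code{gamma > 0}.
#' @return The p-value cutoff (significance is strict \code{<}).
#' @export
fdp_cutoff <- function(null, gamma = 0, alpha = 0.05, observed_p = NULL) {
  stopifnot(inherits(null, "permutation_null"))
  if (gamma < 0 || gamma >= 1) stop("fdp_cutoff: gamma must be in [0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("fdp_cutoff: alpha must be in (0, 1)")
  if (alpha * null$B < 1)
    stop("fdp_cutoff: B = ", null$B, " cannot resolve alpha = ", alpha,
         "; minimum feasible alpha is ", 1 / null$B)
  k <- ceiling(alpha * null$B)
  crit <- function(j) sort(null$sorted_p[, j])[k]
  if (gamma == 0) return(crit(1))
  if (is.null(observed_p))
    stop("fdp_cutoff: observed_p required for gamma > 0")
  p_sorted <- sort(observed_p)
  s_max <- min(length(p_sorted), null$K)
  j_of_s <- pmin(floor(gamma * seq_len(s_max)) + 1, null$K)
  crit_j <- vapply(sort(unique(j_of_s)), crit, numeric(1))
  names(crit_j) <- sort(unique(j_of_s))
  crit_of_s <- crit_j[as.character(j_of_s)]
  ok <- p_sorted[seq_len(s_max)] < crit_of_s
  if (!any(ok)) return(unname(crit_j["1"]))
  s_star <- max(which(ok))
  unname(crit_of_s[s_star])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call significant probes at a grid of FDP and confidence levels
#'
#' Applies \code{\link{fdp_cutoff}} to the observed scan at every
#' combination of FDP limit gamma and confidence level 1 - alpha, returning
#' the significant probe sets, their sizes (a grid shaped like the usual
#' supplementary count table: rows = gamma, columns = alpha) and
#' loss/gain direction tallies. Significance is strict: observed p below
#' the cutoff.
#'
#' @param diff A \code{\link{probe_scan}} result.
#' @param null A \code{\link{build_null}} object built on the same probes.
#' @param gammas,alphas Numeric vectors of FDP limits / alpha levels.
#' @return An object of class \code{"fdp_result"}: list with
#'   \code{counts} (gamma x alpha matrix), \code{cutoffs} (same shape),
#'   \code{significant} (nested list of probe id sets),
#'   \code{direction} (per cell: loss/gain counts), \code{gammas},
#'   \code{alphas}.
#' @export
call_significant <- function(diff, null, gammas = c(0, 0.05, 0.1, 0.2),
                             alphas = c(0.005, 0.01, 0.05)) {
  stopifnot(inherits(null, "permutation_null"))
  if (!setequal(diff$probe_id, null$probe_ids))
    stop("call_significant: probe sets of scan and null differ")
  ok <- diff$testable
  p_obs <- diff$p_value[ok]
  ids <- diff$probe_id[ok]
  delta <- diff$delta_beta[ok]
  counts <- matrix(0L, length(gammas), length(alphas),
                   dimnames = list(paste0("gamma_", gammas),
                                   paste0("alpha_", alphas)))
  cutoffs <- counts * NA_real_
  sig <- vector("list", length(gammas)); names(sig) <- rownames(counts)
  direction <- sig
  for (gi in seq_along(gammas)) {
    sig[[gi]] <- vector("list", length(alphas))
    names(sig[[gi]]) <- colnames(counts)
    direction[[gi]] <- sig[[gi]]
    for (ai in seq_along(alphas)) {
      cut <- fdp_cutoff(null, gammas[gi], alphas[ai], observed_p = p_obs)
      hit <- p_obs < cut
      cutoffs[gi, ai] <- cut
      counts[gi, ai] <- sum(hit)
      sig[[gi]][[ai]] <- ids[hit]
      direction[[gi]][[ai]] <- c(loss = sum(hit & delta < 0),
                                 gain = sum(hit & delta > 0),
                                 zero = sum(hit & delta == 0))
    }
  }
  structure(list(counts = counts, cutoffs = cutoffs, significant = sig,
                 direction = direction, gammas = gammas, alphas = alphas),
            class = "fdp_result")
}

#' @export
print.fdp_result <- function(x, ...) {
  cat("Permutation FDP significance grid (counts of significant probes)\n")
  print(x$counts)
  invisible(x)
}
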