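#' Per-probe two-group differential methylation scan
#'
#' Runs the two-sided Mann-Whitney U test per probe between cases and
#' controls, with group means, delta beta (case minus control) and a
#' standardized separation score delta Z. Samples labelled \code{vus}
#' (variant of unknown significance) are excluded from the test but their
#' group mean is reported alongside. Missing betas are dropped pairwise per
#' probe; a probe left with fewer than two values in either group is flagged
#' untestable (p and effects NA), never silently dropped.
#'
#' delta Z is computed by z-standardizing each probe's betas across
#' cases + controls and reporting mean z(controls) - mean z(cases), so it is
#' positive for loss of methylation in cases.
#'
#' @param beta Probes x samples beta matrix with probe rownames and sample
#'   colnames.
#' @param sheet Sample sheet data frame with columns \code{sample_id} and
#'   \code{group} (\code{case}/\code{control}/\code{vus}).
#' @param exact_threshold Passed to \code{\link{mwu_exact_p}}.
#' @return Data frame (one row per probe): \code{probe_id}, \code{n_case},
#'   \code{n_control}, \code{mean_case}, \code{mean_control},
#'   \code{mean_vus} (NA when no vus samples), \code{p_value},
#'   \code{delta_beta}, \code{delta_z}, \code{testable}.
#' @export
probe_scan <- function(beta, sheet, exact_threshold = 25L) {
  idx <- .match_sheet(beta, sheet)
  case_cols <- idx$case; control_cols <- idx$control; vus_cols <- idx$vus
  if (length(case_cols) < 2 || length(control_cols) < 2)
    stop("probe_scan: need >= 2 case and >= 2 control samples")
  K <- nrow(beta)
  res <- data.frame(probe_id = rownames(beta),
                    n_case = NA_integer_, n_control = NA_integer_,
                    mean_case = NA_real_, mean_control = NA_real_,
                    mean_vus = NA_real_, p_value = NA_real_,
                    delta_beta = NA_real_, delta_z = NA_real_,
                    testable = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  test_cols <- c(case_cols, control_cols)
  if (!anyNA(beta[, test_cols])) {
    # complete data: vectorised scan (exact p is a table lookup per probe)
    sub <- beta[, test_cols, drop = FALSE]
    n_a <- length(case_cols); n_b <- length(control_cols)
    res$n_case <- n_a; res$n_control <- n_b
    res$mean_case <- rowMeans(beta[, case_cols, drop = FALSE])
    res$mean_control <- rowMeans(beta[, control_cols, drop = FALSE])
    if (length(vus_cols) > 0)
      res$mean_vus <- rowMeans(beta[, vus_cols, drop = FALSE], na.rm = TRUE)
    res$delta_beta <- res$mean_case - res$mean_control
    ranks <- t(apply(sub, 1, rank))
    u <- rowSums(ranks[, seq_len(n_a), drop = FALSE]) - n_a * (n_a + 1) / 2
    has_ties <- apply(sub, 1, anyDuplicated) > 0L
    use_exact <- !has_ties & min(n_a, n_b) <= exact_threshold
    p <- numeric(K)
    if (any(use_exact)) p[use_exact] <- mwu_p_table(n_a, n_b)[u[use_exact] + 1]
    if (any(!use_exact)) {
      idx2 <- which(!use_exact)
      for (i in idx2)
        p[i] <- mwu_exact_p(sub[i, seq_len(n_a)], sub[i, -seq_len(n_a)],
                            exact_threshold = exact_threshold)
    }
    res$p_value <- p
    # delta_z = mean z(control) - mean z(case) = (mean_b - mean_a) / sd(pooled)
    s <- apply(sub, 1, stats::sd)
    res$delta_z <- ifelse(s > 0, (res$mean_control - res$mean_case) / s, 0)
    res$testable <- TRUE
    return(res)
  }
  for (i in seq_len(K)) {
    a <- beta[i, case_cols]; a <- a[!is.na(a)]
    b <- beta[i, control_cols]; b <- b[!is.na(b)]
    res$n_case[i] <- length(a); res$n_control[i] <- length(b)
    if (length(vus_cols) > 0)
      res$mean_vus[i] <- mean(beta[i, vus_cols], na.rm = TRUE)
    if (length(a) < 2 || length(b) < 2) next
    res$testable[i] <- TRUE
    res$mean_case[i] <- mean(a); res$mean_control[i] <- mean(b)
    res$delta_beta[i] <- mean(a) - mean(b)
    res$p_value[i] <- mwu_exact_p(a, b, exact_threshold = exact_threshold)
    pooled <- c(a, b)
    s <- stats::sd(pooled)
    if (s > 0) {
      z <- (pooled - mean(pooled)) / s
      res$delta_z[i] <- mean(z[seq_along(b) + length(a)]) - mean(z[seq_along(a)])
    } else res$delta_z[i] <- 0
  }
  res
}

.match_sheet <- function(beta, sheet) {
  if (is.null(colnames(beta))) stop("beta matrix must have sample colnames")
  unknown <- setdiff(colnames(beta), sheet$sample_id)
  if (length(unknown) > 0)
    stop("samples absent from sample sheet: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  grp <- sheet$group[match(colnames(beta), sheet$sample_id)]
  list(case = which(grp == "case"), control = which(grp == "control"),
       vus = which(grp == "vus"))
}

#' Family-aware subset-robustness enumeration
#'
#' Enumerates every combination of one case per family crossed with one
#' relative-slot control (a control flagged \code{relative_pool}), runs the
#' per-probe scan on each reduced cohort (the chosen cases versus the fixed
#' unrelated controls plus the chosen relative), and reports the per-
#' combination significant sets and their intersection at each threshold.
#' With family sizes (3, 2, 2, 2, 1) and 3 eligible relatives this gives
#' 3*2*2*2*1*3 = 72 combinations of 5 cases vs 17 controls.
#'
#' @param beta Probes x samples beta matrix.
#' @param sheet Sample sheet; every case needs a \code{family_id} and at
#'   least one control must have \code{relative_pool = TRUE} (if none does,
#'   a single combination using all controls is run).
#' @param alpha_levels P-value thresholds defining significance per
#'   combination (strict \code{<}).
#' @return A list with \code{n_combinations}, \code{combinations} (list of
#'   case/control id sets), and per alpha level: \code{significant} (list of
#'   per-combination probe id sets) and \code{intersection}.
#' @export
subset_robustness <- function(beta, sheet, alpha_levels = 0.05) {
  cases <- sheet[sheet$group == "case", ]
  if (any(is.na(cases$family_id)))
    stop("subset_robustness: every case needs a family_id")
  fams <- split(cases$sample_id, cases$family_id)
  if (any(lengths(fams) == 0)) stop("subset_robustness: empty family")
  controls <- sheet[sheet$group == "control", ]
  rel <- controls$sample_id[isTRUE_vec(controls$relative_pool)]
  fixed <- setdiff(controls$sample_id, rel)
  rel_choices <- if (length(rel) > 0) as.list(rel) else list(character(0))

  case_grid <- expand.grid(fams, stringsAsFactors = FALSE)
  combos <- list()
  for (i in seq_len(nrow(case_grid))) {
    for (r in rel_choices) {
      combos[[length(combos) + 1L]] <-
        list(cases = unlist(case_grid[i, ], use.names = FALSE),
             controls = c(fixed, r))
    }
  }
  sig_by_alpha <- lapply(alpha_levels, function(a) vector("list", length(combos)))
  names(sig_by_alpha) <- as.character(alpha_levels)
  for (ci in seq_along(combos)) {
    cmb <- combos[[ci]]
    sub_sheet <- data.frame(
      sample_id = c(cmb$cases, cmb$controls),
      group = rep(c("case", "control"),
                  c(length(cmb$cases), length(cmb$controls))),
      stringsAsFactors = FALSE)
    sub_beta <- beta[, sub_sheet$sample_id, drop = FALSE]
    scan <- probe_scan(sub_beta, sub_sheet)
    for (a in as.character(alpha_levels)) {
      sig_by_alpha[[a]][[ci]] <-
        scan$probe_id[scan$testable & scan$p_value < as.numeric(a)]
    }
  }
  out <- list(n_combinations = length(combos), combinations = combos)
  out$significant <- sig_by_alpha
  out$intersection <- lapply(sig_by_alpha, function(sets)
    Reduce(intersect, sets))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
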