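#' Fit a two-group differential methylation model with permutation FDP control
#'
#' The package's central fitting function. Runs the exact Mann-Whitney
#' per-probe scan (\code{\link{probe_scan}}), builds the permutation null
#' (\code{\link{build_null}}) by relabelling cases and controls, and calls
#' significant probes at a grid of false-discovery-proportion limits and
#' confidence levels (\code{\link{call_significant}}).
#'
#' @param beta Probes x samples beta matrix.
#' @param sheet Sample sheet with \code{sample_id}, \code{group}
#'   (\code{case}/\code{control}/\code{vus}).
#' @param B Number of label permutations.
#' @param gammas FDP limits.
#' @param alphas One minus confidence levels.
#' @param seed Seed for the permutation sampling.
#' @param exhaustive Enumerate all label assignments instead of sampling.
#' @param annotation Optional probe annotation to join onto the scan table.
#' @return An object of class \code{"methyl_diff"} with components
#'   \code{scan} (the per-probe table), \code{null}, \code{fdp}
#'   (\code{\link{call_significant}} result), \code{call} and the design
#'   sizes.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_probes = 300, n_spiked = 5, seed = 7))
#' fit <- methyl_diff(sim$beta, sim$sheet, B = 100, seed = 7)
#' summary(fit)
#' @export
methyl_diff <- function(beta, sheet, B = 1000L,
                        gammas = c(0, 0.05, 0.1, 0.2),
                        alphas = c(0.005, 0.01, 0.05),
                        seed = 1L, exhaustive = FALSE, annotation = NULL) {
  scan <- probe_scan(beta, sheet)
  if (!is.null(annotation)) {
    keep <- c("probe_id", "gene_symbol", "distance_to_tss", "cpg_island")
    keep <- intersect(keep, names(annotation))
    scan <- merge(scan, annotation[, keep, drop = FALSE],
                  by = "probe_id", sort = FALSE)
    scan <- scan[match(rownames(beta), scan$probe_id), ]
    rownames(scan) <- NULL
  }
  testable <- beta[scan$probe_id[scan$testable], , drop = FALSE]
  null <- build_null(testable, sheet, B = B, seed = seed,
                     exhaustive = exhaustive)
  fdp <- call_significant(scan[scan$testable, ], null,
                          gammas = gammas, alphas = alphas)
  structure(list(scan = scan, null = null, fdp = fdp,
                 n_case = null$n_case, n_control = null$n_control,
                 B = null$B, seed = seed, call = match.call()),
            class = "methyl_diff")
}

#' @export
print.methyl_diff <- function(x, ...) {
  cat("Differential methylation fit (Mann-Whitney scan + permutation FDP)\n")
  cat(sprintf("  %d probes, %d cases vs %d controls, %d permutations%s\n",
              nrow(x$scan), x$n_case, x$n_control, x$B,
              if (x$null$exhaustive) " (exhaustive)" else ""))
  cat("Significant probe counts (rows = FDP limit, cols = alpha):\n")
  print(x$fdp$counts)
  invisible(x)
}

#' @export
summary.methyl_diff <- function(object, gamma = 0, alpha = NULL,
                                n_top = 10L, ...) {
  alphas <- object$fdp$alphas
  if (is.null(alpha)) alpha <- min(alphas)
  gi <- match(gamma, object$fdp$gammas)
  ai <- match(alpha, alphas)
  if (is.na(gi) || is.na(ai))
    stop("summary.methyl_diff: (gamma, alpha) not in the fitted grid")
  sig <- object$fdp$significant[[gi]][[ai]]
  tab <- object$scan[object$scan$probe_id %in% sig, ]
  tab <- tab[order(tab$delta_beta), ]
  out <- list(counts = object$fdp$counts,
              cutoff = object$fdp$cutoffs[gi, ai],
              gamma = gamma, alpha = alpha,
              n_significant = length(sig),
              direction = object$fdp$direction[[gi]][[ai]],
              top = utils::head(tab, n_top))
  class(out) <- "summary.methyl_diff"
  out
}

#' @export
print.summary.methyl_diff <- function(x, ...) {
  cat(sprintf("FDP <= %g with confidence %g%%: %d significant probes (p < %s)\n",
              x$gamma, 100 * (1 - x$alpha), x$n_significant,
              format_sci(x$cutoff)))
  cat(sprintf("  direction: %d loss / %d gain\n",
              x$direction[["loss"]], x$direction[["gain"]]))
  if (nrow(x$top) > 0) {
    cat("Top probes by methylation loss:\n")
    tp <- x$top
    tp$p_value <- format_sci(tp$p_value)
    print(tp, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Volcano plot of a differential methylation fit
#'
#' Plots delta beta against -log10 p, optionally colouring CpG-island
#' probes and drawing the fitted FDP cutoffs as horizontal lines.
#'
#' @param x A \code{\link{methyl_diff}} fit.
#' @param gamma FDP limit whose cutoffs to draw.
#' @param ... Passed to \code{plot}.
#' @export
plot.methyl_diff <- function(x, gamma = 0, ...) {
  sc <- x$scan[x$scan$testable, ]
  island <- if ("cpg_island" %in% names(sc)) sc$cpg_island else FALSE
  graphics::plot(sc$delta_beta, -log10(sc$p_value),
                 col = ifelse(island, "firebrick", "grey40"),
                 pch = 20, xlab = expression(Delta * beta),
                 ylab = expression(-log[10] ~ p), ...)
  gi <- match(gamma, x$fdp$gammas)
  if (!is.na(gi))
    graphics::abline(h = -log10(x$fdp$cutoffs[gi, ]), lty = 2,
                     col = "steelblue")
  invisible(x)
}

#' Per-probe effect sizes of a fit
#' @param object A \code{\link{methyl_diff}} fit.
#' @param ... Unused.
#' @return Named vector of delta beta (case minus control) per probe.
#' @export
coef.methyl_diff <- function(object, ...) {
  stats::setNames(object$scan$delta_beta, object$scan$probe_id)
}

# p-values in the 9.98E-08 style used in published methylation tables
format_sci <- function(p) {
  ifelse(is.na(p), NA_character_, toupper(sprintf("%.2e", p)))
}
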