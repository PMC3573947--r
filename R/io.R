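#' Read a tab-separated beta matrix
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Values outside [0, 1] or duplicated probe ids are errors with the
#' offending line reported.
#'
#' @param path File path.
#' @return Probes x samples numeric matrix.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("read_beta_matrix: no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_beta_matrix: malformed header in ", path)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop("read_beta_matrix: duplicated probe_id '", ids[dup[1]],
         "' at line ", dup[1] + 1)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("read_beta_matrix: non-numeric values in ", path)
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("read_beta_matrix: beta outside [0,1] at line ", bad[1, 1] + 1)
  m
}

#' Read a GEO-style series matrix
#'
#' Tab-separated with "!"-prefixed metadata lines, which are skipped; the
#' remaining lines form a beta matrix with a probe-id first column.
#' Imported values of exactly 1.0 are accepted (external matrices are not
#' bound by the strictly-below-1 property of intensity-derived betas).
#'
#' @param path File path.
#' @return Probes x samples numeric matrix.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("read_series_matrix: no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  tc <- textConnection(lines[keep])
  on.exit(close(tc))
  df <- utils::read.delim(tc, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop("read_series_matrix: duplicated probe_id '", ids[dup[1]], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a sample sheet
#'
#' CSV with at least \code{sample_id} and \code{group}; the optional
#' columns \code{family_id}, \code{relative_pool}, \code{sex},
#' \code{karyotype}, \code{kdm5c_copies}, \code{kdm5d_copies} are carried
#' through when present.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("read_sample_sheet: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_sample_sheet: missing columns: ", paste(miss, collapse = ", "))
  dup <- which(duplicated(df$sample_id))
  if (length(dup) > 0)
    stop("read_sample_sheet: duplicated sample_id '", df$sample_id[dup[1]],
         "' at line ", dup[1] + 1)
  if ("relative_pool" %in% names(df))
    df$relative_pool <- as.logical(df$relative_pool)
  df
}

#' Read a probe annotation table
#'
#' Tab-separated with \code{probe_id}, \code{gene_symbol},
#' \code{chromosome}, \code{distance_to_tss} (signed, negative upstream of
#' the TSS), \code{cpg_island}, \code{cross_reactive}, \code{snp_overlap}.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("read_probe_annotation: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(df))
    stop("read_probe_annotation: missing probe_id column")
  dup <- which(duplicated(df$probe_id))
  if (length(dup) > 0)
    stop("read_probe_annotation: duplicated probe_id '",
         df$probe_id[dup[1]], "' at line ", dup[1] + 1)
  for (col in c("cpg_island", "cross_reactive", "snp_overlap"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a beta matrix as tab-separated text
#' @param beta Probes x samples matrix.
#' @param path Output file.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline result tables to a directory
#'
#' Writes every data frame / matrix in \code{tables} as tab-separated text
#' named after its list element (matrices gain a leading id column from
#' their rownames). Full numeric precision is kept so a write/read
#' round-trip reproduces the values.
#'
#' @param tables Named list of data frames or matrices.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_results <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    obj <- tables[[nm]]
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (is.matrix(obj)) {
      df <- data.frame(id = rownames(obj), obj, check.names = FALSE,
                       stringsAsFactors = FALSE)
    } else df <- as.data.frame(obj)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}

#' Run the full discovery pipeline from a configuration
#'
#' Executes simulate (or load) / QC / probe filtering / per-probe scan /
#' permutation FDP / clustering + PCA / island asymmetry / dosage stages
#' and returns a machine-readable report. The configuration is a named
#' list, or a path to a JSON or YAML file holding one. Recognised keys:
#' \describe{
#'   \item{seed}{Top-level seed; every stage's randomness derives from it.}
#'   \item{simulate}{List of \code{\link{cohort_config}} arguments (used
#'     when no input paths are given).}
#'   \item{beta_path, sheet_path, annotation_path}{Input files instead of
#'     simulation.}
#'   \item{B, gammas, alphas}{Permutation FDP settings.}
#'   \item{out_dir}{When set, tables and the JSON report are written there.}
#'   \item{dosage}{Logical; also run the dosage-cohort stage (default TRUE
#'     when simulating).}
#' }
#'
#' @param config Named list or path to a JSON/YAML config file.
#' @return The report: a nested list with one section per executed stage.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- .read_config(config)
  seed <- config$seed %||% 1L
  report <- list(seed = seed)

  if (!is.null(config$beta_path)) {
    beta <- read_beta_matrix(config$beta_path)
    sheet <- read_sample_sheet(config$sheet_path)
    ann <- read_probe_annotation(config$annotation_path)
    det_p <- NULL
    report$input <- list(mode = "files", n_probes = nrow(beta),
                         n_samples = ncol(beta))
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- seed
    cfg <- do.call(cohort_config, sim_args)
    sim <- simulate_cohort(cfg)
    beta <- sim$beta; sheet <- sim$sheet; ann <- sim$annotation
    det_p <- sim$intensities$detection_p
    qc <- sample_qc(sim$intensities, qc_policy("strict"))
    report$input <- list(mode = "simulate", n_probes = nrow(beta),
                         n_samples = ncol(beta),
                         n_spiked = sum(sim$truth$is_spiked))
    report$qc <- list(n_pass = sum(qc$pass), n_fail = sum(!qc$pass))
  }

  filt <- filter_probes(beta, ann, detection_p = det_p)
  report$filter <- filt$report
  beta_f <- filt$beta

  B <- config$B %||% 1000L
  alphas <- unlist(config$alphas %||% c(0.005, 0.01, 0.05))
  resolvable <- alphas * B >= 1
  if (!all(resolvable)) {
    warning("run_pipeline: dropping alpha levels unresolvable at B = ", B,
            ": ", paste(alphas[!resolvable], collapse = ", "))
    alphas <- alphas[resolvable]
  }
  if (length(alphas) == 0)
    stop("run_pipeline: no alpha level resolvable at B = ", B)
  fit <- methyl_diff(beta_f, sheet, B = B,
                     gammas = unlist(config$gammas %||% c(0, 0.05, 0.1, 0.2)),
                     alphas = alphas, seed = seed, annotation = ann)
  report$scan <- list(n_testable = sum(fit$scan$testable),
                      min_p = min(fit$scan$p_value, na.rm = TRUE),
                      min_p_printed = format_sci(min(fit$scan$p_value,
                                                     na.rm = TRUE)))
  report$fdp <- list(counts = fit$fdp$counts, cutoffs = fit$fdp$cutoffs)

  sig <- fit$fdp$significant[[1]][[1]]
  report$structure <- list(n_significant_used = length(sig))
  if (length(sig) >= 2) {
    hc <- hclust_cosine_complete(t(beta_f[sig, , drop = FALSE]))
    truth_lab <- sheet$group[match(names(hc$cut), sheet$sample_id)]
    report$structure$ari_two_group_cut <-
      adjusted_rand(hc$cut, ifelse(truth_lab == "case", 1, 2))
    report$structure$newick <- dendrogram_newick(hc)
  }
  pca <- pca_median_knn(beta_f, n_components = 2)
  report$structure$pc1_var_fraction <- pca$explained_fraction[1]

  tal <- direction_tally(fit$scan, ann,
                         p_threshold = fit$fdp$cutoffs[1, 1])
  report$asymmetry <- list(table = tal$table)
  if (sum(tal$table) > 0)
    report$asymmetry$sign_p <-
      asymmetry_test(c(sum(tal$table[, "loss"]), sum(tal$table[, "gain"])))
  report$mean_methylation <- mean_methylation_compare(beta_f, ann, sheet)

  run_dosage <- config$dosage %||% is.null(config$beta_path)
  if (isTRUE(run_dosage)) {
    dos <- simulate_dosage_cohort(dosage_config(seed = seed))
    tr <- dosage_trend(dos$beta[1, ], dos$sheet, seed = seed)
    report$dosage <- list(rho = tr$rho, jt_p = tr$jt_p,
                          group_means = as.list(tr$group_means))
  }

  if (!is.null(config$out_dir)) {
    write_results(list(scan = fit$scan,
                       fdp_counts = fit$fdp$counts,
                       mean_methylation = report$mean_methylation),
                  config$out_dir)
    jsonlite::write_json(.jsonify(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.jsonify <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
  if (is.list(x)) return(lapply(x, .jsonify))
  x
}
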