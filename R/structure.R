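#' Pairwise cosine distance between samples
#'
#' d(x, y) = 1 - x.y / (||x|| ||y||), in [0, 2]; zero iff the vectors are
#' proportional with positive scale.
#'
#' @param x Samples x features numeric matrix (rows are compared).
#' @return A \code{dist} object.
#' @export
cosine_dist <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cosine_dist: zero-norm sample vector")
  sim <- tcrossprod(x / nrm)
  sim[sim > 1] <- 1; sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}

#' Complete-linkage hierarchical clustering under cosine distance
#'
#' Clusters samples (rows) of a beta submatrix — typically the significant
#' probes only — by complete-linkage agglomeration of cosine distances.
#' Samples are ordered lexicographically by id before clustering so tied
#' merges resolve deterministically. The returned object extends
#' \code{hclust} with the two-group cut labels.
#'
#' @param x Samples x probes matrix (e.g. \code{t(beta[sig, ])}), rows named
#'   by sample id; rows with any missing value are rejected.
#' @param k Number of groups for the reported cut (default 2).
#' @return Object of classes \code{c("cosine_hclust", "hclust")} with extra
#'   fields \code{cut} (named cluster labels) and \code{k}.
#' @export
hclust_cosine_complete <- function(x, k = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("hclust_cosine_complete: need >= 2 samples")
  if (anyNA(x)) stop("hclust_cosine_complete: missing values; impute first")
  if (!is.null(rownames(x))) x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(cosine_dist(x), method = "complete")
  hc$cut <- stats::cutree(hc, k = k)
  hc$k <- k
  class(hc) <- c("cosine_hclust", "hclust")
  hc
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths derive from the complete-linkage merge heights.
#'
#' @param hc An \code{hclust}-like object.
#' @param path Optional file; if missing the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  cls <- class(hc); class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' kNN imputation of missing betas
#'
#' Missing values are imputed per probe from the k nearest probes
#' (Euclidean distance over the samples both probes observe), as the mean
#' of the neighbours' values in the missing sample. Probes missing in every
#' sample are an error.
#'
#' @param beta Probes x samples matrix.
#' @param k Number of neighbour probes (default 10).
#' @return The completed matrix.
#' @export
knn_impute <- function(beta, k = 10L) {
  if (k < 1) stop("knn_impute: k must be >= 1")
  if (!anyNA(beta)) return(beta)
  all_missing <- rowSums(!is.na(beta)) == 0
  if (any(all_missing))
    stop("knn_impute: probe missing in all samples: ",
         rownames(beta)[which(all_missing)[1]])
  complete <- beta[stats::complete.cases(beta), , drop = FALSE]
  if (nrow(complete) < k)
    stop("knn_impute: fewer than k complete probes to define neighbors")
  out <- beta
  for (i in which(rowSums(is.na(beta)) > 0)) {
    row <- beta[i, ]
    obs <- !is.na(row)
    d2 <- colSums((t(complete[, obs, drop = FALSE]) - row[obs])^2)
    nn <- order(d2)[seq_len(k)]
    out[i, !obs] <- colMeans(complete[nn, !obs, drop = FALSE])
  }
  out
}

#' PCA with per-probe median centering and kNN imputation
#'
#' Missing betas are imputed to the 10 nearest probes (configurable), every
#' probe is centred at its median, and samples are projected onto principal
#' components. Component signs are fixed by making each component's
#' largest-magnitude probe loading positive, so scores are deterministic.
#'
#' @param beta Probes x samples matrix.
#' @param k Imputation neighbours (default 10).
#' @param n_components Number of components to keep (default
#'   \code{min(dim) - 1}).
#' @return List with \code{scores} (samples x components),
#'   \code{explained_variance} (variances, nonincreasing),
#'   \code{explained_fraction}.
#' @export
pca_median_knn <- function(beta, k = 10L, n_components = NULL) {
  beta <- knn_impute(beta, k = k)
  med <- apply(beta, 1, stats::median)
  centred <- beta - med
  pc <- stats::prcomp(t(centred), center = FALSE, scale. = FALSE)
  ncomp <- min(n_components %||% (min(dim(beta)) - 1), ncol(pc$x))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  load <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  flip <- vapply(seq_len(ncomp),
                 function(j) sign(load[which.max(abs(load[, j])), j]),
                 numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, `*`)
  ev <- pc$sdev[seq_len(ncomp)]^2
  list(scores = scores, explained_variance = ev,
       explained_fraction = ev / sum(pc$sdev^2))
}

#' Cluster samples by a chosen method
#'
#' One interface over the clustering variants used for case/control
#' separation checks: complete-linkage cosine hierarchical clustering,
#' k-means, or k-medians (k-means on ranks of the L1-optimal centre is not
#' provided; medians are updated coordinatewise by Lloyd-style iteration).
#'
#' @param x Samples x features matrix.
#' @param method \code{"hclust"}, \code{"kmeans"} or \code{"kmedians"}.
#' @param k Number of clusters (default 2).
#' @param seed Seed for the k-means/k-medians initialisation.
#' @return Named integer vector of cluster labels.
#' @export
cluster_samples <- function(x, method = c("hclust", "kmeans", "kmedians"),
                            k = 2L, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "hclust") return(hclust_cosine_complete(x, k = k)$cut)
  set.seed(seed)
  if (method == "kmeans") {
    cl <- stats::kmeans(x, centers = k, nstart = 10)$cluster
    return(stats::setNames(cl, rownames(x)))
  }
  # k-medians: Lloyd iterations with coordinatewise medians, L1 assignment
  centers <- x[sample(nrow(x), k), , drop = FALSE]
  for (it in 1:50) {
    d <- sapply(seq_len(k), function(j)
      rowSums(abs(sweep(x, 2, centers[j, ]))))
    cl <- max.col(-d)
    new_centers <- t(sapply(seq_len(k), function(j)
      apply(x[cl == j, , drop = FALSE], 2, stats::median)))
    if (all(abs(new_centers - centers) < 1e-12)) break
    centers <- new_centers
  }
  stats::setNames(cl, rownames(x))
}

#' Adjusted Rand index between two partitions
#' @param a,b Cluster label vectors of equal length.
#' @return The Hubert-Arabie adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Mean silhouette width of a labelling
#'
#' Convenience wrapper around \code{cluster::silhouette} for checking how
#' well a known grouping is separated in a score space.
#'
#' @param x Samples x features matrix (e.g. PCA scores).
#' @param labels Group labels (factor or vector) per sample.
#' @return Mean silhouette width.
#' @export
label_silhouette <- function(x, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(as.matrix(x)))
  mean(sil[, "sil_width"])
}
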