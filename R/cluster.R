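#' Log-scale transform of normalized counts
#'
#' `log2(count / size_factor + 1)` per cell; the variance-compressing
#' transform used before sample distances, clustering and PCA.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param size_factors per-sample factors (default: estimated from `counts`).
#' @return numeric matrix, same dimnames.
#' @export
transform_counts <- function(counts, size_factors = estimate_size_factors(counts)) {
  m <- unclass(counts)
  log2(sweep(m, 2, size_factors, "/") + 1)
}

#' Pairwise Euclidean distances between samples
#'
#' @param mat real matrix, genes x samples (e.g. from [transform_counts()]).
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(mat) {
  if (ncol(mat) < 2) stopf("need >= 2 samples")
  as.matrix(stats::dist(t(mat), method = "euclidean"))
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering on a sample distance matrix. Ties are broken
#' deterministically by `stats::hclust`'s ordering of the input, which is
#' fixed for a fixed matrix.
#'
#' @param d distance matrix from [euclidean_distances()] (or a `dist`).
#' @param linkage linkage criterion; only `"average"` is offered.
#' @return an `hclust` tree.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) < 2) stopf("need >= 2 samples to cluster")
    if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
      stopf("distance matrix must be symmetric with zero diagonal")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = linkage)
}

#' Two-component principal component analysis of samples
#'
#' Column-centered PCA over genes; returns the first two sample scores and
#' the fraction of variance each explains. Sign convention: within each
#' component the largest-magnitude gene loading is made positive, so results
#' do not flip between runs.
#'
#' @param mat real matrix, genes x samples.
#' @return list with `scores` (samples x 2, columns PC1/PC2) and
#'   `explained` (length-2 fractions, PC1 >= PC2).
#' @export
pca_two_components <- function(mat) {
  if (ncol(mat) < 3) stopf("PCA needs >= 3 samples")
  x <- t(mat)                              # samples in rows
  if (all(apply(x, 2, stats::var) == 0)) stopf("zero-variance input")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  for (k in 1:2) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  list(scores = pc$x[, 1:2, drop = FALSE], explained = explained)
}
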