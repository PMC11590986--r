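#' PCA of the protein score matrix
#'
#' Rows are restricted to scoring proteins (positive combined score in at
#' least one category). Columns are mean-centred but not variance-scaled:
#' all eight categories already share the \[0,1\] CaseOLAP score scale, so
#' scaling would inflate low-signal categories. Components come from the
#' singular value decomposition (via [stats::prcomp()]); each loading column
#' is sign-fixed so its largest-magnitude entry is positive.
#'
#' @param scores a `score_matrix`.
#' @param k number of components (default 2, at most the number of
#'   categories).
#' @return List of class `pca_result`: `projections` (scoring proteins x k),
#'   `loadings` (categories x k, orthonormal columns),
#'   `explained_variance_ratio` (length k, non-increasing, sums <= 1),
#'   `proteins` (row ids).
#' @export
score_pca <- function(scores, k = 2) {
  X <- scores$score
  keep <- apply(X, 1, max) > 0
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2) stopf("PCA needs at least 2 scoring proteins")
  if (k > min(dim(X))) {
    stopf("k = %d exceeds min(n proteins, n categories) = %d",
          k, min(dim(X)))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  load <- p$rotation[, seq_len(k), drop = FALSE]
  proj <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      proj[, j] <- -proj[, j]
    }
  }
  ratio <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    projections = proj,
    loadings = load,
    explained_variance_ratio = ratio[seq_len(k)],
    proteins = rownames(X),
    center = p$center
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d proteins, %d components; variance ratios: %s\n",
              length(x$proteins), ncol(x$loadings),
              paste(sprintf("%.3f", x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Hierarchical clustering of protein score profiles
#'
#' Agglomerative clustering of scoring proteins by their category score
#' vectors. The dendrogram uses the chosen metric (Euclidean distance, or
#' one-minus-correlation when `metric = "correlation"`); the returned
#' `pairwise` matrix reports the metric's native value per pair — distances
#' for Euclidean, correlation values in \[-1, 1\] for correlation, which is
#' the scale heatmaps of score profiles use. A constant score profile has no
#' defined correlation with anything; such pairs are recorded as 0 with a
#' warning.
#'
#' @param scores a `score_matrix`.
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @param linkage `"average"` (default), `"complete"`, or `"ward.D2"`.
#' @return List of class `cluster_result`: `linkage_tree` (merge list with
#'   heights, as in [stats::hclust()]), `leaf_order` (protein ids in
#'   dendrogram order), `pairwise` (protein x protein matrix), `metric`,
#'   `linkage`, `hclust` (the underlying object).
#' @export
hierarchical_cluster <- function(scores,
                                 metric = c("euclidean", "correlation"),
                                 linkage = c("average", "complete",
                                             "ward.D2")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  X <- scores$score
  X <- X[apply(X, 1, max) > 0, , drop = FALSE]
  if (nrow(X) < 2) stopf("clustering needs at least 2 scoring proteins")
  if (metric == "euclidean") {
    d <- stats::dist(X, method = "euclidean")
    pairwise <- as.matrix(d)
  } else {
    cc <- suppressWarnings(stats::cor(t(X)))
    if (anyNA(cc)) {
      warnf("%d protein pair(s) with undefined correlation (constant profile) recorded as 0",
            sum(is.na(cc[upper.tri(cc)])))
      cc[is.na(cc)] <- 0
    }
    diag(cc) <- 1
    pairwise <- cc
    d <- stats::as.dist(1 - cc)
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(
    linkage_tree = data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                              height = hc$height),
    leaf_order = rownames(X)[hc$order],
    pairwise = pairwise,
    metric = metric,
    linkage = linkage,
    hclust = hc
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %d proteins, %s metric, %s linkage\n",
              length(x$leaf_order), x$metric, x$linkage))
  invisible(x)
}
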