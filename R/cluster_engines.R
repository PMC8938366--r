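#' Construct a partition object
#'
#' A partition is the common currency between clustering engines and every
#' validity index: integer labels 1..k, canonicalized so that cluster 1 is
#' the cluster containing the lowest-index observation, cluster 2 the
#' cluster containing the lowest-index observation not in cluster 1, and so
#' on. Canonical labels make partitions exactly comparable across engines
#' and runs.
#'
#' @param labels Integer vector of cluster assignments.
#' @param algorithm Tag identifying the producing engine.
#' @param centers Optional k x p matrix of cluster centres (k-means
#'   centroids or PAM medoid rows), reordered to match the canonical labels.
#' @return An object of class `partition` with elements `labels`, `k`,
#'   `algorithm`, `centers`.
#' @export
new_partition <- function(labels, algorithm = "unknown", centers = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("partition labels must not contain NA")
  canon <- canonicalize_labels(labels)
  k <- max(canon$labels)
  if (!all(seq_len(k) %in% canon$labels)) stop("every cluster must be non-empty")
  if (!is.null(centers)) {
    centers <- as.matrix(centers)[canon$old_of_new, , drop = FALSE]
    rownames(centers) <- NULL
  }
  structure(list(labels = canon$labels, k = k, algorithm = algorithm,
                 centers = centers),
            class = "partition")
}

# Relabel clusters in order of first appearance; returns the relabelled
# vector and, for each new label, the old label it came from.
canonicalize_labels <- function(labels) {
  first <- unique(labels)
  new <- match(labels, first)
  list(labels = as.integer(new), old_of_new = first)
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", x$algorithm, "| k =", x$k,
      "| sizes:", paste(tabulate(x$labels, x$k), collapse = "/"), "\n")
  invisible(x)
}

# Accept a partition object or a bare label vector everywhere.
partition_labels <- function(p) {
  if (inherits(p, "partition")) p$labels else as.integer(p)
}

#' Pairwise distance matrix
#'
#' Euclidean by default (the conventional choice for the scaled feature
#' matrix); Manhattan available.
#'
#' @param X Numeric matrix (rows = subjects).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A `dist` object with the metric recorded.
#' @export
feature_dist <- function(X, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stats::dist(X, method = metric)
}

#' K-means clustering under the partition contract
#'
#' Lloyd-type iterations (Hartigan-Wong refinement) over `restarts` random
#' initialisations, keeping the restart with minimal total within-cluster
#' sum of squares. Deterministic given `seed`.
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param restarts Random restarts (default 25).
#' @param max_iter Maximum iterations per restart (default 300).
#' @param seed Optional RNG seed for reproducibility.
#' @return A [partition][new_partition] with k-means centroids in `centers`
#'   and the winning objective in attribute `tot_withinss`.
#' @export
kmeans_fit <- function(X, k, restarts = 25, max_iter = 300, seed = NULL) {
  X <- as.matrix(X)
  check_k(k, nrow(X))
  if (!is.null(seed)) set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(X, centers = k, nstart = restarts, iter.max = max_iter)
  )
  p <- new_partition(km$cluster, algorithm = "kmeans", centers = km$centers)
  attr(p, "tot_withinss") <- km$tot.withinss
  p
}

check_k <- function(k, n) {
  if (k < 2 || k > n - 1) stop("k must satisfy 2 <= k <= n - 1 (k = ", k, ", n = ", n, ")")
  invisible(k)
}

#' Agglomerative hierarchical clustering
#'
#' Average linkage (UPGMA: cluster distance is the mean pairwise distance)
#' or Ward linkage in the Ward.D2 convention (minimal increase in
#' within-cluster sum of squared Euclidean distances, heights on the
#' distance scale). Both linkages are monotone, so merge heights are
#' non-decreasing.
#'
#' @param D A `dist` object, e.g. from [feature_dist()].
#' @param linkage `"average"` or `"ward"`.
#' @return An `hclust` dendrogram with the linkage recorded.
#' @export
hclust_fit <- function(D, linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  if (linkage == "ward" && !is.null(attr(D, "method")) &&
      attr(D, "method") != "euclidean") {
    warning("Ward linkage assumes Euclidean geometry; distance is ",
            attr(D, "method"))
  }
  method <- if (linkage == "ward") "ward.D2" else "average"
  tree <- stats::hclust(D, method = method)
  attr(tree, "linkage") <- linkage
  tree
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k - 1 merges; cuts are nested across k.
#'
#' @param tree An `hclust` object from [hclust_fit()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A [partition][new_partition].
#' @export
cut_dendrogram <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in [1, n]")
  tag <- paste0("hclust_", attr(tree, "linkage") %||% tree$method)
  new_partition(stats::cutree(tree, k = k), algorithm = tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partitioning around medoids
#'
#' BUILD (greedy medoid selection minimising total dissimilarity) followed
#' by SWAP to a local optimum; deterministic given the distance matrix.
#'
#' @param D A `dist` object.
#' @param k Number of clusters.
#' @param X Optional feature matrix; when supplied, medoid rows are attached
#'   as `centers` so the partition can classify new points.
#' @param seed Ignored (PAM on a fixed distance matrix is deterministic);
#'   accepted for engine-interface uniformity.
#' @return A [partition][new_partition] with `medoids` (observation indices)
#'   attached as an attribute.
#' @export
pam_fit <- function(D, k, X = NULL, seed = NULL) {
  n <- attr(D, "Size")
  check_k(k, n)
  fit <- cluster::pam(D, k = k, diss = TRUE)
  med <- as.integer(fit$id.med)
  centers <- if (!is.null(X)) as.matrix(X)[med, , drop = FALSE] else NULL
  p <- new_partition(fit$clustering, algorithm = "pam", centers = centers)
  # reorder medoid ids to the canonical label order
  attr(p, "medoids") <- med[match(seq_len(p$k),
                                  p$labels[med])]
  p
}

#' Engines recognised by the selection protocol
#' @return Character vector of engine tags.
#' @export
available_engines <- function() c("kmeans", "hclust_average", "hclust_ward", "pam")

#' Fit any engine by tag
#'
#' Uniform entry point used by the screening, stability and resampling
#' stages: `"kmeans"`, `"hclust_average"`, `"hclust_ward"` or `"pam"`.
#' Hierarchical engines build the dendrogram on the Euclidean distance
#' matrix and cut at k; PAM gets medoid rows attached for classification.
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param engine Engine tag, see [available_engines()], or a function
#'   `(X, k)` returning a [partition][new_partition] (a custom engine,
#'   e.g. for null-model stability experiments).
#' @param k Number of clusters.
#' @param seed RNG seed (used by k-means restarts).
#' @return A [partition][new_partition].
#' @export
fit_partition <- function(X, engine, k, seed = NULL) {
  X <- as.matrix(X)
  if (is.function(engine)) {
    if (!is.null(seed)) set.seed(seed)
    return(engine(X, k))
  }
  engine <- match.arg(engine, available_engines())
  switch(engine,
    kmeans = kmeans_fit(X, k, seed = seed),
    hclust_average = cut_dendrogram(hclust_fit(feature_dist(X), "average"), k),
    hclust_ward = cut_dendrogram(hclust_fit(feature_dist(X), "ward"), k),
    pam = pam_fit(feature_dist(X), k, X = X, seed = seed)
  )
}
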