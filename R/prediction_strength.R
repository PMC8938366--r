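#' Prediction strength of one train/test split
#'
#' Clusters the training and test halves independently with k clusters,
#' classifies every test point to its nearest training centre (k-means:
#' centroid; PAM: medoid), and for each test cluster with at least two
#' members computes the proportion of unordered member pairs co-assigned
#' to the same training class. The split's prediction strength is the
#' minimum over test clusters; clusters with fewer than two members
#' contribute 1.
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param engine A partitioning engine: `"kmeans"` or `"pam"` (hierarchical
#'   engines have no natural rule for classifying new points).
#' @param k Number of clusters.
#' @param train,test Disjoint row-index sets, each of size >= k.
#' @param seed RNG seed.
#' @return Scalar in [0, 1].
#' @export
ps_single_split <- function(X, engine, k, train, test, seed = NULL) {
  if (!is.function(engine)) engine <- match.arg(engine, c("kmeans", "pam"))
  X <- as.matrix(X)
  if (length(intersect(train, test))) stop("train and test must be disjoint")
  if (length(train) < k || length(test) < k) stop("each fold needs at least k points")
  ptr <- fit_partition(X[train, , drop = FALSE], engine, k, seed = seed)
  pte <- fit_partition(X[test, , drop = FALSE], engine, k, seed = seed)
  centers <- ptr$centers
  if (is.null(centers)) stop("training partition has no centres")
  Xte <- X[test, , drop = FALSE]
  # nearest training centre per test point
  d2 <- outer(rowSums(Xte^2), rowSums(centers^2), "+") - 2 * tcrossprod(Xte, centers)
  train_class <- max.col(-d2, ties.method = "first")
  ps_by_cluster <- vapply(seq_len(pte$k), function(j) {
    members <- which(pte$labels == j)
    nj <- length(members)
    if (nj < 2) return(1)
    counts <- tabulate(train_class[members], nbins = k)
    sum(choose(counts, 2)) / choose(nj, 2)
  }, 0)
  min(ps_by_cluster)
}

#' Cross-validated prediction strength curve
#'
#' The fourth checkpoint (generalizability): subjects are randomly split in
#' half over many iterations (two-fold cross-validation); in each
#' iteration both fold directions are evaluated with [ps_single_split()]
#' and averaged, for every k in the grid. The retained number of clusters
#' is the k with the highest mean prediction strength among those reaching
#' the threshold (default 0.80) — the "highest prediction strength over
#' the cutoff" rule; alternatively (`retain_rule = "largest_k"`) the
#' largest qualifying k.
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param engine `"kmeans"` or `"pam"`.
#' @param k_grid Candidate ks (default 2:10; clipped to the fold size).
#' @param iterations Random half-splits (default 500).
#' @param threshold Retention cutoff on mean prediction strength
#'   (default 0.80).
#' @param retain_rule `"max_ps"` (default) or `"largest_k"`.
#' @param seed RNG seed; the curve is fully reproducible from it.
#' @return A list of class `ps_curve`: `k`, `mean_ps`, `sd_ps`,
#'   `retained_k` (NA when no k qualifies), plus the settings.
#' @export
ps_curve <- function(X, engine = "kmeans", k_grid = 2:10, iterations = 500,
                     threshold = 0.80, retain_rule = c("max_ps", "largest_k"),
                     seed = NULL) {
  retain_rule <- match.arg(retain_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (iterations < 1) stop("iterations must be >= 1")
  n_half <- floor(n / 2)
  k_max_ok <- n_half - 1
  clipped <- k_grid[k_grid >= 2 & k_grid <= k_max_ok]
  if (length(clipped) < length(k_grid)) {
    warning("k grid clipped to [2, ", k_max_ok, "] for fold size ", n_half)
  }
  k_grid <- sort(unique(clipped))
  if (!length(k_grid)) stop("no feasible k for this sample size")
  if (!is.null(seed)) set.seed(seed)
  ps <- matrix(NA_real_, nrow = iterations, ncol = length(k_grid),
               dimnames = list(NULL, k_grid))
  for (it in seq_len(iterations)) {
    idx <- sample.int(n)
    a <- idx[seq_len(n_half)]
    b <- idx[seq(n_half + 1, n)]
    for (j in seq_along(k_grid)) {
      k <- k_grid[j]
      ps[it, j] <- mean(c(ps_single_split(X, engine, k, train = a, test = b),
                          ps_single_split(X, engine, k, train = b, test = a)))
    }
  }
  mean_ps <- colMeans(ps)
  sd_ps <- apply(ps, 2, stats::sd)
  qualifying <- k_grid[mean_ps >= threshold]
  retained <- if (!length(qualifying)) {
    NA_integer_
  } else if (retain_rule == "largest_k") {
    max(qualifying)
  } else {
    qualifying[which.max(mean_ps[as.character(qualifying)])]
  }
  structure(
    list(k = k_grid, mean_ps = unname(mean_ps), sd_ps = unname(sd_ps),
         iterations = iterations, folds = 2L, threshold = threshold,
         retain_rule = retain_rule, retained_k = retained,
         engine = engine, seed = seed),
    class = "ps_curve"
  )
}

#' @export
print.ps_curve <- function(x, ...) {
  cat("prediction strength (", x$engine, ", ", x$iterations,
      " half-split iterations)\n", sep = "")
  print(data.frame(k = x$k, mean_ps = round(x$mean_ps, 3),
                   sd_ps = round(x$sd_ps, 3)), row.names = FALSE)
  cat("retained k (threshold ", x$threshold, ", rule ", x$retain_rule, "): ",
      x$retained_k, "\n", sep = "")
  invisible(x)
}
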