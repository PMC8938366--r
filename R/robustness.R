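#' Cophenetic correlation
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (height of the lowest common merge) of a
#' dendrogram built from them; 1 for ultrametric input. A hierarchical-fit
#' diagnostic: values near 1 mean the tree faithfully encodes the
#' distances.
#'
#' @param D The `dist` object the tree was built from.
#' @param tree An `hclust` object.
#' @return Scalar in [-1, 1].
#' @export
cophenetic_correlation <- function(D, tree) {
  n <- attr(D, "Size")
  if (n < 3) stop("cophenetic correlation needs at least 3 observations")
  stats::cor(as.vector(D), as.vector(stats::cophenetic(tree)))
}

#' Per-observation silhouette profile
#'
#' The same s(i) as [silhouette_mean()], returned per observation with
#' per-cluster means, sorted within cluster for plotting.
#'
#' @param D A `dist` object.
#' @param partition A partition or label vector.
#' @return A data.frame (`observation`, `cluster`, `s`) ordered by cluster
#'   and decreasing s, with per-cluster mean widths in attribute
#'   `cluster_means` and the overall mean in attribute `mean_s`.
#' @export
silhouette_profile <- function(D, partition) {
  labels <- partition_labels(partition)
  s <- silhouette_widths(D, labels)
  out <- data.frame(observation = seq_along(labels), cluster = labels, s = s)
  out <- out[order(out$cluster, -out$s), ]
  rownames(out) <- NULL
  attr(out, "cluster_means") <- tapply(s, labels, mean)
  attr(out, "mean_s") <- mean(s)
  out
}

# Best one-to-one assignment of replicate clusters to reference clusters,
# maximising the matched count of a contingency table. Exhaustive over
# permutations up to 7 clusters, greedy beyond.
match_clusters <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  if (nr <= 7) {
    perms <- permutations_of(nc, nr)
    best <- NULL; best_val <- -Inf
    for (i in seq_len(nrow(perms))) {
      pm <- perms[i, ]
      val <- sum(tab[cbind(seq_len(nr), pm)])
      if (val > best_val) { best_val <- val; best <- pm }
    }
    best
  } else {
    # greedy: repeatedly take the largest remaining cell
    assign <- rep(NA_integer_, nr)
    t2 <- tab
    for (step in seq_len(min(nr, nc))) {
      ij <- arrayInd(which.max(t2), dim(t2))
      assign[ij[1]] <- ij[2]
      t2[ij[1], ] <- -Inf; t2[, ij[2]] <- -Inf
    }
    leftover_rows <- which(is.na(assign))
    leftover_cols <- setdiff(seq_len(nc), assign)
    assign[leftover_rows] <- leftover_cols[seq_along(leftover_rows)]
    assign
  }
}

# All injections of m slots into 1..n (rows: one mapping each).
permutations_of <- function(n, m = n) {
  if (m == 0) return(matrix(integer(0), nrow = 1))
  out <- NULL
  for (v in seq_len(n)) {
    rest <- permutations_of(n, m - 1)
    rest <- rest[apply(rest, 1, function(r) !v %in% r), , drop = FALSE]
    out <- rbind(out, cbind(v, rest))
  }
  unname(out)
}

#' Bootstrap stability (ST) indices
#'
#' Third-checkpoint stability diagnostic for a partitioning solution: the
#' full-data partition is the reference; for each of B bootstrap resamples
#' (n subjects drawn with replacement) the resample is reclustered, the
#' replicate clusters are matched one-to-one to the reference clusters by
#' maximum agreement on the resampled subjects, and each subject present
#' in the resample scores 1 when its mapped replicate label equals its
#' reference label. The individual ST index is each subject's agreement
#' rate over the replicates containing it; the global ST index is the mean
#' individual index. Both lie in [0, 1]; 1 means every resample reproduces
#' the reference partition.
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param engine Engine tag (a partitioning engine: `"kmeans"` or `"pam"`
#'   are the intended users, but any engine works).
#' @param k Number of clusters.
#' @param B Bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return A list of class `st_report`: `global_st`, `individual_st`
#'   (length n), `replicates` (replicates kept), `failed` (dropped), `k`,
#'   `engine`, `seed`.
#' @export
st_indices <- function(X, engine, k, B = 100, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  reference <- fit_partition(X, engine, k)$labels
  agree <- numeric(n)
  seen <- numeric(n)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_labels <- tryCatch(
      fit_partition(X[idx, , drop = FALSE], engine, k)$labels,
      error = function(e) NULL
    )
    if (is.null(rep_labels)) { failed <- failed + 1L; next }
    present <- unique(idx)
    # label of each present subject = label at its first occurrence
    first <- match(present, idx)
    lab_rep <- rep_labels[first]
    lab_ref <- reference[present]
    tab <- table(factor(lab_rep, levels = seq_len(max(rep_labels))),
                 factor(lab_ref, levels = seq_len(k)))
    mapping <- match_clusters(as.matrix(tab))
    mapped <- mapping[lab_rep]
    seen[present] <- seen[present] + 1
    agree[present] <- agree[present] + (mapped == lab_ref)
  }
  if (failed) warning(failed, " bootstrap replicate(s) dropped (engine failure)")
  individual <- ifelse(seen > 0, agree / seen, NA_real_)
  structure(
    list(global_st = mean(individual, na.rm = TRUE),
         individual_st = individual,
         replicates = B - failed, failed = failed,
         k = k, engine = engine, seed = seed),
    class = "st_report"
  )
}

#' @export
print.st_report <- function(x, ...) {
  cat("bootstrap stability:", x$engine, "k =", x$k,
      "| global ST =", round(x$global_st, 3),
      "over", x$replicates, "replicates\n")
  invisible(x)
}
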