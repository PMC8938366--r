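#' Total within-cluster sum of squares
#'
#' Pooled squared Euclidean deviation of observations from their cluster
#' centroid; the W_k shared by the Calinski-Harabasz, Hartigan and
#' Krzanowski-Lai indices.
#'
#' @param X Numeric matrix.
#' @param partition A partition or label vector (all labels 1 gives the
#'   total sum of squares about the grand centroid).
#' @return Non-negative scalar.
#' @export
within_ss <- function(X, partition) {
  X <- as.matrix(X)
  labels <- partition_labels(partition)
  sum(vapply(unique(labels), function(g) {
    xg <- X[labels == g, , drop = FALSE]
    sum(sweep(xg, 2, colMeans(xg))^2)
  }, 0))
}

#' Calinski-Harabasz index
#'
#' Variance-ratio criterion (B / (k - 1)) / (W / (n - k)) with B the
#' between-cluster and W the pooled within-cluster sum of squares;
#' maximised at well-separated, tight partitions.
#'
#' @inheritParams within_ss
#' @return Scalar; `Inf` with a warning when W = 0.
#' @export
calinski_harabasz <- function(X, partition) {
  X <- as.matrix(X)
  labels <- partition_labels(partition)
  n <- nrow(X); k <- max(labels)
  check_k(k, n)
  W <- within_ss(X, labels)
  Tss <- sum(sweep(X, 2, colMeans(X))^2)
  B <- Tss - W
  if (W == 0) {
    warning("zero within-cluster sum of squares; CH reported as Inf")
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio (S_i + S_j) / d(c_i, c_j), with
#' S the mean member-to-centroid distance and d the centroid distance;
#' minimised.
#'
#' @inheritParams within_ss
#' @return Non-negative scalar; coincident centroids are an error.
#' @export
davies_bouldin <- function(X, partition) {
  X <- as.matrix(X)
  labels <- partition_labels(partition)
  k <- max(labels)
  if (k < 2) stop("Davies-Bouldin needs k >= 2")
  cent <- rowsum(X, labels) / tabulate(labels, k)
  S <- vapply(seq_len(k), function(g) {
    xg <- X[labels == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xg, 2, cent[g, ])^2)))
  }, 0)
  dc <- as.matrix(stats::dist(cent))
  if (any(dc[upper.tri(dc)] == 0)) stop("Davies-Bouldin undefined: coincident centroids")
  mean(vapply(seq_len(k), function(i) {
    max(((S[i] + S[-i]) / dc[i, -i]))
  }, 0))
}

#' C-index
#'
#' (S - S_min) / (S_max - S_min), where S is the sum of within-cluster
#' pairwise distances over N_w pairs and S_min / S_max are the sums of the
#' N_w smallest / largest pairwise distances overall; minimised.
#'
#' @param D A `dist` object.
#' @param partition A partition or label vector.
#' @return Scalar in [0, 1].
#' @export
c_index <- function(D, partition) {
  labels <- partition_labels(partition)
  Dm <- as.matrix(D)
  ut <- upper.tri(Dm)
  within <- outer(labels, labels, "==") & ut
  nw <- sum(within)
  if (nw == 0) stop("C-index undefined: no within-cluster pairs")
  S <- sum(Dm[within])
  d_sorted <- sort(Dm[ut])
  smin <- sum(d_sorted[seq_len(nw)])
  smax <- sum(d_sorted[seq(length(d_sorted) - nw + 1, length(d_sorted))])
  if (smax == smin) stop("C-index undefined: all pairwise distances equal")
  (S - smin) / (smax - smin)
}

#' McClain-Rao index
#'
#' Mean within-cluster pair distance divided by mean between-cluster pair
#' distance; minimised.
#'
#' @inheritParams c_index
#' @return Positive scalar.
#' @export
mcclain_rao <- function(D, partition) {
  labels <- partition_labels(partition)
  Dm <- as.matrix(D)
  ut <- upper.tri(Dm)
  within <- outer(labels, labels, "==") & ut
  between <- (!outer(labels, labels, "==")) & ut
  if (!sum(within) || !sum(between)) stop("McClain-Rao needs both pair types")
  mean(Dm[within]) / mean(Dm[between])
}

index_rules <- c(ch = "max", db = "min", silhouette = "max", dunn = "max",
                 cindex = "min", mcclain = "min",
                 hartigan = "max_diff", kl = "max")

#' Multi-index battery over a k grid
#'
#' The second checkpoint: for one engine, computes eight internal indices
#' for every k in the grid — Calinski-Harabasz (max), Davies-Bouldin (min),
#' mean silhouette (max), Dunn (max), C-index (min), McClain-Rao (min),
#' Hartigan (vote at the largest drop of
#' H(k) = (W_k / W_(k+1) - 1)(n - k - 1)) and Krzanowski-Lai (max of
#' |DIFF_k| / |DIFF_(k+1)| with DIFF_k = (k-1)^(2/p) W_(k-1) -
#' k^(2/p) W_k). Hartigan and Krzanowski-Lai need neighbouring k and
#' abstain on a single-k grid. Indices undefined at some k are skipped.
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param engine Engine tag.
#' @param k_grid Candidate ks (within [2, n - 1]).
#' @param seed RNG seed.
#' @return A data.frame of class `index_scores`: columns `index`, `k`,
#'   `value`, `rule`, `chosen` (the k this index votes for).
#' @export
index_battery <- function(X, engine, k_grid = 2:10, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  k_grid <- sort(unique(k_grid[k_grid >= 2 & k_grid <= n - 1]))
  if (!length(k_grid)) stop("empty k grid")
  D <- feature_dist(X)
  k_all <- max(2, min(k_grid) - 1):min(n - 1, max(k_grid) + 1)
  parts <- lapply(k_all, function(k) fit_partition(X, engine, k, seed = seed))
  names(parts) <- k_all
  W <- vapply(parts, function(pt) within_ss(X, pt), 0)
  W1 <- sum(sweep(X, 2, colMeans(X))^2)
  Wk <- function(k) {
    if (k == 1) W1 else if (as.character(k) %in% names(W)) W[[as.character(k)]] else NA_real_
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- list()
  for (k in k_grid) {
    pt <- parts[[as.character(k)]]
    rows[[length(rows) + 1L]] <- data.frame(
      index = c("ch", "db", "silhouette", "dunn", "cindex", "mcclain"),
      k = k,
      value = c(safe(calinski_harabasz(X, pt)), safe(davies_bouldin(X, pt)),
                safe(silhouette_mean(D, pt)), safe(dunn_index(D, pt)),
                safe(c_index(D, pt)), safe(mcclain_rao(D, pt))),
      stringsAsFactors = FALSE
    )
  }
  if (length(k_grid) >= 2) {
    H <- function(k) {
      wk <- Wk(k); wk1 <- Wk(k + 1)
      if (is.na(wk) || is.na(wk1) || wk1 == 0) return(NA_real_)
      (wk / wk1 - 1) * (n - k - 1)
    }
    DIFF <- function(k) {
      wkm <- Wk(k - 1); wk <- Wk(k)
      if (is.na(wkm) || is.na(wk)) return(NA_real_)
      (k - 1)^(2 / p) * wkm - k^(2 / p) * wk
    }
    for (k in k_grid) {
      rows[[length(rows) + 1L]] <- data.frame(
        index = c("hartigan", "kl"), k = k,
        value = c(H(k), {
          dk <- DIFF(k); dk1 <- DIFF(k + 1)
          if (is.na(dk) || is.na(dk1) || dk1 == 0) NA_real_ else abs(dk) / abs(dk1)
        }),
        stringsAsFactors = FALSE
      )
    }
  }
  scores <- do.call(rbind, rows)
  scores$rule <- unname(index_rules[scores$index])
  scores$chosen <- FALSE
  for (idx in unique(scores$index)) {
    sel <- scores$index == idx & is.finite(scores$value)
    s <- scores[sel, , drop = FALSE]
    if (!nrow(s)) next
    pick <- switch(index_rules[[idx]],
      max = s$k[which.max(s$value)],
      min = s$k[which.min(s$value)],
      max_diff = {
        # largest drop H(k-1) - H(k); H below the grid uses the extended W
        Hprev <- vapply(s$k, function(k) {
          wkm <- Wk(k - 1); wk <- Wk(k)
          if (is.na(wkm) || is.na(wk) || wk == 0) NA_real_
          else (wkm / wk - 1) * (n - k)
        }, 0)
        drop <- Hprev - s$value
        if (all(is.na(drop))) NA_integer_ else s$k[which.max(drop)]
      }
    )
    if (!is.na(pick)) scores$chosen[scores$index == idx & scores$k == pick] <- TRUE
  }
  class(scores) <- c("index_scores", "data.frame")
  attr(scores, "engine") <- engine
  scores
}

#' Majority vote for the number of clusters
#'
#' Each index votes for the k its rule selects; indices with no defined
#' choice abstain. The modal k wins; ties are reported and, when a single
#' value is forced, broken toward the smaller k.
#'
#' @param scores An `index_scores` data.frame from [index_battery()].
#' @return A list of class `k_vote`: `choices` (per-index k), `tally`,
#'   `modal_k` (all co-winners), `k_forced`, `tie`.
#' @export
vote_for_k <- function(scores) {
  ch <- scores[scores$chosen, c("index", "k"), drop = FALSE]
  if (!nrow(ch)) stop("all indices abstained: no vote possible")
  tally <- sort(table(ch$k), decreasing = TRUE)
  modal <- sort(as.integer(names(tally)[tally == max(tally)]))
  structure(
    list(choices = ch,
         tally = data.frame(k = as.integer(names(tally)),
                            votes = as.integer(tally)),
         modal_k = modal, k_forced = modal[1], tie = length(modal) > 1),
    class = "k_vote"
  )
}

#' @export
print.k_vote <- function(x, ...) {
  cat("index vote over", nrow(x$choices), "indices:\n")
  print(x$tally, row.names = FALSE)
  cat(if (x$tie) "tied modal k:" else "modal k:", paste(x$modal_k, collapse = ", "), "\n")
  invisible(x)
}
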