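#' Connectivity validity measure
#'
#' Penalises nearest neighbours split across clusters: for every
#' observation i and its j-th nearest neighbour (Euclidean, ties broken by
#' observation index), add 1/j when the neighbour lies in a different
#' cluster. Lower is better; a partition whose clusters are
#' neighbourhood-closed scores 0.
#'
#' @param X Numeric matrix.
#' @param partition A partition or label vector.
#' @param L Neighbourhood size (default 10, clipped to n - 1).
#' @return Non-negative scalar.
#' @export
connectivity <- function(X, partition, L = 10) {
  X <- as.matrix(X)
  labels <- partition_labels(partition)
  n <- nrow(X)
  if (L >= n) stop("L must be smaller than n")
  Dm <- as.matrix(stats::dist(X))
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(Dm[i, -i], setdiff(seq_len(n), i))
    nbrs <- setdiff(seq_len(n), i)[ord][seq_len(L)]
    diff <- labels[nbrs] != labels[i]
    total <- total + sum((1 / seq_len(L))[diff])
  }
  total
}

#' Dunn index
#'
#' Minimum between-cluster point-pair distance divided by the maximum
#' within-cluster diameter. Scale invariant; higher is better.
#'
#' @param D A `dist` object.
#' @param partition A partition or label vector.
#' @return Positive scalar.
#' @export
dunn_index <- function(D, partition) {
  labels <- partition_labels(partition)
  k <- max(labels)
  if (k < 2) stop("Dunn index needs k >= 2")
  Dm <- as.matrix(D)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  max_diam <- max(Dm[same & !is.na(same)], -Inf)
  if (!is.finite(max_diam) || max_diam == 0) {
    stop("Dunn index undefined: maximum within-cluster diameter is zero")
  }
  min_sep <- min(Dm[!same & !is.na(same)])
  min_sep / max_diam
}

# Per-observation silhouette widths s(i) = (b - a) / max(a, b); singleton
# clusters and degenerate a = b = 0 both give s(i) = 0.
silhouette_widths <- function(D, labels) {
  Dm <- as.matrix(D)
  n <- length(labels)
  k <- max(labels)
  if (k < 2) stop("silhouette needs k >= 2")
  sizes <- tabulate(labels, k)
  # mean distance from each observation to each cluster
  agg <- vapply(seq_len(k), function(g) rowSums(Dm[, labels == g, drop = FALSE]), numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- agg[i, g] / (sizes[g] - 1)
    b <- min(agg[i, -g] / sizes[-g])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Mean silhouette width
#'
#' @param D A `dist` object.
#' @param partition A partition or label vector.
#' @return Scalar in [-1, 1].
#' @export
silhouette_mean <- function(D, partition) {
  mean(silhouette_widths(D, partition_labels(partition)))
}

#' Leave-one-column-out stability measures (APN, AD, ADM, FOM)
#'
#' Reclusters the data with each feature column removed (same engine, same
#' k, same seed) and compares against the full-data partition. With C0(i)
#' the full-data cluster of observation i and Cl(i) its cluster after
#' deleting column l:
#' \itemize{
#'   \item APN: mean over (i, l) of 1 - |C0(i) intersect Cl(i)| / |C0(i)|
#'     (average proportion of non-overlap, in [0, 1]).
#'   \item AD: mean over (i, l) of the average full-feature distance
#'     between all pairs (x, y), x in C0(i), y in Cl(i).
#'   \item ADM: mean over (i, l) of the full-feature distance between the
#'     centroids of C0(i) and Cl(i).
#'   \item FOM: mean over l of the root-mean within-cluster variance of the
#'     deleted column, clusters taken from the deleted-column partition,
#'     times the adjustment sqrt(n / (n - k)).
#' }
#' All four are minimised; a partition untouched by any column deletion
#' has APN = ADM = 0.
#'
#' @param X Numeric matrix (p >= 2 columns).
#' @param engine Engine tag, see [available_engines()].
#' @param k Number of clusters.
#' @param seed RNG seed shared between the full and reduced fits.
#' @return Named numeric vector `c(APN, AD, ADM, FOM)`; measures whose
#'   reduced fit failed are `NA` with a warning.
#' @export
stability_measures <- function(X, engine, k, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("stability measures need at least 2 feature columns")
  full <- fit_partition(X, engine, k, seed = seed)$labels
  Dm <- as.matrix(stats::dist(X))
  ind0 <- outer(full, seq_len(k), "==") * 1
  n0 <- colSums(ind0)
  cent0 <- crossprod(ind0, X) / n0
  apn_l <- ad_l <- adm_l <- fom_l <- rep(NA_real_, p)
  for (l in seq_len(p)) {
    red <- tryCatch(
      fit_partition(X[, -l, drop = FALSE], engine, k, seed = seed)$labels,
      error = function(e) NULL
    )
    if (is.null(red)) {
      warning("engine failed with column ", l, " removed; measures set to NA")
      next
    }
    kl <- max(red)
    indl <- outer(red, seq_len(kl), "==") * 1
    nl <- colSums(indl)
    tab <- crossprod(ind0, indl)                       # k x kl contingency
    # APN: observation (r, s) overlaps n_rs / n0_r
    apn_l[l] <- 1 - sum(tab^2 / n0) / n
    # AD: cross-cluster mean distances weighted by cell counts
    S <- crossprod(ind0, Dm %*% indl)                  # sum of d over (r0, sl) pairs
    meanD <- S / outer(n0, nl)
    ad_l[l] <- sum(tab * meanD) / n
    centl <- crossprod(indl, X) / nl
    cd <- as.matrix(stats::dist(rbind(cent0, centl)))[seq_len(k),
                                                      k + seq_len(kl),
                                                      drop = FALSE]
    adm_l[l] <- sum(tab * cd) / n
    within_means <- (crossprod(indl, X[, l]) / nl)[red]
    fom_l[l] <- sqrt(mean((X[, l] - within_means)^2)) * sqrt(n / (n - kl))
  }
  c(APN = mean(apn_l), AD = mean(ad_l), ADM = mean(adm_l), FOM = mean(fom_l))
}

validity_measure_directions <- c(
  connectivity = "minimize", dunn = "maximize", silhouette = "maximize",
  APN = "minimize", AD = "minimize", ADM = "minimize", FOM = "minimize"
)

#' Validity and stability screen over engines and cluster counts
#'
#' The first checkpoint of the selection protocol: computes internal
#' validity (connectivity, Dunn, mean silhouette) and leave-one-column-out
#' stability (APN, AD, ADM, FOM) for every engine and every k in the grid,
#' then applies the majority rule of [majority_rule()].
#'
#' @param X Numeric matrix or `symptom_matrix`.
#' @param engines Engine tags (default all four:
#'   k-means, hierarchical average and Ward, PAM).
#' @param k_grid Candidate cluster counts (default 2:10, clipped to n - 1).
#' @param L Connectivity neighbourhood size (default 10).
#' @param measures Which measures vote (default all seven).
#' @param seed RNG seed.
#' @return A `selection_report`: list with `scores` (long data.frame),
#'   `optima`, `votes` and `winner`; see [majority_rule()].
#' @export
validity_screen <- function(X, engines = available_engines(), k_grid = 2:10,
                            L = 10, measures = names(validity_measure_directions),
                            seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k_grid <- k_grid[k_grid >= 2 & k_grid <= n - 1]
  if (!length(k_grid)) stop("empty k grid after clipping to [2, n - 1]")
  measures <- match.arg(measures, names(validity_measure_directions),
                        several.ok = TRUE)
  D <- feature_dist(X)
  rows <- list()
  for (eng in engines) {
    for (k in k_grid) {
      p <- fit_partition(X, eng, k, seed = seed)
      vals <- c(
        connectivity = if ("connectivity" %in% measures) connectivity(X, p, L = min(L, n - 1)) else NA,
        dunn = if ("dunn" %in% measures) dunn_index(D, p) else NA,
        silhouette = if ("silhouette" %in% measures) silhouette_mean(D, p) else NA
      )
      if (any(c("APN", "AD", "ADM", "FOM") %in% measures)) {
        st <- suppressWarnings(stability_measures(X, eng, k, seed = seed))
        vals <- c(vals, st)
      }
      vals <- vals[measures]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = measures, algorithm = eng, k = k, value = unname(vals),
        direction = unname(validity_measure_directions[measures]),
        stringsAsFactors = FALSE
      )
    }
  }
  scores <- do.call(rbind, rows)
  majority_rule(scores)
}

#' Majority rule over validity and stability scores
#'
#' Every measure votes for the (algorithm, k) pair that optimises it in its
#' own direction; the winner is the modal vote. Ties are reported as
#' co-winners; when a single winner is forced downstream the tie is broken
#' by smaller k first, then by engine order k-means, hierarchical
#' (average, Ward), PAM.
#'
#' @param scores Long data.frame with columns `measure`, `algorithm`, `k`,
#'   `value`, `direction`.
#' @return A `selection_report` list: `scores`, `optima` (one row per
#'   measure), `votes` (tally), `winner` (co-winners data.frame),
#'   `winner_forced` (single row after tie-break), `tie` (logical).
#' @export
majority_rule <- function(scores) {
  if (!nrow(scores)) stop("empty score grid")
  measures <- unique(scores$measure)
  optima <- do.call(rbind, lapply(measures, function(m) {
    s <- scores[scores$measure == m & is.finite(scores$value), , drop = FALSE]
    if (!nrow(s)) return(NULL)
    best <- if (s$direction[1] == "minimize") min(s$value) else max(s$value)
    cand <- s[s$value == best, , drop = FALSE]
    cand <- cand[order(cand$k, engine_rank(cand$algorithm)), , drop = FALSE]
    cand[1, c("measure", "algorithm", "k", "value"), drop = FALSE]
  }))
  key <- paste(optima$algorithm, optima$k, sep = "|")
  tally <- sort(table(key), decreasing = TRUE)
  top <- names(tally)[tally == max(tally)]
  winner <- do.call(rbind, lapply(strsplit(top, "|", fixed = TRUE), function(w) {
    data.frame(algorithm = w[1], k = as.integer(w[2]), votes = max(tally),
               stringsAsFactors = FALSE)
  }))
  winner <- winner[order(winner$k, engine_rank(winner$algorithm)), , drop = FALSE]
  structure(
    list(scores = scores, optima = optima,
         votes = data.frame(candidate = names(tally), votes = as.integer(tally),
                            stringsAsFactors = FALSE),
         winner = winner, winner_forced = winner[1, , drop = FALSE],
         tie = nrow(winner) > 1),
    class = "selection_report"
  )
}

engine_rank <- function(engine) {
  match(engine, c("kmeans", "hclust_average", "hclust_ward", "pam"),
        nomatch = 99L)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("validity/stability screen over",
      length(unique(x$scores$algorithm)), "engine(s),",
      "k in {", paste(sort(unique(x$scores$k)), collapse = ", "), "}\n")
  cat("votes:\n")
  print(x$votes, row.names = FALSE)
  cat(if (x$tie) "co-winners (tie):\n" else "winner:\n")
  print(x$winner, row.names = FALSE)
  invisible(x)
}
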