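# Independent brute-force re-implementations of every statistic, written as
# plain loops over definitions. These never share code with the package
# internals they check.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracle_connectivity <- function(X, labels, L) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) euclid(X[i, ], X[j, ]))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    for (j in seq_len(L)) {
      if (labels[ord[j]] != labels[i]) total <- total + 1 / j
    }
  }
  total
}

oracle_dunn <- function(X, labels) {
  n <- nrow(X)
  min_between <- Inf; max_within <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- euclid(X[i, ], X[j, ])
    if (labels[i] == labels[j]) max_within <- max(max_within, d)
    else min_between <- min(min_between, d)
  }
  min_between / max_within
}

oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) euclid(X[i, ], X[j, ])))
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(sapply(which(labels == g), function(j) euclid(X[i, ], X[j, ])))
    }))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_wss <- function(X, labels) {
  total <- 0
  for (g in unique(labels)) {
    xg <- X[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    for (i in seq_len(nrow(xg))) total <- total + sum((xg[i, ] - cg)^2)
  }
  total
}

oracle_ch <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  W <- oracle_wss(X, labels)
  B <- oracle_wss(X, rep(1, n)) - W
  (B / (k - 1)) / (W / (n - k))
}

oracle_db <- function(X, labels) {
  ks <- sort(unique(labels)); k <- length(ks)
  cent <- lapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]))
  S <- sapply(ks, function(g) {
    mean(sapply(which(labels == g), function(i) euclid(X[i, ], cent[[g]])))
  })
  mean(sapply(seq_len(k), function(i) {
    max(sapply(setdiff(seq_len(k), i), function(j) {
      (S[i] + S[j]) / euclid(cent[[i]], cent[[j]])
    }))
  }))
}

oracle_cindex <- function(X, labels) {
  n <- nrow(X)
  d_all <- c(); d_within <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- euclid(X[i, ], X[j, ])
    d_all <- c(d_all, d)
    if (labels[i] == labels[j]) d_within <- c(d_within, d)
  }
  nw <- length(d_within)
  srt <- sort(d_all)
  (sum(d_within) - sum(srt[1:nw])) /
    (sum(rev(srt)[1:nw]) - sum(srt[1:nw]))
}

oracle_mcclain <- function(X, labels) {
  n <- nrow(X)
  w <- c(); b <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- euclid(X[i, ], X[j, ])
    if (labels[i] == labels[j]) w <- c(w, d) else b <- c(b, d)
  }
  mean(w) / mean(b)
}

# Leave-one-column-out stability, materializing every reduced clustering.
oracle_stability <- function(X, engine, k, seed) {
  n <- nrow(X); p <- ncol(X)
  full <- fit_partition(X, engine, k, seed = seed)$labels
  apn <- ad <- adm <- fom <- c()
  for (l in seq_len(p)) {
    red <- fit_partition(X[, -l, drop = FALSE], engine, k, seed = seed)$labels
    apn_i <- ad_i <- adm_i <- numeric(n)
    for (i in seq_len(n)) {
      c0 <- which(full == full[i]); cl <- which(red == red[i])
      apn_i[i] <- 1 - length(intersect(c0, cl)) / length(c0)
      dsum <- 0
      for (x in c0) for (y in cl) dsum <- dsum + euclid(X[x, ], X[y, ])
      ad_i[i] <- dsum / (length(c0) * length(cl))
      adm_i[i] <- euclid(colMeans(X[c0, , drop = FALSE]),
                         colMeans(X[cl, , drop = FALSE]))
    }
    apn <- c(apn, mean(apn_i)); ad <- c(ad, mean(ad_i)); adm <- c(adm, mean(adm_i))
    sq <- 0
    for (g in unique(red)) {
      members <- which(red == g)
      m <- mean(X[members, l])
      sq <- sq + sum((X[members, l] - m)^2)
    }
    fom <- c(fom, sqrt(sq / n) * sqrt(n / (n - k)))
  }
  c(APN = mean(apn), AD = mean(ad), ADM = mean(adm), FOM = mean(fom))
}

# Exhaustive PAM: best k-subset of medoids by total dissimilarity.
oracle_pam <- function(X, k) {
  n <- nrow(X)
  combos <- utils::combn(n, k)
  best_cost <- Inf; best_labels <- NULL
  for (c_i in seq_len(ncol(combos))) {
    med <- combos[, c_i]
    d_to_med <- sapply(med, function(m) {
      sapply(seq_len(n), function(i) euclid(X[i, ], X[m, ]))
    })
    cost <- sum(apply(d_to_med, 1, min))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best_labels <- apply(d_to_med, 1, which.min)
    }
  }
  list(cost = best_cost, labels = best_labels)
}

pam_cost <- function(X, labels, medoids) {
  sum(sapply(seq_len(nrow(X)), function(i) euclid(X[i, ], X[medoids[labels[i]], ])))
}

# Prediction strength of one split by explicit pair enumeration.
oracle_ps_split <- function(test_labels, train_class) {
  worst <- 1
  for (g in unique(test_labels)) {
    members <- which(test_labels == g)
    nj <- length(members)
    if (nj < 2) next
    same <- 0; pairs <- 0
    for (a in seq_len(nj - 1)) for (b in seq(a + 1, nj)) {
      pairs <- pairs + 1
      if (train_class[members[a]] == train_class[members[b]]) same <- same + 1
    }
    worst <- min(worst, same / pairs)
  }
  worst
}

# Benjamini-Hochberg step-up by definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    i <- ord[pos]
    cands <- sapply(pos:m, function(q) p[ord[q]] * m / q)
    adj[i] <- min(1, min(cands))
  }
  adj
}
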