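test_that("connectivity is zero for neighbourhood-closed partitions and counts split neighbours", {
  X <- make_blobs(rbind(c(0, 0), c(20, 20)), n_per = 8, sd = 0.3, seed = 6)
  expect_equal(connectivity(X, attr(X, "truth"), L = 5), 0)
  # interleaved 1-D: every nearest neighbour is in the other cluster
  X1 <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(connectivity(X1, c(1, 2, 1, 2), L = 1), 4.0)
  # non-negative and non-decreasing in L
  set.seed(12)
  Xr <- matrix(rnorm(24), ncol = 2)
  lab <- sample(1:2, 12, replace = TRUE)
  lab[1:2] <- 1:2
  vals <- sapply(1:8, function(L) connectivity(Xr, lab, L))
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("Dunn index matches hand distances and is scale invariant", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  D <- feature_dist(X)
  p <- c(1, 1, 2, 2)
  expect_equal(dunn_index(D, p), 9.0)
  expect_equal(dunn_index(feature_dist(X * 37), p), 9.0)
  expect_error(dunn_index(feature_dist(X), c(1, 2, 3, 4)), "diameter is zero")
})

test_that("silhouette matches the four-point hand computation and conventions", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  D <- feature_dist(X)
  s_hand <- ((10.5 - 1) / 10.5 + (9.5 - 1) / 9.5) / 2
  expect_equal(silhouette_mean(D, c(1, 1, 2, 2)), s_hand, tolerance = 1e-12)
  # identical duplicated points split across clusters: a = b = 0 -> s = 0
  Xd <- matrix(rep(c(1, 1), 4), ncol = 2, byrow = TRUE)
  expect_equal(silhouette_mean(feature_dist(Xd), c(1, 2, 1, 2)), 0)
  # bounds on random data
  set.seed(8)
  Xr <- matrix(rnorm(30), ncol = 3)
  lab <- c(1, 2, sample(1:2, 8, replace = TRUE))
  prof <- silhouette_profile(feature_dist(Xr), lab)
  expect_true(all(prof$s >= -1 & prof$s <= 1))
})

test_that("silhouette agrees with the cluster package's implementation", {
  set.seed(14)
  X <- matrix(rnorm(40), ncol = 2)
  lab <- c(1, 2, 3, sample(1:3, 17, replace = TRUE))
  D <- feature_dist(X)
  ours <- silhouette_mean(D, lab)
  ref <- mean(cluster::silhouette(lab, D)[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("validity measures are invariant to cluster relabelling", {
  set.seed(15)
  X <- matrix(rnorm(36), ncol = 2)
  lab <- c(1, 2, 3, sample(1:3, 15, replace = TRUE))
  relab <- c(3, 1, 2)[lab]
  D <- feature_dist(X)
  expect_equal(silhouette_mean(D, lab), silhouette_mean(D, relab))
  expect_equal(dunn_index(D, lab), dunn_index(D, relab))
  expect_equal(connectivity(X, lab, 5), connectivity(X, relab, 5))
})

test_that("stability measures vanish when column deletion leaves the partition unchanged", {
  X <- make_blobs(rbind(c(0, 0), c(9, 9)), n_per = 8, sd = 0.2, seed = 16)
  Xdup <- cbind(X, X)   # redundant columns: any single deletion is harmless
  st <- stability_measures(Xdup, "kmeans", 2, seed = 3)
  expect_equal(unname(st["APN"]), 0)
  expect_equal(unname(st["ADM"]), 0)
  expect_true(st["AD"] > 0)     # includes within-cluster spread even at perfect overlap
  expect_true(st["FOM"] > 0)
})

test_that("stability measures equal the brute-force leave-one-column-out oracle", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(6, 0, 0.4), 3, 2), matrix(rnorm(6, 4, 0.4), 3, 2))
    X <- cbind(X, rnorm(6, 2, 0.5))
    for (eng in c("kmeans", "hclust_average", "pam")) {
      got <- stability_measures(X, eng, 2, seed = seed)
      want <- oracle_stability(X, eng, 2, seed = seed)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the majority rule tallies measure votes and honours the tie contract", {
  grid <- expand.grid(algorithm = c("kmeans", "hclust_average", "pam"),
                      k = 2:3, stringsAsFactors = FALSE)
  mk <- function(measure, winner_alg, winner_k, direction = "maximize") {
    s <- merge(grid, data.frame(measure = measure, stringsAsFactors = FALSE))
    s$direction <- direction
    s$value <- ifelse(s$algorithm == winner_alg & s$k == winner_k, 10, 1)
    if (direction == "minimize") s$value <- -s$value
    s
  }
  scores <- rbind(mk("m1", "kmeans", 2), mk("m2", "kmeans", 2),
                  mk("m3", "kmeans", 2), mk("m4", "kmeans", 2),
                  mk("m5", "hclust_average", 2), mk("m6", "hclust_average", 2),
                  mk("m7", "pam", 3, "minimize"))
  rep <- majority_rule(scores)
  expect_equal(rep$winner_forced$algorithm, "kmeans")
  expect_equal(rep$winner_forced$k, 2L)
  expect_equal(sum(rep$votes$votes), 7)
  expect_false(rep$tie)
  # unanimous agreement
  rep2 <- majority_rule(rbind(mk("m1", "pam", 3), mk("m2", "pam", 3)))
  expect_equal(rep2$winner$votes, 2)
  # two-way tie: both reported, forced pick = smaller k then engine order
  rep3 <- majority_rule(rbind(mk("m1", "pam", 2), mk("m2", "kmeans", 3)))
  expect_true(rep3$tie)
  expect_equal(nrow(rep3$winner), 2)
  expect_equal(rep3$winner_forced$algorithm, "pam")
  expect_equal(rep3$winner_forced$k, 2L)
  expect_error(majority_rule(data.frame()), "empty")
})

test_that("the validity screen prefers the true blob structure", {
  X <- make_blobs(rbind(c(0, 0), c(8, 8)), n_per = 10, sd = 0.4, seed = 17)
  rep <- validity_screen(X, k_grid = 2:4, L = 4, seed = 17)
  expect_equal(rep$winner_forced$k, 2L)
  expect_equal(sum(rep$votes$votes), 7)
})
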