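test_that("Calinski-Harabasz matches the hand sums of squares and is translation invariant", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  p <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(X, p), 200.0)
  expect_equal(calinski_harabasz(X + 1000, p), 200.0)
  # true labels on separated blobs beat random labels
  Xb <- make_blobs(rbind(c(0, 0), c(10, 10)), n_per = 10, sd = 0.4, seed = 18)
  set.seed(18)
  rnd <- c(1, 2, sample(1:2, 18, replace = TRUE))
  expect_gt(calinski_harabasz(Xb, attr(Xb, "truth")), calinski_harabasz(Xb, rnd))
  expect_warning(calinski_harabasz(matrix(c(0, 0, 1, 1), ncol = 1), p), "Inf")
})

test_that("Davies-Bouldin matches the hand value, shrinks with tight clusters, stays non-negative", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(davies_bouldin(X, c(1, 1, 2, 2)), 0.1)
  Xtight <- matrix(c(0, 0.01, 10, 10.01), ncol = 1)
  expect_lt(davies_bouldin(Xtight, c(1, 1, 2, 2)), 0.01)
  set.seed(19)
  Xr <- matrix(rnorm(24), ncol = 2)
  lab <- c(1, 2, sample(1:2, 10, replace = TRUE))
  expect_gte(davies_bouldin(Xr, lab), 0)
  expect_error(davies_bouldin(rbind(X, X), rep(1:2, each = 4)), "coincident")
})

test_that("every battery index equals its brute-force oracle on seeded instances", {
  for (seed in c(41, 42, 43, 44)) {
    inst <- random_instance(seed, n = sample(8:12, 1), p = sample(2:3, 1),
                            k = sample(2:3, 1))
    X <- inst$X; lab <- inst$labels
    D <- feature_dist(X)
    expect_equal(calinski_harabasz(X, lab), oracle_ch(X, lab), tolerance = 1e-10)
    expect_equal(davies_bouldin(X, lab), oracle_db(X, lab), tolerance = 1e-10)
    expect_equal(silhouette_mean(D, lab), oracle_silhouette(X, lab), tolerance = 1e-10)
    expect_equal(dunn_index(D, lab), oracle_dunn(X, lab), tolerance = 1e-10)
    expect_equal(c_index(D, lab), oracle_cindex(X, lab), tolerance = 1e-10)
    expect_equal(mcclain_rao(D, lab), oracle_mcclain(X, lab), tolerance = 1e-10)
    expect_equal(within_ss(X, lab), oracle_wss(X, lab), tolerance = 1e-10)
    expect_equal(connectivity(X, lab, L = 4), oracle_connectivity(X, lab, 4),
                 tolerance = 1e-10)
  }
})

test_that("the index battery votes k = 3 on three separated blobs for every engine", {
  X <- make_blobs(rbind(c(0, 0), c(6, 0), c(3, 5)), n_per = 12, sd = 0.25,
                  seed = 20)
  for (eng in available_engines()) {
    scores <- index_battery(X, eng, k_grid = 2:6, seed = 20)
    v <- vote_for_k(scores)
    expect_equal(v$k_forced, 3L, info = eng)
    # the three named headline indices individually agree
    for (idx in c("ch", "silhouette", "dunn")) {
      expect_equal(scores$k[scores$index == idx & scores$chosen], 3L, info = idx)
    }
  }
})

test_that("Hartigan and Krzanowski-Lai abstain on a single-k grid", {
  X <- make_blobs(rbind(c(0, 0), c(5, 5)), n_per = 8, sd = 0.3, seed = 21)
  scores <- index_battery(X, "kmeans", k_grid = 2, seed = 21)
  expect_false(any(scores$index %in% c("hartigan", "kl")))
  v <- vote_for_k(scores)
  expect_equal(v$k_forced, 2L)
})

test_that("Hartigan is consistent with the within-SS sequence used by CH", {
  X <- make_blobs(rbind(c(0, 0), c(4, 4), c(8, 0)), n_per = 8, sd = 0.5, seed = 22)
  n <- nrow(X)
  scores <- index_battery(X, "kmeans", k_grid = 2:5, seed = 22)
  W <- sapply(2:6, function(k) within_ss(X, fit_partition(X, "kmeans", k, seed = 22)))
  names(W) <- 2:6
  for (k in 2:5) {
    h_direct <- (W[[as.character(k)]] / W[[as.character(k + 1)]] - 1) * (n - k - 1)
    expect_equal(scores$value[scores$index == "hartigan" & scores$k == k],
                 h_direct, tolerance = 1e-10)
  }
})

test_that("indices are invariant to observation reordering", {
  inst <- random_instance(51, n = 12, p = 2, k = 3)
  set.seed(51)
  perm <- sample(12)
  X <- inst$X; lab <- inst$labels
  D <- feature_dist(X); Dp <- feature_dist(X[perm, ])
  expect_equal(calinski_harabasz(X, lab), calinski_harabasz(X[perm, ], lab[perm]))
  expect_equal(c_index(D, lab), c_index(Dp, lab[perm]))
  expect_equal(mcclain_rao(D, lab), mcclain_rao(Dp, lab[perm]))
  expect_equal(dunn_index(D, lab), dunn_index(Dp, lab[perm]))
})

test_that("vote_for_k reports modal k, ties and single-index votes per contract", {
  mk <- function(index, ks, chosen_k, rule = "max") {
    data.frame(index = index, k = ks, value = as.numeric(ks == chosen_k),
               rule = rule, chosen = ks == chosen_k, stringsAsFactors = FALSE)
  }
  s5 <- rbind(mk("a", 2:3, 2), mk("b", 2:3, 2), mk("c", 2:3, 2),
              mk("d", 2:3, 2), mk("e", 2:3, 3))
  v <- vote_for_k(s5)
  expect_equal(v$modal_k, 2L)
  expect_equal(sum(v$tally$votes), 5)
  v2 <- vote_for_k(rbind(mk("a", 2:3, 2), mk("b", 2:3, 3)))
  expect_true(v2$tie)
  expect_equal(v2$modal_k, c(2L, 3L))
  expect_equal(v2$k_forced, 2L)
  v1 <- vote_for_k(mk("only", 2:4, 4))
  expect_equal(v1$modal_k, 4L)
  s_none <- mk("a", 2:3, 2); s_none$chosen <- FALSE
  expect_error(vote_for_k(s_none), "abstained")
})
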