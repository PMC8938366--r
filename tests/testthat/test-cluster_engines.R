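test_that("k-means recovers separated blobs and the enumerated 1-D optimum", {
  X <- make_blobs(rbind(c(0, 0), c(10, 10)), n_per = 20, sd = 0.3, seed = 2)
  p <- kmeans_fit(X, 2, seed = 1)
  expect_equal(p$labels, attr(X, "truth"))
  # {0, 1, 10, 11}: the optimal 2-partition (by enumeration) is {0,1}|{10,11}
  # with within-SS 0.5 + 0.5 = 1
  X1 <- matrix(c(0, 1, 10, 11), ncol = 1)
  p1 <- kmeans_fit(X1, 2, seed = 1)
  expect_equal(p1$labels, c(1, 1, 2, 2))
  expect_equal(attr(p1, "tot_withinss"), 1.0)
})

test_that("k-means is deterministic given a seed and its objective is monotone", {
  X <- make_blobs(rbind(c(0, 0), c(3, 3), c(0, 4)), n_per = 12, sd = 0.8, seed = 4)
  a <- kmeans_fit(X, 3, seed = 99)
  b <- kmeans_fit(X, 3, seed = 99)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
  # Lloyd iterations never increase the objective
  wss <- sapply(1:6, function(im) {
    set.seed(7)
    suppressWarnings(stats::kmeans(X, 3, iter.max = im, nstart = 1,
                                   algorithm = "Lloyd"))$tot.withinss
  })
  expect_true(all(diff(wss) <= 1e-8))
})

test_that("average-linkage agglomeration matches the hand-computed merge sequence", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  tree <- hclust_fit(feature_dist(X), "average")
  # (0,1) merge at 1, then 10 joins at (10 + 9)/2 = 9.5
  expect_equal(tree$height, c(1, 9.5))
  p <- cut_dendrogram(tree, 2)
  expect_equal(p$labels, c(1, 1, 2))
})

test_that("merge heights are non-decreasing for both linkages", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(30), ncol = 3)
    for (link in c("average", "ward")) {
      tree <- hclust_fit(feature_dist(X), link)
      expect_true(all(diff(tree$height) >= -1e-10))
    }
  }
})

test_that("ultrametric distances are a fixed point of average linkage", {
  set.seed(3)
  base <- hclust_fit(feature_dist(matrix(rnorm(16), ncol = 2)), "average")
  U <- stats::cophenetic(base)      # ultrametric by construction
  tree <- hclust_fit(U, "average")
  expect_equal(as.vector(stats::cophenetic(tree)), as.vector(U))
  expect_equal(cophenetic_correlation(U, tree), 1.0)
})

test_that("dendrogram cuts cover the trivial extremes and are nested", {
  set.seed(5)
  X <- matrix(rnorm(20), ncol = 2)
  tree <- hclust_fit(feature_dist(X), "ward")
  expect_equal(cut_dendrogram(tree, 1)$labels, rep(1L, 10))
  expect_equal(sort(unique(cut_dendrogram(tree, 10)$labels)), 1:10)
  for (k in 2:9) {
    fine <- cut_dendrogram(tree, k + 1)$labels
    coarse <- cut_dendrogram(tree, k)$labels
    # every fine cluster sits inside exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
})

test_that("PAM matches exhaustive medoid search on small instances", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  p <- pam_fit(feature_dist(X), 2, X = X)
  expect_equal(p$labels, c(1, 1, 2, 2))
  expect_equal(pam_cost(X, p$labels, attr(p, "medoids")), 2.0)
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    Xr <- matrix(rnorm(2 * n), ncol = 2)
    p <- pam_fit(feature_dist(Xr), k, X = Xr)
    expect_equal(pam_cost(Xr, p$labels, attr(p, "medoids")),
                 oracle_pam(Xr, k)$cost, tolerance = 1e-10)
  }
})

test_that("PAM with k = n - 1 isolates exactly the closest pair", {
  set.seed(21)
  X <- matrix(rnorm(12), ncol = 2)
  D <- as.matrix(feature_dist(X))
  diag(D) <- Inf
  closest <- which(D == min(D), arr.ind = TRUE)[1, ]
  p <- pam_fit(feature_dist(X), nrow(X) - 1, X = X)
  sizes <- tabulate(p$labels, p$k)
  expect_equal(sort(sizes, decreasing = TRUE)[1], 2L)
  expect_equal(sum(sizes == 1), nrow(X) - 2)
  expect_equal(p$labels[closest[1]], p$labels[closest[2]])
})

test_that("partitions are permutation-equivariant and canonically labelled", {
  set.seed(9)
  X <- make_blobs(rbind(c(0, 0), c(6, 6)), n_per = 6, sd = 0.2, seed = 9)
  perm <- sample(nrow(X))
  p <- pam_fit(feature_dist(X), 2, X = X)
  pp <- pam_fit(feature_dist(X[perm, ]), 2, X = X[perm, ])
  # same clusters as sets of subjects
  expect_equal(outer(p$labels[perm], p$labels[perm], "=="),
               outer(pp$labels, pp$labels, "=="))
  # canonical: label 1 is the cluster of observation 1, labels contiguous
  expect_equal(pp$labels[1], 1L)
  expect_equal(sort(unique(pp$labels)), seq_len(pp$k))
})
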