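test_that("the Shapiro-Wilk gate routes normal, skewed and degenerate data correctly", {
  set.seed(34)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(normality_gate(x, y), "parametric")
  skew <- exp(rnorm(50))
  expect_equal(normality_gate(x, skew), "nonparametric")
  expect_equal(normality_gate(x, y, alpha = 1), "nonparametric")
  expect_warning(gate <- normality_gate(rep(2, 10), y), "constant")
  expect_equal(gate, "nonparametric")
  expect_error(normality_gate(1:2, y), "n >= 3")
})

test_that("Mann-Whitney U, Z and r match the closed-form rank computation", {
  res <- mann_whitney_r(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$Z, (4.5 - 0.5) / sqrt(5.25), tolerance = 1e-10)
  expect_equal(res$r, res$Z / sqrt(6), tolerance = 1e-10)
  expect_gt(res$r, 0)   # second group is stochastically higher
})

test_that("Mann-Whitney r is antisymmetric, bounded and zero under identity", {
  set.seed(35)
  for (i in 1:5) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 15, replace = TRUE) + (i %% 2)
    a <- mann_whitney_r(x, y)
    b <- mann_whitney_r(y, x)
    expect_equal(a$r, -b$r, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_lte(abs(a$r), 1)
  }
  same <- mann_whitney_r(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$r, 0)
  ties <- mann_whitney_r(rep(4, 6), rep(4, 8))
  expect_equal(ties$p, 1)
  expect_equal(ties$r, 0)
})

test_that("Mann-Whitney normal approximation matches wilcox.test and the exact law", {
  set.seed(36)
  for (i in 1:6) {
    x <- rnorm(10); y <- rnorm(12, mean = 0.5)
    ours <- mann_whitney_r(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$U, unname(ref$statistic), tolerance = 1e-10)
    # exact enumeration (tie-free, n = 8 + 8): approximation within 0.02
    x8 <- rnorm(8); y8 <- rnorm(8, mean = i / 4)
    exact_p <- stats::wilcox.test(x8, y8, exact = TRUE)$p.value
    expect_lt(abs(mann_whitney_r(x8, y8)$p - exact_p), 0.02)
  }
})

test_that("Welch's t behaves at the identity, separation and scaling boundaries", {
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(37)
  lo <- rnorm(6, 0, 1e-4); hi <- rnorm(6, 1, 1e-4)
  expect_lt(welch_t(lo, hi)$p, 0.001)
  x <- rnorm(10); y <- rnorm(10, 1)
  a <- welch_t(x, y); b <- welch_t(2 * x, 2 * y)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$d, b$d, tolerance = 1e-12)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("chi-square association matches hand expected counts and the phi identity", {
  res <- chi_square_assoc(matrix(c(10, 20, 20, 10), 2), yates = FALSE)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-10)   # all E = 15
  expect_equal(res$effect, sqrt((20 / 3) / 60), tolerance = 1e-10)
  # phi^2 * N = chi2 on any uncorrected 2x2
  set.seed(38)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    r <- chi_square_assoc(tab, yates = FALSE)
    expect_equal(r$effect^2 * sum(tab), r$chi2, tolerance = 1e-10)
  }
  expect_error(chi_square_assoc(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero marginal")
  wide <- matrix(c(10, 12, 9, 11, 30, 5), 2, 3)
  rw <- chi_square_assoc(wide)
  expect_equal(rw$effect_type, "cramers_v")
  expect_equal(rw$df, 2)
})

test_that("BH adjustment equals the brute-force step-up and preserves p-value order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(39)
  for (i in 1:8) {
    p <- runif(sample(3:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("compare_groups routes tests, corrects within family, and is honest for one variable", {
  set.seed(40)
  n <- 60
  tab <- as_cohort_table(data.frame(
    subject_id = sprintf("s%02d", 1:n),
    PANSS_P2 = sample(1:7, n, TRUE), PANSS_N5 = sample(1:7, n, TRUE),
    SANS_9 = sample(0:5, n, TRUE), SANS_10 = sample(0:5, n, TRUE),
    SANS_12 = sample(0:5, n, TRUE),
    score_a = rnorm(n), score_b = c(rnorm(n / 2), rnorm(n / 2, 2)),
    cat_var = sample(c("x", "y"), n, TRUE)
  ))
  labels <- rep(1:2, each = n / 2)
  fams <- c(score_a = "one_var_family", score_b = "neuro", cat_var = "neuro")
  cmp <- compare_groups(tab, labels, families = fams)
  expect_equal(nrow(cmp), 3)
  one <- cmp[cmp$variable == "score_a", ]
  expect_equal(one$p_fdr, one$p_raw)
  expect_equal(cmp$test[cmp$variable == "cat_var"], "chi_square")
  expect_lt(cmp$p_fdr[cmp$variable == "score_b"], 0.001)
  expect_gt(cmp$effect[cmp$variable == "score_b"], 0)  # group 2 higher -> positive
  expect_error(compare_groups(tab, rep(1:3, length.out = n), families = fams),
               "k = 2")
})

test_that("effect signs follow the second-group-lower convention", {
  set.seed(41)
  x_high <- rnorm(40, 5); y_low <- rnorm(40, 3)
  expect_lt(mann_whitney_r(x_high, y_low)$r, 0)
  expect_lt(welch_t(x_high, y_low)$d, 0)
  expect_gt(mann_whitney_r(y_low, x_high)$r, 0)
})

test_that("correlograms recover planted rank correlation and handle exact anticorrelation", {
  set.seed(42)
  n <- 200
  z <- rnorm(n)
  tab <- as_cohort_table(data.frame(
    subject_id = sprintf("s%03d", 1:n),
    PANSS_P2 = sample(1:7, n, TRUE), PANSS_N5 = sample(1:7, n, TRUE),
    SANS_9 = sample(0:5, n, TRUE), SANS_10 = sample(0:5, n, TRUE),
    SANS_12 = sample(0:5, n, TRUE),
    v1 = z, v2 = 0.5 * scale(rank(z))[, 1] + sqrt(1 - 0.25) * rnorm(n),
    v3 = -z
  ))
  labels <- rep(1, n)
  cg <- correlogram(tab, labels, c("v1", "v2", "v3"), method = "spearman")
  g <- cg$group1
  expect_equal(unname(diag(g$r)), c(1, 1, 1))
  expect_equal(g$r["v1", "v3"], -1)
  expect_lt(abs(g$r["v1", "v2"] - 0.5), 0.1)
  expect_true(isSymmetric(g$p_fdr))
  # the three off-diagonal pairs are the FDR family; diagonal excluded
  expect_equal(g$p_fdr["v1", "v2"],
               bh_fdr(c(g$p_raw["v1", "v2"], g$p_raw["v1", "v3"],
                        g$p_raw["v2", "v3"]))[1])
})
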