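# Gaussian blob fixtures and tiny cohort tables, built in code.

make_blobs <- function(centers, n_per = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[i, ], "+")
  }))
  attr(X, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  X
}

tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("a", "b", "c"),
    PANSS_P2 = c(1, 4, 7), PANSS_N5 = c(2, 3, 5),
    SANS_9 = c(0, 2, 5), SANS_10 = c(1, 3, 4), SANS_12 = c(0, 1, 5),
    stringsAsFactors = FALSE
  )
}

write_tiny_cohort <- function(df = tiny_cohort_df()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Small seeded random instances for the oracle-equivalence suites.
random_instance <- function(seed, n = 10, p = 2, k = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  labels <- sample(rep(seq_len(k), length.out = n))
  list(X = X, labels = labels)
}
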