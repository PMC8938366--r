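#' Normality gate for two-group comparisons
#'
#' Shapiro-Wilk on each group: the comparison is routed to a parametric
#' test (Welch) only when both groups look normal (p >= alpha in both),
#' otherwise to the Mann-Whitney U test. Constant vectors are routed
#' nonparametric with a warning.
#'
#' @param x,y Numeric vectors, each with n >= 3 (Shapiro-Wilk's domain;
#'   groups above 5000 are subsampled is not supported here — clinical
#'   cohorts are far smaller).
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) stop("each group needs n >= 3")
  pvals <- vapply(list(x, y), function(v) {
    if (stats::sd(v) == 0) {
      warning("constant vector: routed nonparametric")
      return(0)
    }
    stats::shapiro.test(v)$p.value
  }, 0)
  if (all(pvals >= alpha)) "parametric" else "nonparametric"
}

#' Mann-Whitney U test with rank effect size r
#'
#' U from rank sums with midranks for ties; Z from the normal
#' approximation with tie-corrected variance and (by default) continuity
#' correction; two-sided p; effect size r = |Z| / sqrt(n_x + n_y), signed
#' negative when the second group `y` is stochastically lower than `x`
#' (so with `x` = reference group and `y` = deficit group, deficits print
#' as negative r, the field's reporting convention).
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @param continuity Apply the 0.5 continuity correction (default TRUE).
#' @return List with `U`, `Z`, `p`, `r`, `n`, `median_x`, `median_y`.
#' @export
mann_whitney_r <- function(x, y, continuity = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both groups need at least one value")
  N <- nx + ny
  r_all <- rank(c(x, y))
  U <- sum(r_all[seq_len(nx)]) - nx * (nx + 1) / 2   # number of (x > y) pairs, ties half
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    out <- list(U = U, Z = 0, p = 1, r = 0, n = N,
                median_x = stats::median(x), median_y = stats::median(y))
    return(out)
  }
  dev <- abs(U - mu)
  cc <- if (continuity) min(0.5, dev) else 0
  Z <- (dev - cc) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-Z))
  sgn <- if (U > mu) -1 else if (U < mu) 1 else 0
  list(U = U, Z = Z, p = p, r = sgn * Z / sqrt(N), n = N,
       median_x = stats::median(x), median_y = stats::median(y))
}

#' Welch two-sample t test with Cohen's d
#'
#' Welch statistic with Satterthwaite degrees of freedom; Cohen's d uses
#' the pooled SD. Sign convention matches [mann_whitney_r()]: d < 0 when
#' the second group `y` has the lower mean.
#'
#' @param x,y Numeric vectors (NAs dropped), each n >= 2.
#' @return List with `t`, `df`, `p`, `d`, means.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1, d = 0,
                                        mean_x = mean(x), mean_y = mean(y)))
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  # d > 0 when x exceeds y; flip so y-lower prints negative like r
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = -d,
       mean_x = mean(x), mean_y = mean(y))
}

#' Upper-tail chi-square probability
#'
#' @param statistic Chi-square statistic.
#' @param df Degrees of freedom.
#' @return Upper-tail probability.
#' @export
chisq_tail_p <- function(statistic, df) {
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Phi coefficient from a 2x2 chi-square
#'
#' phi = sqrt(chi2 / N).
#'
#' @param statistic Chi-square statistic.
#' @param n Total count.
#' @return Non-negative scalar.
#' @export
phi_coefficient <- function(statistic, n) sqrt(statistic / n)

#' Cramer's V from a chi-square
#'
#' V = sqrt(chi2 / (N * (min(r, c) - 1))); reduces to phi for 2 x c tables.
#'
#' @param statistic Chi-square statistic.
#' @param n Total count.
#' @param dims Table dimensions `c(r, c)`.
#' @return Non-negative scalar.
#' @export
cramers_v <- function(statistic, n, dims) {
  sqrt(statistic / (n * (min(dims) - 1)))
}

#' Chi-square test of association with effect size
#'
#' Pearson chi-square on an r x c count table, Yates continuity correction
#' by default for 2 x 2; effect size is phi for 2 x 2 and Cramer's V
#' otherwise. For any 2 x 2 table the uncorrected statistic satisfies
#' phi^2 * N = chi2 exactly.
#'
#' @param tab Count matrix (at least 2 x 2, non-negative, no zero
#'   marginals).
#' @param yates Continuity correction for 2 x 2 tables (default TRUE).
#' @return List with `chi2`, `df`, `p`, `effect` and `effect_type`
#'   (`"phi"` or `"cramers_v"`).
#' @export
chi_square_assoc <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal: association undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  N <- sum(tab)
  is2x2 <- nrow(tab) == 2 && ncol(tab) == 2
  eff <- if (is2x2) phi_coefficient(unname(ct$statistic), N)
         else cramers_v(unname(ct$statistic), N, dim(tab))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), effect = eff,
       effect_type = if (is2x2) "phi" else "cramers_v")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, adj_(i) =
#' min(1, min over j >= i of p_(j) * m / j), original order restored.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order; always >= the raw values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Default variable families for FDR correction
#'
#' Three families corrected separately: sociodemographic (age, sex,
#' education, site), clinical functioning (the eight GF-Social / GF-Role
#' variants) and neurocognition (six test scores).
#'
#' @return Named character vector mapping variable name to family.
#' @export
default_families <- function() {
  c(age = "sociodemographic", sex = "sociodemographic",
    education_years = "sociodemographic", site = "sociodemographic",
    gfs_high_lifetime = "clinical", gfs_high_pastyear = "clinical",
    gfs_low_pastyear = "clinical", gfs_current = "clinical",
    gfr_high_lifetime = "clinical", gfr_high_pastyear = "clinical",
    gfr_low_pastyear = "clinical", gfr_current = "clinical",
    wais_vocabulary = "neurocognition", wais_matrices = "neurocognition",
    fluency_phonological = "neurocognition", fluency_semantic = "neurocognition",
    digit_forward = "neurocognition", digit_backward = "neurocognition")
}

#' Two-group comparison of validation variables
#'
#' For every variable: categorical variables go to the chi-square test of
#' association; numeric variables pass the Shapiro-Wilk gate and go to
#' Welch's t (both groups normal) or Mann-Whitney U otherwise.
#' Benjamini-Hochberg FDR is applied within each declared family
#' separately. Group 1 is the reference (first-listed) group, group 2 the
#' comparison group; rank r and Cohen's d are negative when group 2 is
#' lower.
#'
#' @param tab A `cohort_table`.
#' @param partition A two-cluster partition (or label vector) aligned with
#'   the rows of `tab`; rows without a label (e.g. excluded from
#'   clustering) can be marked `NA` and are dropped.
#' @param families Named character vector variable -> family; defaults to
#'   [default_families()] restricted to columns present.
#' @param alpha Shapiro-Wilk gate level (default 0.05).
#' @return A data.frame of class `group_comparison`: one row per variable
#'   with `family`, `test`, `statistic`, `z`, `p_raw`, `p_fdr`, `effect`,
#'   `effect_type` and per-group medians (or top-level proportions for
#'   categoricals).
#' @export
compare_groups <- function(tab, partition, families = NULL, alpha = 0.05) {
  labels <- if (inherits(partition, "partition")) partition$labels else as.integer(partition)
  if (length(labels) != nrow(tab)) stop("partition length must match table rows")
  keep <- !is.na(labels)
  tab <- tab[keep, , drop = FALSE]
  labels <- labels[keep]
  ks <- sort(unique(labels))
  if (length(ks) != 2) {
    stop("compare_groups is defined for k = 2 subgroups; got k = ", length(ks),
         " (pairwise mode is out of scope)")
  }
  if (is.null(families)) {
    families <- default_families()
    families <- families[names(families) %in% names(tab)]
  }
  if (!length(families)) stop("no variables to compare")
  g1 <- labels == ks[1]; g2 <- labels == ks[2]
  rows <- lapply(names(families), function(v) {
    vals <- tab[[v]]
    base <- data.frame(variable = v, family = unname(families[[v]]),
                       stringsAsFactors = FALSE)
    if (is.character(vals) || is.factor(vals) || is.logical(vals)) {
      ct <- table(factor(labels[!is.na(vals)]), vals[!is.na(vals)])
      res <- chi_square_assoc(as.matrix(ct))
      base$test <- "chi_square"; base$statistic <- res$chi2
      base$z <- NA_real_; base$p_raw <- res$p
      base$effect <- res$effect; base$effect_type <- res$effect_type
      base$group1 <- NA_real_; base$group2 <- NA_real_
    } else {
      x <- vals[g1]; y <- vals[g2]
      gate <- tryCatch(normality_gate(x[!is.na(x)], y[!is.na(y)], alpha = alpha),
                       warning = function(w) "nonparametric")
      if (gate == "parametric") {
        res <- welch_t(x, y)
        base$test <- "welch_t"; base$statistic <- res$t
        base$z <- NA_real_; base$p_raw <- res$p
        base$effect <- res$d; base$effect_type <- "cohens_d"
      } else {
        res <- mann_whitney_r(x, y)
        base$test <- "mann_whitney"; base$statistic <- res$U
        base$z <- res$Z; base$p_raw <- res$p
        base$effect <- res$r; base$effect_type <- "rank_r"
      }
      base$group1 <- stats::median(x, na.rm = TRUE)
      base$group2 <- stats::median(y, na.rm = TRUE)
    }
    base
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
  }
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' FDR-corrected correlation matrices per subgroup
#'
#' Pairwise correlations (Spearman by default, appropriate for ordinal
#' symptom and functioning scales) over pairwise-complete observations,
#' computed within each subgroup, with two-sided p-values and
#' Benjamini-Hochberg FDR across the unique off-diagonal pairs of each
#' subgroup's matrix separately. Variables with fewer than 3 complete
#' pairings against everything get an NA row.
#'
#' @param tab A `cohort_table`.
#' @param partition A partition or label vector (NA rows dropped).
#' @param variables Columns to correlate (>= 2).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Named list (one element per subgroup) of lists with `r`,
#'   `p_raw`, `p_fdr` matrices, `n`, `method`.
#' @export
correlogram <- function(tab, partition, variables,
                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(variables) < 2) stop("need at least 2 variables")
  labels <- if (inherits(partition, "partition")) partition$labels else as.integer(partition)
  keep <- !is.na(labels)
  tab <- tab[keep, , drop = FALSE]; labels <- labels[keep]
  out <- lapply(sort(unique(labels)), function(g) {
    sub <- as.data.frame(tab)[labels == g, variables, drop = FALSE]
    m <- length(variables)
    r <- p <- matrix(NA_real_, m, m, dimnames = list(variables, variables))
    diag(r) <- 1; diag(p) <- 0
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        ok <- stats::complete.cases(sub[[i]], sub[[j]])
        if (sum(ok) < 3) next
        ct <- suppressWarnings(
          stats::cor.test(sub[[i]][ok], sub[[j]][ok], method = method,
                          exact = FALSE)
        )
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
    padj <- matrix(NA_real_, m, m, dimnames = dimnames(p))
    diag(padj) <- 0
    ut <- which(upper.tri(p) & !is.na(p))
    if (length(ut)) {
      padj[ut] <- bh_fdr(p[ut])
      padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    }
    list(r = r, p_raw = p, p_fdr = padj, n = nrow(sub), method = method)
  })
  names(out) <- paste0("group", sort(unique(labels)))
  out
}
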