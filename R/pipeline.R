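#' Configure a protocol run
#'
#' Collects every tunable of the four-checkpoint protocol in one
#' serializable list. Supply either `cohort` (an in-memory table),
#' `cohort_path` (a CSV in the [read_cohort()] dialect) or `generator`
#' (a [generator_spec()]); exactly one is used, in that order of
#' precedence.
#'
#' @param cohort Optional `cohort_table` or data.frame.
#' @param cohort_path Optional CSV path.
#' @param generator Optional [generator_spec()].
#' @param items Feature columns to cluster on (default: the five-item FTD
#'   schema).
#' @param scaling Feature scaling (default `"range_unit"`).
#' @param engines Engines screened at checkpoint one.
#' @param k_grid Cluster-count grid (default 2:10).
#' @param iterations Prediction-strength half-split iterations
#'   (default 500).
#' @param threshold Prediction-strength retention cutoff (default 0.80).
#' @param st_replicates Bootstrap replicates for the ST indices
#'   (default 100).
#' @param families FDR families for [compare_groups()].
#' @param correlogram_method `"spearman"` or `"pearson"`.
#' @param seed Master seed; per-stage sub-seeds are derived from it
#'   deterministically (seed + 1, + 2, ... by stage order) so stages can
#'   be rerun in isolation.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, cohort_path = NULL, generator = NULL,
                            items = NULL, scaling = "range_unit",
                            engines = available_engines(), k_grid = 2:10,
                            iterations = 500, threshold = 0.80,
                            st_replicates = 100, families = NULL,
                            correlogram_method = "spearman",
                            seed = 1L, out_dir = NULL) {
  if (is.null(cohort) && is.null(cohort_path) && is.null(generator)) {
    stop("config error: supply one of cohort, cohort_path or generator")
  }
  if (!length(engines)) stop("config error: empty engine list")
  engines <- match.arg(engines, available_engines(), several.ok = TRUE)
  structure(
    list(cohort = cohort, cohort_path = cohort_path, generator = generator,
         items = items, scaling = scaling, engines = engines,
         k_grid = k_grid, iterations = iterations, threshold = threshold,
         st_replicates = st_replicates, families = families,
         correlogram_method = correlogram_method,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage_seed <- function(config, stage) {
  config$seed + c(screen = 1L, vote = 2L, st = 3L, ps = 4L, final = 5L)[[stage]]
}

#' Run the four-checkpoint selection protocol end to end
#'
#' Executes, in order: cohort construction and feature scaling; the
#' validity/stability screen with its majority rule (checkpoint i); the
#' multi-index k vote on the winning engine (checkpoint ii); robustness
#' diagnostics — cophenetic correlation and silhouette profile for
#' hierarchical candidates, bootstrap ST indices for the partitioning
#' winner (checkpoint iii); the cross-validated prediction-strength curve
#' with the retention rule (checkpoint iv); then the downstream validation
#' layer (two-group comparisons with family-wise FDR, correlograms, and
#' the 2-D principal-component projection). Clusters of the final
#' partition are ordered by mean scaled symptom severity, so cluster 1 is
#' the Low and cluster 2 the High subgroup.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `cohort`, `X`,
#'   `screen`, `vote`, `robustness`, `ps`, `final_k`, `final_engine`,
#'   `partition`, `comparisons`, `correlograms`, `pca`, `recovery` (when a
#'   generator supplied ground truth), `manifest`. Artifacts are written
#'   under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$cohort)) {
    cohort <- as_cohort_table(as.data.frame(config$cohort))
  } else if (!is.null(config$cohort_path)) {
    cohort <- read_cohort(config$cohort_path)
  } else {
    gen <- generate_cohort(config$generator)
    cohort <- gen$cohort
    truth <- gen$truth
  }
  X <- build_feature_matrix(cohort, items = config$items, scaling = config$scaling)

  screen <- validity_screen(X, engines = config$engines, k_grid = config$k_grid,
                            seed = stage_seed(config, "screen"))
  winner <- screen$winner_forced

  battery <- index_battery(X, winner$algorithm, k_grid = config$k_grid,
                           seed = stage_seed(config, "vote"))
  vote <- vote_for_k(battery)
  final_k <- vote$k_forced
  final_engine <- winner$algorithm

  robust <- list()
  D <- feature_dist(X)
  hier <- intersect(config$engines, c("hclust_average", "hclust_ward"))
  for (h in hier) {
    tree <- hclust_fit(D, sub("hclust_", "", h))
    robust[[h]] <- list(
      cophenetic = cophenetic_correlation(D, tree),
      silhouette = silhouette_profile(D, cut_dendrogram(tree, final_k))
    )
  }
  part_engine <- pick_partitioning_engine(final_engine, screen)
  robust$st <- st_indices(X, part_engine, final_k, B = config$st_replicates,
                          seed = stage_seed(config, "st"))

  ps <- ps_curve(X, engine = part_engine, k_grid = config$k_grid,
                 iterations = config$iterations, threshold = config$threshold,
                 seed = stage_seed(config, "ps"))
  if (!is.na(ps$retained_k)) final_k <- ps$retained_k

  partition <- fit_partition(X, part_engine, final_k,
                             seed = stage_seed(config, "final"))
  partition <- order_by_severity(partition, X)

  labels_full <- rep(NA_integer_, nrow(cohort))
  labels_full[match(rownames(X), cohort$subject_id)] <- partition$labels

  comparisons <- correlograms <- recovery <- NULL
  if (final_k == 2) {
    fams <- config$families %||% {
      f <- default_families(); f[names(f) %in% names(cohort)]
    }
    if (length(fams)) {
      comparisons <- compare_groups(cohort, labels_full, families = fams)
      corr_vars <- c(colnames(X),
                     names(fams)[fams %in% c("clinical", "neurocognition")])
      corr_vars <- intersect(corr_vars, names(cohort))
      if (length(corr_vars) >= 2) {
        correlograms <- correlogram(cohort, labels_full, corr_vars,
                                    method = config$correlogram_method)
      }
    }
  }
  pca <- pca_projection(X, partition)
  if (!is.null(truth)) {
    tr <- truth[match(rownames(X), truth$subject_id), ]
    recovery <- recovery_score(partition, tr)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ftdclust")),
    seed = config$seed, scaling = config$scaling, engines = config$engines,
    k_grid = config$k_grid, iterations = config$iterations,
    threshold = config$threshold,
    screen_winner = winner, index_vote_k = vote$k_forced,
    retained_k = ps$retained_k, final_k = final_k,
    final_engine = final_engine, global_st = robust$st$global_st
  )
  result <- structure(
    list(cohort = cohort, X = X, screen = screen, battery = battery,
         vote = vote, robustness = robust, ps = ps,
         final_k = final_k, final_engine = final_engine,
         partition = partition, labels = labels_full,
         comparisons = comparisons, correlograms = correlograms,
         pca = pca, recovery = recovery, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

# The generalizability checkpoint needs an engine that can classify new
# points (centroid or medoid); when the screen winner is hierarchical, the
# partitioning engine with the most screen-optimum support steps in
# (ties toward k-means, the engine preference order).
pick_partitioning_engine <- function(final_engine, screen) {
  if (final_engine %in% c("kmeans", "pam")) return(final_engine)
  support <- table(factor(screen$optima$algorithm, levels = c("kmeans", "pam")))
  names(support)[order(-support, engine_rank(names(support)))][1]
}

# Relabel a partition so clusters are ordered by increasing mean feature
# severity (cluster 1 = least severe).
order_by_severity <- function(partition, X) {
  sev <- rowMeans(as.matrix(X))
  cluster_sev <- tapply(sev, partition$labels, mean)
  ord <- order(cluster_sev)
  relab <- match(partition$labels, ord)
  centers <- if (!is.null(partition$centers)) {
    partition$centers[ord, , drop = FALSE]
  }
  out <- structure(list(labels = as.integer(relab), k = partition$k,
                        algorithm = partition$algorithm, centers = centers),
                   class = "partition")
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$screen$scores,
                   file.path(out_dir, "validity_scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$battery),
                   file.path(out_dir, "index_battery.csv"), row.names = FALSE)
  utils::write.csv(data.frame(k = result$ps$k, mean_ps = result$ps$mean_ps,
                              sd_ps = result$ps$sd_ps),
                   file.path(out_dir, "ps_curve.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = result$cohort$subject_id,
                              cluster = result$labels),
                   file.path(out_dir, "partition.csv"), row.names = FALSE)
  if (!is.null(result$comparisons)) {
    utils::write.csv(as.data.frame(result$comparisons),
                     file.path(out_dir, "group_comparisons.csv"), row.names = FALSE)
  }
  utils::write.csv(data.frame(subject_id = rownames(result$X),
                              result$pca$coords,
                              cluster = result$partition$labels),
                   file.path(out_dir, "pca_projection.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("four-checkpoint selection protocol\n")
  cat("  screen winner: ", x$manifest$screen_winner$algorithm,
      ", k = ", x$manifest$screen_winner$k, "\n", sep = "")
  cat("  index vote k: ", x$manifest$index_vote_k, "\n", sep = "")
  cat("  global ST: ", round(x$manifest$global_st, 3), "\n", sep = "")
  cat("  retained k (prediction strength): ", x$manifest$retained_k, "\n", sep = "")
  cat("  final: ", x$final_engine, ", k = ", x$final_k, "\n", sep = "")
  invisible(x)
}

#' Two-dimensional principal-component projection
#'
#' First two principal components of the column-centred feature matrix,
#' with variance-explained fractions, for the standard cluster scatter
#' plot. Rank-1 data get a zero-filled second component with a warning.
#'
#' @param X Numeric matrix or `symptom_matrix` (p >= 2).
#' @param partition Optional partition; labels are attached to the
#'   coordinates.
#' @return List with `coords` (n x 2, columns PC1/PC2), `var_explained`
#'   (length 2) and `cluster` (labels or NULL).
#' @export
pca_projection <- function(X, partition = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("PCA projection needs p >= 2")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (ncol(pc$x) < 2 || pc$sdev[2] < 1e-8 * pc$sdev[1]) {
    warning("feature matrix has rank < 2; second component zero-filled")
    coords <- cbind(PC1 = pc$x[, 1], PC2 = 0)
    ve <- c(ve[1], 0)
  } else {
    coords <- pc$x[, 1:2]
    colnames(coords) <- c("PC1", "PC2")
    ve <- ve[1:2]
  }
  list(coords = coords, var_explained = ve,
       cluster = if (!is.null(partition)) partition_labels(partition))
}

#' Specificity rerun on an alternative feature set
#'
#' Reruns the stability and generalizability checkpoints on a different
#' set of feature columns (e.g. non-FTD symptom items, or pure noise) and
#' reports them side by side with the main features, so claims that the
#' main solution is *specifically* supported by its features can be
#' evaluated: a less informative feature set should show a lower global
#' ST index and lower mean prediction strength.
#'
#' @param config A [pipeline_config()].
#' @param alternative_features Column names of the alternative feature
#'   set; must exist in the cohort.
#' @param k Cluster count compared on both sides (default 2).
#' @return A data.frame with one row per feature set: `global_st`,
#'   `mean_ps_k`, plus settings.
#' @export
sanity_rerun <- function(config, alternative_features, k = 2) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$cohort)) {
    cohort <- as_cohort_table(as.data.frame(config$cohort))
  } else if (!is.null(config$cohort_path)) {
    cohort <- read_cohort(config$cohort_path)
  } else {
    cohort <- generate_cohort(config$generator)$cohort
  }
  missing_cols <- setdiff(alternative_features, names(cohort))
  if (length(missing_cols)) {
    stop("config error: alternative feature(s) not in cohort: ",
         paste(missing_cols, collapse = ", "))
  }
  main_items <- config$items %||% item_names(attr(cohort, "schema"))
  one_side <- function(items, scaling) {
    Xs <- if (all(items %in% item_names(attr(cohort, "schema")))) {
      build_feature_matrix(cohort, items = items, scaling = scaling)
    } else {
      m <- as.matrix(as.data.frame(cohort)[, items, drop = FALSE])
      storage.mode(m) <- "double"
      m <- m[stats::complete.cases(m), , drop = FALSE]
      m
    }
    st <- st_indices(Xs, "kmeans", k, B = config$st_replicates,
                     seed = stage_seed(config, "st"))
    ps <- ps_curve(Xs, engine = "kmeans", k_grid = k,
                   iterations = config$iterations,
                   threshold = config$threshold,
                   seed = stage_seed(config, "ps"))
    data.frame(features = paste(items, collapse = "+"),
               global_st = st$global_st,
               mean_ps_k = ps$mean_ps[ps$k == k],
               k = k, stringsAsFactors = FALSE)
  }
  rbind(cbind(set = "main", one_side(main_items, config$scaling)),
        cbind(set = "alternative", one_side(alternative_features, config$scaling)))
}
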