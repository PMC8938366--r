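#' Define an ordinal symptom item
#'
#' An item definition names one clustering feature and declares the
#' instrument it comes from and its theoretical score range. The range is
#' used both for validation on input and for range-unit scaling.
#'
#' @param name Column name of the item in a cohort table.
#' @param instrument One of `"PANSS"`, `"SANS"`, `"OTHER"`. PANSS items are
#'   scored 1-7, SANS items 0-5; these ranges are enforced.
#' @param min_score,max_score Theoretical score range. For PANSS and SANS
#'   instruments the range is filled in automatically and checked.
#' @return An object of class `item_def`.
#' @export
#' @examples
#' item_def("PANSS_P2", "PANSS")
#' item_def("SANS_9", "SANS")
item_def <- function(name, instrument = c("PANSS", "SANS", "OTHER"),
                     min_score = NULL, max_score = NULL) {
  instrument <- match.arg(instrument)
  defaults <- switch(instrument,
    PANSS = c(1L, 7L),
    SANS  = c(0L, 5L),
    OTHER = c(NA_integer_, NA_integer_)
  )
  if (is.null(min_score)) min_score <- defaults[1]
  if (is.null(max_score)) max_score <- defaults[2]
  if (is.na(min_score) || is.na(max_score)) {
    stop("items with instrument 'OTHER' need an explicit min_score and max_score")
  }
  min_score <- as.integer(min_score)
  max_score <- as.integer(max_score)
  if (min_score >= max_score) stop("min_score must be < max_score")
  if (instrument == "PANSS" && (min_score != 1L || max_score != 7L)) {
    stop("PANSS items are scored on [1, 7]")
  }
  if (instrument == "SANS" && (min_score != 0L || max_score != 5L)) {
    stop("SANS items are scored on [0, 5]")
  }
  structure(
    list(name = name, instrument = instrument,
         min_score = min_score, max_score = max_score),
    class = "item_def"
  )
}

#' Default five-item formal-thought-disorder schema
#'
#' The five FTD-related items used as clustering features: conceptual
#' disorganization (PANSS P2), difficulty in abstract thinking (PANSS N5),
#' poverty of speech (SANS 9), poverty of content of speech (SANS 10) and
#' increased latency of response (SANS 12).
#'
#' @return A named list of [item_def()] objects.
#' @export
ftd_item_schema <- function() {
  items <- list(
    item_def("PANSS_P2", "PANSS"),
    item_def("PANSS_N5", "PANSS"),
    item_def("SANS_9",  "SANS"),
    item_def("SANS_10", "SANS"),
    item_def("SANS_12", "SANS")
  )
  names(items) <- vapply(items, `[[`, "", "name")
  items
}

item_names <- function(schema) vapply(schema, `[[`, "", "name")

#' Read and validate a cohort table
#'
#' Reads a comma-delimited cohort file (UTF-8, header row, one row per
#' subject, missing cells empty or `NA`), checks that every schema item is
#' present and that all non-missing item values lie inside their declared
#' instrument range, and that subject identifiers are unique. Out-of-range
#' values abort with a diagnostic naming the offending rows and items;
#' missing cells are passed through.
#'
#' @param path Path to a CSV file with a `subject_id` column.
#' @param schema List of [item_def()]s; defaults to [ftd_item_schema()].
#' @return A `data.frame` of class `cohort_table` with the schema attached
#'   as attribute `"schema"`.
#' @export
read_cohort <- function(path, schema = ftd_item_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  as_cohort_table(tab, schema = schema)
}

#' Validate an in-memory cohort table
#'
#' @param tab A data.frame with `subject_id` and the schema's item columns.
#' @inheritParams read_cohort
#' @return A `cohort_table`.
#' @export
as_cohort_table <- function(tab, schema = ftd_item_schema()) {
  if (!"subject_id" %in% names(tab)) stop("cohort table needs a 'subject_id' column")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) {
    stop("subject_id values must be unique; duplicated: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  }
  missing_cols <- setdiff(item_names(schema), names(tab))
  if (length(missing_cols)) {
    stop("schema error: missing item column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- character(0)
  for (it in schema) {
    v <- tab[[it$name]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      tab[[it$name]] <- v
    }
    out <- which(!is.na(v) & (v < it$min_score | v > it$max_score))
    if (length(out)) {
      bad <- c(bad, sprintf("row %d: %s = %s (allowed [%d, %d])",
                            out, it$name, format(v[out]), it$min_score, it$max_score))
    }
  }
  if (length(bad)) {
    stop("validation error: out-of-range item values:\n  ",
         paste(bad, collapse = "\n  "))
  }
  structure(tab, schema = schema, class = c("cohort_table", "data.frame"))
}

#' Write a cohort table back to CSV
#'
#' Inverse of [read_cohort()]: round-tripping a table through
#' `write_cohort()` and `read_cohort()` reproduces it cell for cell.
#'
#' @param tab A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build the clustering feature matrix
#'
#' Selects the item columns, drops subjects with any missing selected
#' feature (listwise deletion; the excluded ids are recorded), and scales.
#' `"range_unit"` maps each item through (x - min) / (max - min) using the
#' instrument's theoretical range, so a PANSS 7 becomes 1 and a SANS 3
#' becomes 0.6 regardless of the sample. `"zscore"` standardises by the
#' sample column mean and SD. `"none"` leaves raw scores.
#'
#' @param tab A `cohort_table`.
#' @param items Character vector of item names; defaults to all schema items.
#' @param scaling `"range_unit"` (default), `"zscore"` or `"none"`.
#' @return A numeric matrix of class `symptom_matrix` with subject ids as
#'   row names and attributes `item_defs`, `scaling` and `excluded`
#'   (ids dropped for missingness).
#' @export
build_feature_matrix <- function(tab, items = NULL,
                                 scaling = c("range_unit", "zscore", "none")) {
  scaling <- match.arg(scaling)
  schema <- attr(tab, "schema")
  if (is.null(items)) items <- item_names(schema)
  missing_cols <- setdiff(items, names(tab))
  if (length(missing_cols)) {
    stop("item(s) not present in cohort table: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(tab)[, items, drop = FALSE])
  storage.mode(X) <- "double"
  keep <- stats::complete.cases(X)
  excluded <- tab$subject_id[!keep]
  if (!any(keep)) stop("all rows excluded: every subject is missing a selected feature")
  if (length(excluded)) {
    message(length(excluded), " subject(s) excluded for missing clustering features")
  }
  X <- X[keep, , drop = FALSE]
  rownames(X) <- tab$subject_id[keep]
  defs <- schema[match(items, item_names(schema))]
  if (scaling == "range_unit") {
    for (j in seq_along(items)) {
      d <- defs[[j]]
      if (is.null(d)) stop("range_unit scaling needs an item definition for ", items[j])
      X[, j] <- (X[, j] - d$min_score) / (d$max_score - d$min_score)
    }
  } else if (scaling == "zscore") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance column under zscore scaling: ",
           paste(items[sds == 0], collapse = ", "))
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  structure(X, item_defs = defs, scaling = scaling, excluded = excluded,
            class = c("symptom_matrix", class(X)))
}

#' Missingness by subgroup
#'
#' Counts missing cells per variable within each cluster and compares the
#' missing/observed split across clusters with Fisher's exact test
#' (exact, so balanced patterns give p = 1). Variables with no missing
#' cells are reported with the comparison skipped.
#'
#' @param tab A `cohort_table`.
#' @param partition A [partition][new_partition] or an integer label vector
#'   aligned with the rows of `tab`.
#' @param variables Variables to audit; defaults to every column except
#'   `subject_id`.
#' @return A data.frame with one row per variable: missing count per group
#'   and the exact-test p-value (`NA` when skipped).
#' @export
missingness_report <- function(tab, partition, variables = NULL) {
  labels <- partition_labels(partition)
  if (length(labels) != nrow(tab)) {
    stop("grouping length (", length(labels), ") does not match table rows (", nrow(tab), ")")
  }
  if (is.null(variables)) variables <- setdiff(names(tab), "subject_id")
  ks <- sort(unique(labels))
  rows <- lapply(variables, function(v) {
    miss <- is.na(tab[[v]])
    counts <- vapply(ks, function(g) sum(miss[labels == g]), 0L)
    totals <- vapply(ks, function(g) sum(labels == g), 0L)
    p <- NA_real_
    if (any(counts > 0)) {
      m <- rbind(missing = counts, observed = totals - counts)
      p <- stats::fisher.test(m)$p.value
    }
    out <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (i in seq_along(ks)) out[[paste0("missing_g", ks[i])]] <- counts[i]
    out$p_value <- p
    out
  })
  do.call(rbind, rows)
}
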