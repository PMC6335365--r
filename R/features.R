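# Feature assembly: graph metrics -> fixed-order named feature vectors and
# subjects x features tables. For an N-ROI parcellation the vector has
# 7N + 5 entries (817 when N = 116): seven nodal metrics in metric-major
# order followed by the five global metrics.

NODAL_METRIC_NAMES <- c(
  "degree", "clustering", "local_efficiency", "betweenness",
  "eigenvector", "participation", "within_module_z"
)
GLOBAL_METRIC_NAMES <- c(
  "transitivity", "char_path_length", "global_efficiency",
  "mean_clustering", "modularity"
)

#' Metadata columns of a feature table
#'
#' Columns of a feature table that describe the subject rather than the
#' network; every other column is a feature.
#'
#' @return Character vector of reserved column names.
#' @export
feature_meta_cols <- function() {
  c("subject_id", "site", "age", "age_group", "diagnosis")
}

#' Names of the feature columns of a feature table
#'
#' @param table A feature table (tibble from [fc_features()] or
#'   [concatenate_pipelines()]).
#' @return Character vector of feature column names, in table order.
#' @export
feature_names <- function(table) {
  setdiff(names(table), feature_meta_cols())
}

#' Assemble the fixed-order feature vector of one subject
#'
#' Flattens nodal and global metric tables into a single named vector:
#' metric-major nodal blocks (`<metric>_<ROI>` in parcellation order)
#' followed by the five `<metric>_global` entries. Length is 7N + 5; the
#' canonical 116-ROI parcellation yields 817 features.
#'
#' @param nodal Tibble from [nodal_metrics()].
#' @param global_m One-row tibble from [global_metrics()].
#' @return Named numeric vector of length `7 * nrow(nodal) + 5`.
#' @export
assemble_features <- function(nodal, global_m) {
  if (!all(c("roi", NODAL_METRIC_NAMES) %in% names(nodal))) {
    stop("`nodal` lacks the seven nodal metric columns.", call. = FALSE)
  }
  if (nrow(global_m) != 1 || !all(GLOBAL_METRIC_NAMES %in% names(global_m))) {
    stop("`global_m` must be one row with the five global metric columns.",
      call. = FALSE
    )
  }
  n <- nrow(nodal)
  vals <- unlist(lapply(NODAL_METRIC_NAMES, function(m) nodal[[m]]), use.names = FALSE)
  if (length(vals) != 7 * n || anyNA(vals) || any(!is.finite(vals))) {
    stop("Nodal metric columns must be complete and finite (length N each).",
      call. = FALSE
    )
  }
  gvals <- unlist(global_m[1, GLOBAL_METRIC_NAMES], use.names = FALSE)
  if (anyNA(gvals) || any(!is.finite(gvals))) {
    stop("Global metrics must be finite.", call. = FALSE)
  }
  names_out <- c(
    unlist(lapply(NODAL_METRIC_NAMES, function(m) paste0(m, "_", nodal$roi)),
      use.names = FALSE
    ),
    paste0(GLOBAL_METRIC_NAMES, "_global")
  )
  if (anyDuplicated(names_out)) {
    stop("Feature names are not unique; check ROI labels.", call. = FALSE)
  }
  out <- setNames(c(vals, gvals), names_out)
  stopifnot(length(out) == 7 * n + 5)
  out
}

#' Compute a subjects-by-features table for a cohort
#'
#' Runs the per-subject pipeline — connectivity estimation, proportional
#' thresholding, module detection, nodal + global metrics, feature assembly
#' — and stacks the resulting vectors into a tidy feature table.
#'
#' @param cohort Cohort tibble from [read_cohort()] or [simulate_cohort()]
#'   (columns `subject_id`, `site`, `age`, `age_group`, `diagnosis`, `ts`).
#' @param estimator Connectivity estimator name; see [connectivity_matrix()].
#' @param keep_fraction Edge fraction kept by [proportional_threshold()].
#' @param rank_by Threshold ranking mode, `"signed"` or `"absolute"`.
#' @param seed Seed for module detection (one shared seed; the per-subject
#'   partition is still graph-specific).
#' @param ... Estimator parameters forwarded to [connectivity_matrix()].
#' @return Tibble: the metadata columns of `cohort` plus 7N + 5 numeric
#'   feature columns, rows aligned with `cohort`.
#' @export
fc_features <- function(cohort, estimator = "spearman", keep_fraction = 0.2,
                        rank_by = c("signed", "absolute"), seed = 1L, ...) {
  rank_by <- match.arg(rank_by)
  stopifnot(is.data.frame(cohort), "ts" %in% names(cohort))
  vecs <- purrr::map(cohort$ts, function(ts) {
    cm <- connectivity_matrix(ts, estimator, ...)
    g <- proportional_threshold(cm, keep_fraction, rank_by = rank_by)
    membership <- detect_modules(g, seed = seed)
    assemble_features(
      nodal_metrics(g, membership = membership),
      global_metrics(g, membership = membership)
    )
  })
  nm <- names(vecs[[1]])
  bad <- which(!purrr::map_lgl(vecs, ~ identical(names(.x), nm)))
  if (length(bad)) {
    stop("Subjects do not share a parcellation (first mismatch: row ", bad[1],
      ").",
      call. = FALSE
    )
  }
  feat <- tibble::as_tibble(do.call(rbind, vecs))
  meta <- dplyr::select(cohort, dplyr::any_of(feature_meta_cols()))
  out <- dplyr::bind_cols(meta, feat)
  attr(out, "estimator") <- estimator
  attr(out, "keep_fraction") <- keep_fraction
  attr(out, "seed") <- seed
  out
}

#' Concatenate per-estimator feature tables into one meta-pipeline table
#'
#' Joins the feature tables of several connectivity estimators on the same
#' subjects into a single wide table, prefixing every feature name with its
#' estimator tag so names stay unique. Five 817-feature tables yield 4085
#' features.
#'
#' @param tables Named list of feature tables over identical subjects in
#'   identical order; names are the estimator tags used as prefixes.
#' @return A feature table with `sum(F_k)` feature columns.
#' @export
concatenate_pipelines <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("`tables` must be a named list (estimator tags).", call. = FALSE)
  }
  ids <- purrr::map(tables, ~ .x$subject_id)
  if (!all(purrr::map_lgl(ids, identical, y = ids[[1]]))) {
    stop("All tables must cover the same subjects in the same order.",
      call. = FALSE
    )
  }
  meta <- dplyr::select(tables[[1]], dplyr::any_of(feature_meta_cols()))
  blocks <- purrr::imap(tables, function(tb, tag) {
    f <- dplyr::select(tb, dplyr::all_of(feature_names(tb)))
    rlang::set_names(f, paste0(tag, ".", names(f)))
  })
  out <- dplyr::bind_cols(meta, blocks)
  if (anyDuplicated(feature_names(out))) {
    stop("Concatenation produced duplicate feature names.", call. = FALSE)
  }
  attr(out, "estimator") <- paste(names(tables), collapse = "+")
  out
}

#' Between-group difference of features (Welch's t-test)
#'
#' Tests each named feature for an ASD-vs-HC mean difference with Welch's
#' unequal-variance t-test. A feature constant within both groups is
#' degenerate: it is reported with `statistic = 0`, `p.value = 1` and a
#' warning.
#'
#' @param table A feature table with a `diagnosis` column.
#' @param features Feature names to test; default all features.
#' @return Tibble: `feature`, `statistic`, `df`, `p.value`, `mean_asd`,
#'   `mean_hc`, sorted as given.
#' @export
group_difference <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_names(table)
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    stop("Unknown feature(s): ", paste(head(missing, 3), collapse = ", "),
      call. = FALSE
    )
  }
  asd <- table$diagnosis == "ASD"
  purrr::map_dfr(features, function(f) {
    a <- table[[f]][asd]
    b <- table[[f]][!asd]
    if (var(table[[f]]) == 0) {
      warning("Feature '", f, "' is constant; group difference undefined, ",
        "reporting p = 1.",
        call. = FALSE
      )
    }
    wt <- welch_t(a, b)
    tibble::tibble(
      feature = f, statistic = wt$statistic, df = wt$df, p.value = wt$p.value,
      mean_asd = mean(a), mean_hc = mean(b)
    )
  })
}

#' Write a feature table with a JSON metadata sidecar
#'
#' @param table A feature table.
#' @param path Output CSV path; metadata (estimator, threshold, seed) goes
#'   to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      estimator = attr(table, "estimator"),
      keep_fraction = attr(table, "keep_fraction"),
      seed = attr(table, "seed"),
      n_subjects = nrow(table),
      n_features = length(feature_names(table))
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
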