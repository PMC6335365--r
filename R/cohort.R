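# Cohort ingestion, validation and age stratification.

AGE_GROUP_LEVELS <- c("5-10", "10-15", "15-20", "20-30", ">30")
AGE_GROUP_LOWER <- c(5, 10, 15, 20, 30)
AGE_GROUP_UPPER <- c(10, 15, 20, 30, Inf)

#' Age-group labels used for cohort stratification
#'
#' Five half-open age bands: 5-year increments up to 20, one 10-year band,
#' and an unbounded band above 30. Together they cover ages from 5 upward.
#'
#' @return Character vector of the five group labels, in increasing age order.
#' @export
age_group_levels <- function() AGE_GROUP_LEVELS

#' Assign ages to cohort age groups
#'
#' Maps each age to one of five half-open bands: \[5,10), \[10,15), \[15,20),
#' \[20,30), \[30,Inf). Boundary ages fall in the upper band (age 10 is in
#' "10-15"). Cohorts analysed with this package start at age 5; younger
#' ages are rejected.
#'
#' @param age Numeric vector of ages in years, all \eqn{\ge 5}.
#' @return Factor with levels `age_group_levels()`, same length as `age`.
#' @examples
#' assign_age_group(c(7, 12, 33))
#' @export
assign_age_group <- function(age) {
  if (!is.numeric(age) || anyNA(age)) {
    stop("`age` must be numeric with no missing values.", call. = FALSE)
  }
  if (any(age < 5)) {
    stop(
      "Ages below 5 are outside the supported cohort range (first group starts at 5): ",
      paste(age[age < 5], collapse = ", "),
      call. = FALSE
    )
  }
  idx <- findInterval(age, AGE_GROUP_LOWER)
  factor(AGE_GROUP_LEVELS[idx], levels = AGE_GROUP_LEVELS)
}

#' AAL-116 region abbreviations
#'
#' The 116 region abbreviations of the automatic anatomical labeling (AAL)
#' parcellation, in atlas order. Used as default ROI labels for time-series
#' files without a header row.
#'
#' @return Character vector of length 116.
#' @export
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.txt", package = "graphfc")
  readLines(path)
}

validate_timeseries <- function(ts, subject_id) {
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("Time series for subject ", subject_id, " is not a numeric matrix.", call. = FALSE)
  }
  if (nrow(ts) < 2 || ncol(ts) < 3) {
    stop(
      "Time series for subject ", subject_id, " must have >= 2 time points and >= 3 ROIs.",
      call. = FALSE
    )
  }
  if (anyNA(ts) || any(!is.finite(ts))) {
    stop("Time series for subject ", subject_id, " contains non-finite values.", call. = FALSE)
  }
  labels <- colnames(ts)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("ROI labels for subject ", subject_id, " are missing or not distinct.", call. = FALSE)
  }
  invisible(ts)
}

read_timeseries_file <- function(path, roi_labels = NULL) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[\t ,]+")[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(fields)))
  raw <- read.table(path, header = has_header, check.names = FALSE)
  ts <- as.matrix(raw)
  storage.mode(ts) <- "double"
  if (!has_header) {
    if (is.null(roi_labels)) {
      if (ncol(ts) != 116) {
        stop(
          "Time-series file ", basename(path), " has no header and ", ncol(ts),
          " columns; default AAL labels require 116 columns. ",
          "Supply `roi_labels` explicitly.",
          call. = FALSE
        )
      }
      roi_labels <- aal116_labels()
    }
    if (length(roi_labels) != ncol(ts)) {
      stop(
        "`roi_labels` has length ", length(roi_labels), " but ", basename(path),
        " has ", ncol(ts), " columns.",
        call. = FALSE
      )
    }
    colnames(ts) <- roi_labels
  }
  ts
}

#' Load a cohort of subjects with their ROI time series
#'
#' Reads a phenotype table and one time-series file per subject, validates
#' both, and excludes subjects with any all-zero ROI column (regions with a
#' consistently zero signal indicate failed extraction; such subjects are
#' dropped with a message). Optionally, near-constant columns can also be
#' excluded via `min_variance`.
#'
#' @param phenotype_path Path to a CSV with header
#'   `subject_id,site,age,diagnosis`; `diagnosis` must be `"ASD"` or `"HC"`.
#' @param timeseries_dir Directory containing `<subject_id>.tsv` (or `.txt`,
#'   `.1D`) files: whitespace/tab-delimited numeric matrices, rows = time
#'   points, columns = ROIs, optional header row of ROI labels.
#' @param roi_labels Labels used for headerless files. Default `NULL` uses
#'   the packaged AAL-116 abbreviations when a file has 116 columns.
#' @param min_variance Minimum per-column variance; columns at or below it
#'   trigger exclusion of the subject. Default 0 (only exactly-zero columns
#'   excluded).
#' @return A tibble with one row per retained subject: `subject_id`, `site`,
#'   `age`, `diagnosis` (factor ASD/HC), `age_group`, and `ts` (list column
#'   of T x N matrices with ROI column names).
#' @export
read_cohort <- function(phenotype_path, timeseries_dir, roi_labels = NULL,
                        min_variance = 0) {
  if (!file.exists(phenotype_path)) {
    stop("Phenotype file not found: ", phenotype_path, call. = FALSE)
  }
  pheno <- read.csv(phenotype_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "site", "age", "diagnosis")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols)) {
    stop("Phenotype file lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(pheno$subject_id)) {
    stop("Duplicate subject_id in phenotype table.", call. = FALSE)
  }
  for (i in seq_len(nrow(pheno))) {
    age_i <- suppressWarnings(as.numeric(pheno$age[i]))
    if (is.na(age_i) || age_i <= 0) {
      stop("Row ", i, " of phenotype table: unparseable or non-positive age '",
        pheno$age[i], "'.",
        call. = FALSE
      )
    }
    if (!pheno$diagnosis[i] %in% c("ASD", "HC")) {
      stop("Row ", i, " of phenotype table: diagnosis '", pheno$diagnosis[i],
        "' is not one of ASD, HC.",
        call. = FALSE
      )
    }
  }
  pheno$age <- as.numeric(pheno$age)

  rows <- purrr::map(seq_len(nrow(pheno)), function(i) {
    id <- pheno$subject_id[i]
    candidates <- file.path(timeseries_dir, paste0(id, c(".tsv", ".txt", ".1D")))
    path <- candidates[file.exists(candidates)][1]
    if (is.na(path)) {
      stop("No time-series file found for subject ", id, " in ", timeseries_dir,
        call. = FALSE
      )
    }
    ts <- read_timeseries_file(path, roi_labels)
    validate_timeseries(ts, id)
    col_var <- apply(ts, 2, var)
    zero_cols <- colnames(ts)[apply(ts, 2, function(x) all(x == 0)) |
      col_var <= min_variance & min_variance > 0]
    if (length(zero_cols)) {
      message(
        "Excluding subject ", id, ": all-zero/constant ROI column(s) ",
        paste(head(zero_cols, 3), collapse = ", "),
        if (length(zero_cols) > 3) ", ..."
      )
      return(NULL)
    }
    tibble::tibble(
      subject_id = id, site = pheno$site[i], age = pheno$age[i],
      diagnosis = factor(pheno$diagnosis[i], levels = c("ASD", "HC")),
      ts = list(ts)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      subject_id = character(), site = character(), age = numeric(),
      diagnosis = factor(character(), levels = c("ASD", "HC")),
      age_group = factor(character(), levels = AGE_GROUP_LEVELS),
      ts = list()
    ))
  }
  out$age_group <- assign_age_group(out$age)
  dplyr::relocate(out, "age_group", .after = "age")
}
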