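# Cross-validated evaluation and pairwise model comparison.

# Welch's unequal-variance t-test with explicit handling of the degenerate
# zero-variance branches (stats::t.test refuses essentially-constant data).
welch_t <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  v1 <- var(a)
  v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0 || is.na(se2)) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, df = n1 + n2 - 2, p.value = 1))
    }
    warning("Zero within-sample variance with unequal means; p-value -> 0.",
      call. = FALSE
    )
    return(list(
      statistic = sign(mean(a) - mean(b)) * Inf, df = n1 + n2 - 2,
      p.value = 0
    ))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment; corrected values are monotone in the p-value ranks
#' and capped at 1.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Numeric vector of adjusted p-values, each \eqn{\ge} its raw value
#'   and \eqn{\le 1}.
#' @export
fdr_correct <- function(pvalues) {
  pmin(1, stats::p.adjust(pvalues, method = "BH"))
}

confusion_counts <- function(truth, pred, positive = "ASD") {
  list(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive)
  )
}

#' Stratified k-fold cross-validation of an SVM on selected features
#'
#' Evaluates the classifier with stratified folds (per-fold class counts
#' within one subject of proportionality); every subject is predicted
#' exactly once. ASD is the positive class. The chance level is the
#' proportion of the most populous class — the accuracy of a classifier
#' that always predicts the majority group.
#'
#' @param table A feature table with a `diagnosis` column.
#' @param features Feature names used by the model (e.g. an
#'   `sffs_selection$features`, or an `sffs_selection` itself).
#' @param folds Number of folds (default 10).
#' @param seed Seed fixing the fold assignment.
#' @param kernel,cost,standardize Classifier settings; see [train_svm()].
#' @param fold_id Optional explicit fold assignment (overrides
#'   `folds`/`seed`); used to share identical folds across pipelines.
#' @return An `fc_cv` object: per-fold confusion counts plus aggregate
#'   `accuracy`, `sensitivity` (TP/(TP+FN)), `specificity` (TN/(TN+FP)) and
#'   `chance`. Has [tidy()] and [glance()] methods.
#' @export
cross_validate <- function(table, features, folds = 10, seed = 1L,
                           kernel = c("linear", "radial"), cost = 1,
                           standardize = TRUE, fold_id = NULL) {
  kernel <- match.arg(kernel)
  if (inherits(features, "sffs_selection")) features <- features$features
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    stop("Unknown feature(s): ", paste(head(missing, 3), collapse = ", "),
      call. = FALSE
    )
  }
  y <- droplevels(as.factor(table$diagnosis))
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed = seed)
  x <- as.matrix(table[, features, drop = FALSE])
  fold_rows <- purrr::map_dfr(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (standardize) {
      std <- standardize_fit(xtr)
      xtr <- standardize_apply(xtr, std)
      xte <- standardize_apply(xte, std)
    }
    fit <- e1071::svm(xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    pred <- stats::predict(fit, xte)
    cc <- confusion_counts(y[!tr], pred)
    tibble::tibble(
      fold = f, tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn
    )
  })
  tp <- sum(fold_rows$tp)
  tn <- sum(fold_rows$tn)
  fp <- sum(fold_rows$fp)
  fn <- sum(fold_rows$fn)
  n <- length(y)
  stopifnot(tp + tn + fp + fn == n)
  structure(
    list(
      folds = fold_rows,
      accuracy = (tp + tn) / n,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      chance = max(table(y)) / n,
      n = n,
      fold_id = fold_id,
      config = list(
        folds = length(unique(fold_id)), seed = seed, kernel = kernel,
        cost = cost, features = features
      )
    ),
    class = "fc_cv"
  )
}

#' @export
print.fc_cv <- function(x, ...) {
  cat("<fc_cv> ", x$config$folds, "-fold stratified CV, n = ", x$n, "\n",
    sep = ""
  )
  cat(sprintf(
    "  accuracy %.3f | sensitivity %.3f | specificity %.3f | chance %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$chance
  ))
  invisible(x)
}

#' Repeated-CV accuracy comparison of pipelines (Welch + BH)
#'
#' Runs `repeats` repetitions of stratified `folds`-fold CV, with the fold
#' assignment of each repetition shared across all pipelines, then compares
#' every pipeline pair with Welch's unequal-variance t-test on their
#' accuracy samples (null: equal mean accuracy) and applies
#' Benjamini-Hochberg correction over the pairs, capped at 1.
#'
#' By default the test compares the `repeats` repetition-mean accuracies
#' per pipeline (fold-level accuracies within one repetition are dependent,
#' so repetition means are the safer unit); `level = "fold"` compares the
#' `repeats * folds` per-fold accuracies instead.
#'
#' @param tables Named list of feature tables over identical subjects in
#'   identical order (one per pipeline).
#' @param features Named list (same names) of character vectors of selected
#'   features per pipeline, or `NULL` to run [sffs_select()] with `k`
#'   features per pipeline first.
#' @param k Features to select per pipeline when `features` is `NULL`.
#' @param repeats Number of CV repetitions (default 10).
#' @param folds Folds per repetition (default 10).
#' @param seed Base seed; repetition r uses fold seed `seed * 1000 + r`.
#' @param kernel,cost,standardize Classifier settings; see [train_svm()].
#' @param level `"repetition"` (default) or `"fold"`: the unit of the
#'   accuracy samples fed to the Welch tests.
#' @return An `fc_comparison`: `accuracy` (samples x pipelines matrix),
#'   `statistic`, `p.value`, `p.adjusted` (pipelines x pipelines symmetric
#'   matrices; self-comparisons have t = 0, p = 1). Has [tidy()] and
#'   [autoplot()] methods.
#' @export
repeated_cv_compare <- function(tables, features = NULL, k = 10, repeats = 10,
                                folds = 10, seed = 1L,
                                kernel = c("linear", "radial"), cost = 1,
                                standardize = TRUE,
                                level = c("repetition", "fold")) {
  kernel <- match.arg(kernel)
  level <- match.arg(level)
  if (repeats < 2) stop("Need at least 2 repetitions.", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("`tables` must be a named list of pipelines.", call. = FALSE)
  }
  ids <- purrr::map(tables, ~ .x$subject_id)
  if (!all(purrr::map_lgl(ids, identical, y = ids[[1]]))) {
    stop("All pipelines must cover the same subjects in the same order.",
      call. = FALSE
    )
  }
  pipes <- names(tables)
  if (is.null(features)) {
    features <- purrr::map(tables, function(tb) {
      sffs_select(tb, k = k, folds = folds, seed = seed, kernel = kernel,
                  cost = cost, standardize = standardize)$features
    })
  }
  y <- droplevels(as.factor(tables[[1]]$diagnosis))
  acc_mat <- do.call(rbind, purrr::map(seq_len(repeats), function(r) {
    fold_id <- stratified_folds(y, folds, seed = seed * 1000L + r)
    cols <- purrr::map(pipes, function(p) {
      cv <- cross_validate(tables[[p]], features[[p]],
        fold_id = fold_id, seed = seed, kernel = kernel, cost = cost,
        standardize = standardize
      )
      if (level == "repetition") {
        cv$accuracy
      } else {
        fr <- cv$folds
        (fr$tp + fr$tn) / (fr$tp + fr$tn + fr$fp + fr$fn)
      }
    })
    m <- do.call(cbind, cols)
    colnames(m) <- pipes
    m
  }))
  p_n <- length(pipes)
  stat <- p_raw <- matrix(0, p_n, p_n, dimnames = list(pipes, pipes))
  diag(p_raw) <- 1
  for (i in seq_len(p_n)) {
    for (j in seq_len(p_n)) {
      if (i < j) {
        wt <- welch_t(acc_mat[, i], acc_mat[, j])
        stat[i, j] <- wt$statistic
        stat[j, i] <- -wt$statistic
        p_raw[i, j] <- p_raw[j, i] <- wt$p.value
      }
    }
  }
  upper <- which(upper.tri(p_raw))
  p_adj <- p_raw
  p_adj[upper] <- fdr_correct(p_raw[upper])
  p_adj <- pmax(p_adj, t(p_adj)) # mirror the corrected upper triangle
  diag(p_adj) <- 1
  structure(
    list(
      accuracy = acc_mat, statistic = stat, p.value = p_raw,
      p.adjusted = p_adj, features = features,
      config = list(
        repeats = repeats, folds = folds, seed = seed, kernel = kernel,
        cost = cost, level = level
      )
    ),
    class = "fc_comparison"
  )
}

#' @export
print.fc_comparison <- function(x, ...) {
  cat("<fc_comparison> ", ncol(x$accuracy), " pipelines, ",
    x$config$repeats, " x ", x$config$folds, "-fold CV (",
    x$config$level, "-level samples)\n",
    sep = ""
  )
  cat("  mean accuracies:\n")
  print(round(colMeans(x$accuracy), 3))
  invisible(x)
}

#' Write a CV result as JSON and per-fold CSV
#'
#' @param cv An `fc_cv`.
#' @param path Output stem: writes `<path>.json` (aggregates) and
#'   `<path>_folds.csv` (per-fold confusion counts).
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  jsonlite::write_json(
    list(
      accuracy = cv$accuracy, sensitivity = cv$sensitivity,
      specificity = cv$specificity, chance = cv$chance, n = cv$n,
      config = cv$config
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  write.csv(as.data.frame(cv$folds), paste0(path, "_folds.csv"),
    row.names = FALSE
  )
  invisible(path)
}
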