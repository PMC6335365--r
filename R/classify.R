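# SVM classification and sequential forward (floating) feature selection.

#' Stratified fold assignment
#'
#' Assigns subjects to `k` cross-validation folds so that each class is
#' spread as evenly as possible: per fold, each class count deviates from
#' perfect proportionality by at most 1, and remainders of successive
#' classes are offset so total fold sizes also differ by at most 1.
#'
#' @param y Factor (or vector) of class labels.
#' @param k Number of folds; every class must have at least `k` members.
#' @param seed Integer seed; the shuffle within each class is seeded, so an
#'   identical `(y, k, seed)` gives identical folds.
#' @return Integer vector of fold ids in `1:k`, aligned with `y`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts < k)) {
    stop(
      "Class '", names(counts)[which.min(counts)], "' has ", min(counts),
      " members, fewer than k = ", k, " folds.",
      call. = FALSE
    )
  }
  fold <- integer(length(y))
  offset <- 0L
  withr::with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)
}

#' Train a support vector machine on selected features
#'
#' Fits an SVM on the given feature columns. Features are standardized with
#' mean/SD learned from the training rows only; the same transform is
#' applied at prediction time. The default is a linear kernel with C = 1 —
#' the least flexible choice, used to limit overfitting on small cohorts —
#' with a Gaussian (radial) kernel available.
#'
#' @param table A feature table with a `diagnosis` column.
#' @param features Character vector of feature names to use.
#' @param kernel `"linear"` (default) or `"radial"` (Gaussian).
#' @param cost SVM regularization parameter C (> 0).
#' @param standardize Standardize features from training data; default TRUE.
#' @return An `fc_svm` model object with a [predict][predict.fc_svm] method.
#' @export
train_svm <- function(table, features, kernel = c("linear", "radial"),
                      cost = 1, standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("`cost` must be > 0.", call. = FALSE)
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    stop("Unknown feature(s): ", paste(head(missing, 3), collapse = ", "),
      call. = FALSE
    )
  }
  y <- droplevels(as.factor(table$diagnosis))
  if (nlevels(y) < 2 || any(table(y) < 2)) {
    stop("Need at least 2 subjects in each of 2 classes.", call. = FALSE)
  }
  x <- as.matrix(table[, features, drop = FALSE])
  std <- if (standardize) standardize_fit(x) else NULL
  if (!is.null(std)) x <- standardize_apply(x, std)
  fit <- e1071::svm(x, y, kernel = kernel, cost = cost, scale = FALSE)
  structure(
    list(fit = fit, features = features, std = std, kernel = kernel,
         cost = cost, levels = levels(y)),
    class = "fc_svm"
  )
}

#' Predict diagnoses with a trained SVM
#'
#' @param object An `fc_svm` from [train_svm()].
#' @param newdata A feature table (or data frame) containing the model's
#'   feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.fc_svm <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("`newdata` lacks feature(s): ",
      paste(head(missing, 3), collapse = ", "),
      call. = FALSE
    )
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  if (!is.null(object$std)) x <- standardize_apply(x, object$std)
  stats::predict(object$fit, x)
}

# Pooled CV accuracy of an SVM on the columns `features`, under fixed folds.
# Standardization is refit inside every training fold (no leakage).
cv_accuracy <- function(x, y, fold, features_idx, kernel, cost,
                        standardize = TRUE) {
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    xtr <- x[tr, features_idx, drop = FALSE]
    xte <- x[!tr, features_idx, drop = FALSE]
    if (standardize) {
      std <- standardize_fit(xtr)
      xtr <- standardize_apply(xtr, std)
      xte <- standardize_apply(xte, std)
    }
    fit <- e1071::svm(xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    pred <- stats::predict(fit, xte)
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Sequential forward (floating) feature selection around an SVM
#'
#' Wrapper selection scored by stratified k-fold cross-validated accuracy
#' with one fixed fold assignment. Iteration 1 scores every feature alone
#' and keeps the best; each later iteration adds the feature that maximises
#' the grown subset's CV accuracy. With `floating = TRUE`, after each
#' addition a conditional-exclusion step removes a previously selected
#' feature whenever removal strictly improves on the best accuracy recorded
#' for that subset size. Ties are broken by the lowest feature index in
#' canonical table order; the procedure stops when exactly `k` features are
#' held, so both modes return `k` features.
#'
#' @param table A feature table with a `diagnosis` column.
#' @param k Number of features to select (default 10).
#' @param folds Number of stratified CV folds used for scoring (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @param kernel,cost,standardize Classifier settings; see [train_svm()].
#' @param floating Enable the conditional-exclusion step; default FALSE
#'   (plain sequential forward selection).
#' @param candidates Optional character vector restricting the candidate
#'   pool (default: all features).
#' @return An `sffs_selection` object: `features` (selected names, in order
#'   of addition), `trace` (best CV accuracy at each subset size), the fold
#'   assignment and configuration. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
sffs_select <- function(table, k = 10, folds = 10, seed = 1L,
                        kernel = c("linear", "radial"), cost = 1,
                        standardize = TRUE, floating = FALSE,
                        candidates = NULL) {
  kernel <- match.arg(kernel)
  feats <- feature_names(table)
  if (!is.null(candidates)) {
    missing <- setdiff(candidates, feats)
    if (length(missing)) {
      stop("Unknown candidate feature(s): ",
        paste(head(missing, 3), collapse = ", "),
        call. = FALSE
      )
    }
    feats <- intersect(feats, candidates)
  }
  if (k >= length(feats)) {
    stop("`k` (", k, ") must be smaller than the number of candidate features (",
      length(feats), ").",
      call. = FALSE
    )
  }
  y <- droplevels(as.factor(table$diagnosis))
  fold <- stratified_folds(y, folds, seed = seed)
  for (f in seq_len(folds)) {
    if (length(unique(y[fold == f])) < 2) {
      stop("Fold ", f, " contains a single class; reduce `folds`.", call. = FALSE)
    }
  }
  x <- as.matrix(table[, feats, drop = FALSE])

  cache <- new.env(parent = emptyenv())
  score <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- cv_accuracy(x, y, fold, sort(idx), kernel, cost, standardize)
    cache[[key]] <- val
    val
  }

  selected <- integer(0)
  best_at_size <- numeric(k) # best accuracy recorded per subset size
  trace <- numeric(0)
  while (length(selected) < k) {
    pool <- setdiff(seq_along(feats), selected)
    scores <- vapply(pool, function(j) score(c(selected, j)), numeric(1))
    best <- pool[which.max(scores)] # which.max: first max = lowest index
    selected <- c(selected, best)
    sz <- length(selected)
    acc <- max(scores)
    best_at_size[sz] <- max(best_at_size[sz], acc)
    trace[sz] <- best_at_size[sz]
    if (length(selected) == k) break
    if (floating) {
      repeat {
        sz <- length(selected)
        if (sz <= 2) break
        drop_scores <- vapply(
          seq_along(selected),
          function(i) score(selected[-i]), numeric(1)
        )
        i_best <- which.max(drop_scores)
        if (selected[i_best] != best && drop_scores[i_best] > best_at_size[sz - 1]) {
          selected <- selected[-i_best]
          best_at_size[sz - 1] <- drop_scores[i_best]
          trace[sz - 1] <- best_at_size[sz - 1]
        } else {
          break
        }
      }
    }
  }
  structure(
    list(
      features = feats[selected],
      trace = trace,
      fold = fold,
      config = list(
        k = k, folds = folds, seed = seed, kernel = kernel, cost = cost,
        standardize = standardize, floating = floating
      )
    ),
    class = "sffs_selection"
  )
}

#' @export
print.sffs_selection <- function(x, ...) {
  cat("<sffs_selection> ", length(x$features), " features (",
    if (x$config$floating) "floating" else "plain forward", ", ",
    x$config$folds, "-fold CV scoring)\n",
    sep = ""
  )
  cat("  final CV accuracy: ", round(x$trace[length(x$trace)], 3), "\n", sep = "")
  for (i in seq_along(x$features)) {
    cat(sprintf("  %2d. %s (%.3f)\n", i, x$features[i], x$trace[i]))
  }
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Writes names, selection ranks, the accuracy trace and the configuration
#' (including the seed) of an [sffs_select()] result.
#'
#' @param selection An `sffs_selection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(
      features = selection$features,
      rank = seq_along(selection$features),
      trace = selection$trace,
      config = selection$config
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
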