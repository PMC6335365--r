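# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a selection result
#'
#' @param x An `sffs_selection`.
#' @param ... Unused.
#' @return Tibble: `rank`, `feature`, `cv_accuracy` (best CV accuracy at
#'   that subset size).
#' @method tidy sffs_selection
#' @export
tidy.sffs_selection <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$features),
    feature = x$features,
    cv_accuracy = x$trace[seq_along(x$features)]
  )
}

#' One-row summary of a selection result
#'
#' @inheritParams tidy.sffs_selection
#' @return One-row tibble: `n_selected`, `final_cv_accuracy`, `folds`,
#'   `kernel`, `floating`.
#' @method glance sffs_selection
#' @export
glance.sffs_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$features),
    final_cv_accuracy = x$trace[length(x$trace)],
    folds = x$config$folds,
    kernel = x$config$kernel,
    floating = x$config$floating
  )
}

#' Plot the selection accuracy trace
#'
#' @param object An `sffs_selection`.
#' @param ... Unused.
#' @return A ggplot: best CV accuracy against subset size.
#' @method autoplot sffs_selection
#' @export
autoplot.sffs_selection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$cv_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$rank) +
    ggplot2::labs(
      x = "features selected", y = "CV accuracy",
      title = "Sequential forward selection trace"
    )
}

#' Tidy a cross-validation result
#'
#' @param x An `fc_cv`.
#' @param ... Unused.
#' @return Tibble of per-fold confusion counts and accuracy.
#' @method tidy fc_cv
#' @export
tidy.fc_cv <- function(x, ...) {
  dplyr::mutate(
    x$folds,
    accuracy = (.data$tp + .data$tn) /
      (.data$tp + .data$tn + .data$fp + .data$fn)
  )
}

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.fc_cv
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `chance`, `n`, `folds`.
#' @method glance fc_cv
#' @export
glance.fc_cv <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, chance = x$chance, n = x$n,
    folds = x$config$folds
  )
}

#' Plot per-fold CV accuracy
#'
#' @param object An `fc_cv`.
#' @param ... Unused.
#' @return A ggplot of per-fold accuracies with the aggregate and chance
#'   levels marked.
#' @method autoplot fc_cv
#' @export
autoplot.fc_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = 3) +
    ggplot2::labs(
      x = "fold", y = "accuracy",
      title = "Stratified cross-validation",
      subtitle = "dashed: pooled accuracy; dotted: chance level"
    )
}

#' Tidy a pipeline comparison
#'
#' @param x An `fc_comparison`.
#' @param ... Unused.
#' @return Long tibble over pipeline pairs: `pipeline1`, `pipeline2`,
#'   `statistic`, `p.value`, `p.adjusted`.
#' @method tidy fc_comparison
#' @export
tidy.fc_comparison <- function(x, ...) {
  pipes <- colnames(x$p.value)
  pairs <- which(upper.tri(x$p.value), arr.ind = TRUE)
  tibble::tibble(
    pipeline1 = pipes[pairs[, 1]],
    pipeline2 = pipes[pairs[, 2]],
    statistic = x$statistic[pairs],
    p.value = x$p.value[pairs],
    p.adjusted = x$p.adjusted[pairs]
  )
}

#' Heatmap of FDR-corrected pipeline comparison p-values
#'
#' @param object An `fc_comparison`.
#' @param adjusted Plot BH-corrected p-values (default) or raw ones.
#' @param ... Unused.
#' @return A ggplot tile map of pairwise p-values.
#' @method autoplot fc_comparison
#' @export
autoplot.fc_comparison <- function(object, adjusted = TRUE, ...) {
  m <- if (adjusted) object$p.adjusted else object$p.value
  d <- tibble::as_tibble(as.table(m), .name_repair = ~ c("pipeline1", "pipeline2", "p"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pipeline1, y = .data$pipeline2,
                                  fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "#08306b", high = "#f7fbff",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = if (adjusted) "BH p" else "raw p",
      title = "Pairwise pipeline comparison (Welch's t)",
      subtitle = if (adjusted) "Benjamini-Hochberg corrected, capped at 1"
                 else "raw p-values"
    )
}
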