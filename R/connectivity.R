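# Functional-connectivity estimators: each maps one subject's T x N ROI
# time-series matrix to a symmetric N x N association matrix with zero
# diagonal (the diagonal carries no edge information downstream).

new_fc_matrix <- function(w, estimator, params = list()) {
  w <- (w + t(w)) / 2
  diag(w) <- 0
  structure(w, class = c("fc_matrix", "matrix", "array"),
            estimator = estimator, params = params)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("<fc_matrix> ", nrow(x), " x ", ncol(x), " (", attr(x, "estimator"),
    ")\n",
    sep = ""
  )
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

check_ts <- function(ts, min_t = 3) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("`ts` must be a numeric matrix.", call. = FALSE)
  if (nrow(ts) < min_t) {
    stop("Need at least ", min_t, " time points, got ", nrow(ts), ".", call. = FALSE)
  }
  invisible(ts)
}

check_no_constant <- function(ts) {
  const <- apply(ts, 2, function(x) diff(range(x)) == 0)
  if (any(const)) {
    stop(
      "Constant ROI column(s): ",
      paste(head(colnames(ts)[const], 5), collapse = ", "),
      ". Rank/correlation undefined; exclude these subjects upstream.",
      call. = FALSE
    )
  }
  invisible(ts)
}

#' Spearman rank-correlation connectivity
#'
#' Pairwise Spearman rank correlation between all ROI columns. Rank-based,
#' hence invariant to strictly monotone transformations of any column.
#'
#' @param ts T x N numeric matrix, rows = time points, columns = ROIs
#'   (column names are the ROI labels).
#' @return An `fc_matrix`: symmetric N x N matrix, entries in \[-1, 1\],
#'   diagonal set to 0.
#' @export
spearman_connectivity <- function(ts) {
  check_ts(ts)
  check_no_constant(ts)
  new_fc_matrix(cor(ts, method = "spearman"), "spearman")
}

# Percentage-bend marginal transform (Wilcox): robust location/scale from a
# beta-trimmed absolute-deviation scale, then winsorising psi at +/- 1.
pbend_transform <- function(x, beta) {
  n <- length(x)
  w <- sort(abs(x - median(x)))
  m <- floor((1 - beta) * n + 0.5)
  omega <- w[m]
  if (omega == 0) {
    stop("Percentage-bend scale is zero (column nearly constant).", call. = FALSE)
  }
  z <- (x - median(x)) / omega
  i1 <- sum(z < -1)
  i2 <- sum(z > 1)
  sx <- sum(x[z >= -1 & z <= 1])
  phi <- (omega * (i2 - i1) + sx) / (n - i1 - i2)
  u <- (x - phi) / omega
  # beta = 0: no observation is bent, psi is the identity and the
  # correlation reduces exactly to Pearson
  if (beta == 0) u else pmax(-1, pmin(1, u))
}

#' Percentage-bend correlation connectivity
#'
#' Robust correlation that downweights the most extreme `beta` fraction of
#' observations in each margin before correlating. With `beta = 0` it
#' reduces exactly to Pearson correlation.
#'
#' @inheritParams spearman_connectivity
#' @param beta Bend fraction in \[0, 0.5): the proportion of observations
#'   allowed to be bent (winsorised) in each margin. Default 0.2, the
#'   conventional setting.
#' @return An `fc_matrix` with entries in \[-1, 1\].
#' @export
bend_connectivity <- function(ts, beta = 0.2) {
  check_ts(ts)
  check_no_constant(ts)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta >= 0.5) {
    stop("`beta` must be a single value in [0, 0.5).", call. = FALSE)
  }
  a <- apply(ts, 2, pbend_transform, beta = beta)
  ss <- colSums(a^2)
  w <- crossprod(a) / sqrt(outer(ss, ss))
  new_fc_matrix(w, "bend", list(beta = beta))
}

#' Partial-correlation connectivity
#'
#' Correlation between each ROI pair conditioned on all remaining ROIs,
#' computed from the inverse sample covariance:
#' \eqn{w_{ij} = -p_{ij}/\sqrt{p_{ii} p_{jj}}} for precision matrix `p`.
#' When there are fewer time points than ROIs the sample covariance is
#' singular; a small ridge is added by default in that case.
#'
#' @inheritParams spearman_connectivity
#' @param ridge Ridge added to the covariance diagonal before inversion.
#'   `NULL` (default) uses `1e-6 * trace/N` when `T <= N` and 0 otherwise.
#' @return An `fc_matrix` with entries in \[-1, 1\].
#' @export
partial_connectivity <- function(ts, ridge = NULL) {
  check_ts(ts)
  check_no_constant(ts)
  s <- cov(ts)
  n <- ncol(s)
  if (is.null(ridge)) {
    ridge <- if (nrow(ts) <= n) 1e-6 * sum(diag(s)) / n else 0
  }
  p <- tryCatch(
    solve(s + diag(ridge, n)),
    error = function(e) {
      stop(
        "Sample covariance is singular and ridge = ", ridge,
        "; rerun with a positive `ridge` (e.g. 1e-6 * trace/N).",
        call. = FALSE
      )
    }
  )
  d <- sqrt(diag(p))
  w <- -p / outer(d, d)
  new_fc_matrix(w, "partial", list(ridge = ridge))
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# Graphical-lasso coordinate descent (Friedman-style block updates) on a
# correlation matrix. Returns the estimated covariance W and precision Theta.
glasso_fit <- function(s, lambda, max_iter = 200, tol = 1e-5) {
  p <- ncol(s)
  w <- s
  diag(w) <- diag(s) + lambda
  beta_store <- matrix(0, p - 1, p)
  off_scale <- mean(abs(s[upper.tri(s)]))
  if (off_scale == 0) off_scale <- 1
  converged <- FALSE
  final_delta <- Inf
  for (iter in seq_len(max_iter)) {
    w_old <- w
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      w11 <- w[idx, idx, drop = FALSE]
      s12 <- s[idx, j]
      beta <- beta_store[, j]
      # inner lasso coordinate descent on: min .5 b'W11 b - s12'b + lambda|b|_1
      for (inner in seq_len(100)) {
        beta_old <- beta
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(w11[k, ] * beta) + w11[k, k] * beta[k]
          beta[k] <- soft_threshold(r, lambda) / w11[k, k]
        }
        if (max(abs(beta - beta_old)) < tol * 1e-2) break
      }
      beta_store[, j] <- beta
      w12 <- drop(w11 %*% beta)
      w[idx, j] <- w12
      w[j, idx] <- w12
    }
    final_delta <- mean(abs(w - w_old)) / off_scale
    if (final_delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(
      "Graphical lasso did not converge in ", max_iter,
      " iterations (relative change ", signif(final_delta, 3),
      " > tol ", tol, ").",
      call. = FALSE
    )
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- beta_store[, j]
    theta[j, j] <- 1 / (w[j, j] - sum(w[idx, j] * beta))
    theta[idx, j] <- -beta * theta[j, j]
  }
  theta <- (theta + t(theta)) / 2
  list(w = w, theta = theta)
}

#' Sparse inverse covariance (graphical lasso) connectivity
#'
#' Estimates a sparse precision matrix by L1-penalised Gaussian
#' log-likelihood on the standardized time series, then converts it to
#' partial-correlation form \eqn{-\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}}.
#' Off-diagonal zeros of the precision matrix become exact zeros of the
#' connectivity matrix, so weak conditional dependencies are pruned.
#'
#' @inheritParams spearman_connectivity
#' @param lambda L1 penalty, \eqn{\ge 0}, on the scale of the correlation
#'   matrix (columns are standardized internally). Default 0.1.
#' @param max_iter,tol Outer coordinate-descent iteration cap and relative
#'   convergence tolerance.
#' @return An `fc_matrix`; attributes `precision` and `cov` carry the
#'   estimated precision matrix and its covariance dual for diagnostics.
#' @export
sice_connectivity <- function(ts, lambda = 0.1, max_iter = 200, tol = 1e-5) {
  check_ts(ts)
  check_no_constant(ts)
  if (lambda < 0) stop("`lambda` must be >= 0.", call. = FALSE)
  s <- cor(ts)
  fit <- glasso_fit(s, lambda, max_iter = max_iter, tol = tol)
  d <- sqrt(diag(fit$theta))
  w <- -fit$theta / outer(d, d)
  dimnames(w) <- dimnames(s)
  out <- new_fc_matrix(w, "sice", list(lambda = lambda))
  attr(out, "precision") <- fit$theta
  attr(out, "cov") <- fit$w
  out
}

discretize_column <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) stop("Cannot bin a constant column.", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Mutual information of two series under equal-width binning
#'
#' Histogram estimate of mutual information in nats. `mutual_information(x, x)`
#' equals the entropy of the binned series.
#'
#' @param x,y Numeric vectors of equal length.
#' @param bins Number of equal-width bins per margin.
#' @return Nonnegative scalar, nats.
#' @export
mutual_information <- function(x, y, bins) {
  bx <- discretize_column(x, bins)
  by <- discretize_column(y, bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / length(x)
  px <- tabulate(bx, nbins = bins) / length(x)
  py <- tabulate(by, nbins = bins) / length(y)
  pxy <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pxy[nz]))
}

#' Mutual-information connectivity
#'
#' Pairwise histogram mutual information between ROI columns, in nats.
#' Entries are nonnegative; the matrix is symmetric by construction and the
#' diagonal is set to 0 like every other estimator (per-column entropies are
#' available through [mutual_information()]).
#'
#' @inheritParams spearman_connectivity
#' @param bins Number of equal-width bins per margin; default
#'   `ceiling(sqrt(T))`. Must satisfy `2 <= bins <= T`.
#' @return An `fc_matrix` with nonnegative entries.
#' @export
mi_connectivity <- function(ts, bins = NULL) {
  check_ts(ts)
  check_no_constant(ts)
  t_len <- nrow(ts)
  if (is.null(bins)) bins <- ceiling(sqrt(t_len))
  if (bins < 2 || bins > t_len) {
    stop("`bins` must satisfy 2 <= bins <= number of time points.", call. = FALSE)
  }
  n <- ncol(ts)
  binned <- apply(ts, 2, discretize_column, bins = bins)
  w <- matrix(0, n, n, dimnames = list(colnames(ts), colnames(ts)))
  marg <- lapply(seq_len(n), function(j) tabulate(binned[, j], nbins = bins) / t_len)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      joint <- tabulate(binned[, i] + bins * (binned[, j] - 1L),
        nbins = bins * bins
      ) / t_len
      pxy <- outer(marg[[i]], marg[[j]])
      nz <- joint > 0
      w[i, j] <- w[j, i] <- sum(joint[nz] * log(joint[nz] / pxy[nz]))
    }
  }
  new_fc_matrix(w, "mutual_information", list(bins = bins))
}

#' Estimate a connectivity matrix with a named estimator
#'
#' Dispatcher over the five estimators; the workhorse behind
#' [fc_features()].
#'
#' @inheritParams spearman_connectivity
#' @param estimator One of `"spearman"`, `"bend"`, `"partial"`, `"sice"`,
#'   `"mutual_information"`.
#' @param ... Passed to the chosen estimator (e.g. `beta`, `ridge`,
#'   `lambda`, `bins`).
#' @return An `fc_matrix`.
#' @export
connectivity_matrix <- function(ts, estimator = c(
                                  "spearman", "bend", "partial", "sice",
                                  "mutual_information"
                                ), ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
    spearman = spearman_connectivity(ts, ...),
    bend = bend_connectivity(ts, ...),
    partial = partial_connectivity(ts, ...),
    sice = sice_connectivity(ts, ...),
    mutual_information = mi_connectivity(ts, ...)
  )
}

#' Write a connectivity matrix with a parameter sidecar
#'
#' Writes the matrix as a ROI-labelled CSV and a `.json` sidecar recording
#' the estimator and its parameters.
#'
#' @param cm An `fc_matrix`.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  jsonlite::write_json(
    list(estimator = attr(cm, "estimator"), params = attr(cm, "params")),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
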