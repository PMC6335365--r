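test_that("spearman connectivity matches rank arithmetic on hand cases", {
  ts <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  w <- spearman_connectivity(ts)
  expect_equal(w["a", "b"], 0.8) # 1 - 6*2/(4*15)
  expect_equal(w["a", "c"], -1)
  ts2 <- cbind(x = 1:5, y = 1:5)
  ts2 <- cbind(ts2, z = c(2, 1, 4, 3, 5))
  expect_equal(spearman_connectivity(ts2)["x", "y"], 1)
})

test_that("spearman is invariant to strictly monotone column transforms", {
  ts <- make_ts(40, 4, seed = 2)
  w1 <- spearman_connectivity(ts)
  ts2 <- ts
  ts2[, 1] <- exp(ts2[, 1])
  ts2[, 3] <- ts2[, 3]^3
  expect_equal(unclass(spearman_connectivity(ts2)), unclass(w1))
})

test_that("constant columns are rejected by the correlation estimators", {
  ts <- make_ts(20, 4)
  ts[, 2] <- 7
  expect_error(spearman_connectivity(ts), "Constant ROI column")
  expect_error(bend_connectivity(ts), "Constant ROI column")
})

test_that("percentage-bend reduces to Pearson at beta 0 and matches the
           direct algorithm transcription", {
  ts <- make_ts(60, 5, seed = 3)
  w0 <- bend_connectivity(ts, beta = 0)
  expect_equal(unclass(w0) + diag(ncol(ts)), cor(ts), tolerance = 1e-12,
    ignore_attr = TRUE
  )

  w <- bend_connectivity(ts, beta = 0.2)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(w[i, j], oracle_pbcor(ts[, i], ts[, j], 0.2),
        tolerance = 1e-12
      )
    }
  }
  ts_same <- cbind(a = ts[, 1], b = ts[, 1], c = ts[, 2])
  expect_equal(bend_connectivity(ts_same, beta = 0.2)["a", "b"], 1)
  expect_error(bend_connectivity(ts, beta = 0.5), "beta")
  expect_error(bend_connectivity(ts, beta = -0.1), "beta")
})

test_that("percentage-bend resists a gross outlier better than Pearson", {
  withr::with_seed(4, {
    x <- rnorm(80)
    y <- 0.8 * x + rnorm(80, sd = 0.4)
    clean_pearson <- cor(x, y)
    y_cont <- y
    y_cont[1] <- 40 # gross outlier
    contaminated_pearson <- cor(x, y_cont)
    ts <- cbind(a = x, b = y_cont, c = rnorm(80))
    bend <- bend_connectivity(ts, beta = 0.2)["a", "b"]
    expect_lt(
      abs(bend - clean_pearson),
      abs(contaminated_pearson - clean_pearson)
    )
  })
})

test_that("partial correlation agrees with the 3-variable closed form and
           the 2-variable identity", {
  withr::with_seed(5, {
    ts3 <- matrix(rnorm(200 * 3), 200, 3) %*%
      chol(matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3))
    colnames(ts3) <- c("x", "y", "z")
    r <- cor(ts3)
    expected <- (r["x", "y"] - r["x", "z"] * r["y", "z"]) /
      sqrt((1 - r["x", "z"]^2) * (1 - r["y", "z"]^2))
    w <- partial_connectivity(ts3, ridge = 0)
    expect_equal(w["x", "y"], expected, tolerance = 1e-10)

    ts2 <- ts3[, 1:2]
    # nothing to condition on: partial equals Pearson up to cov scaling
    expect_equal(partial_connectivity(ts2, ridge = 0)[1, 2], r["x", "y"],
      tolerance = 1e-10
    )
  })
})

test_that("partial correlation of independent columns is near zero and
           singular covariance demands a ridge", {
  ts <- make_ts(2000, 4, seed = 6)
  w <- partial_connectivity(ts, ridge = 0)
  expect_lt(max(abs(w)), 0.1)

  short <- make_ts(3, 6, seed = 7) # T < N: singular
  expect_error(partial_connectivity(short, ridge = 0), "ridge")
  expect_silent(w2 <- partial_connectivity(short)) # default ridge kicks in
  expect_true(all(is.finite(w2)))
})

test_that("graphical lasso shrinks fully at large lambda and matches the
           dense inverse at lambda 0", {
  ts <- make_ts(300, 5, seed = 8)
  s <- cor(ts)
  lam_max <- max(abs(s[upper.tri(s)]))
  w_big <- sice_connectivity(ts, lambda = lam_max + 0.05)
  expect_equal(max(abs(w_big[upper.tri(w_big)])), 0)

  w0 <- sice_connectivity(ts, lambda = 0, tol = 1e-8)
  # lambda = 0: precision is the plain inverse, so the partial-correlation
  # transform of the standardized data is the oracle
  std <- scale(ts)
  expect_equal(unclass(w0), unclass(partial_connectivity(std, ridge = 0)),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})

test_that("graphical lasso solution satisfies the KKT conditions", {
  ts <- make_ts(200, 6, seed = 9)
  lambda <- 0.15
  w <- sice_connectivity(ts, lambda = lambda, tol = 1e-7)
  theta <- attr(w, "precision")
  sigma_hat <- attr(w, "cov")
  s <- cor(ts)
  grad <- sigma_hat - s # d/dTheta of loglik at the solution
  off <- upper.tri(theta)
  zero_entries <- off & abs(theta) < 1e-8
  active <- off & abs(theta) >= 1e-8
  expect_true(all(abs(grad[zero_entries]) <= lambda + 1e-4))
  if (any(active)) {
    expect_equal(grad[active], -lambda * sign(theta[active]), tolerance = 1e-3)
  }
})

test_that("mutual information recovers log k for identical equiprobable
           columns and is exactly symmetric", {
  k <- 4
  x <- rep(seq_len(k), each = 10) + 0 # k equal-count levels
  expect_equal(mutual_information(x, x, bins = k), log(k))

  ts <- make_ts(100, 4, seed = 10)
  w <- mi_connectivity(ts)
  expect_identical(unclass(w), t(unclass(w)))
  expect_true(all(w >= 0))
  expect_error(mi_connectivity(ts, bins = 1), "bins")
  expect_error(mi_connectivity(make_ts(4, 3), bins = 5), "bins")
})

test_that("mutual information of independent series stays near the
           small-sample bias floor", {
  ts <- make_ts(3000, 3, seed = 11)
  w <- mi_connectivity(ts, bins = 8)
  # chi-square approximation of histogram-MI bias: (k-1)^2 / (2T)
  bias_bound <- (8 - 1)^2 / (2 * 3000)
  expect_lt(max(w[upper.tri(w)]), 5 * bias_bound)
})

test_that("all five estimators return symmetric finite same-shape matrices
           and are permutation-equivariant", {
  ts <- make_ts(64, 5, seed = 12)
  perm <- c(3, 1, 5, 2, 4)
  for (est in c("spearman", "bend", "partial", "sice", "mutual_information")) {
    w <- connectivity_matrix(ts, est)
    expect_equal(dim(w), c(5, 5))
    expect_true(all(is.finite(w)))
    expect_lt(max(abs(w - t(w))), 1e-10)
    expect_equal(diag(unclass(w)), rep(0, 5), ignore_attr = TRUE)
    wp <- connectivity_matrix(ts[, perm], est)
    expect_equal(unclass(wp), unclass(w)[perm, perm], tolerance = 1e-8,
      ignore_attr = TRUE
    )
  }
})

test_that("connectivity CSV export carries labels and a parameter sidecar", {
  dir <- withr::local_tempdir()
  w <- bend_connectivity(make_ts(40, 4, seed = 13), beta = 0.1)
  path <- file.path(dir, "cm.csv")
  write_connectivity(w, path)
  back <- read.csv(path, row.names = 1)
  expect_equal(as.matrix(back), unclass(w), ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$estimator, "bend")
  expect_equal(meta$params$beta, 0.1)
})
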