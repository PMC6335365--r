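test_that("cross-validation on perfectly separated groups is perfect and
           confusion identities hold on every run", {
  tb <- make_feature_table(n_per_group = 20, n_features = 4, n_info = 2,
                           shift = 8, seed = 71)
  cv <- cross_validate(tb, c("f001", "f002"), folds = 10, seed = 72)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$chance, 0.5)

  # identities on an imperfect run
  tb2 <- make_feature_table(n_per_group = 18, n_features = 6, n_info = 1,
                            shift = 1, seed = 73)
  cv2 <- cross_validate(tb2, feature_names(tb2), folds = 6, seed = 74)
  agg <- colSums(cv2$folds[, c("tp", "tn", "fp", "fn")])
  expect_equal(sum(agg), cv2$n)
  expect_equal(cv2$accuracy, (agg[["tp"]] + agg[["tn"]]) / cv2$n)
  expect_equal(cv2$sensitivity, agg[["tp"]] / (agg[["tp"]] + agg[["fn"]]))
  expect_equal(cv2$specificity, agg[["tn"]] / (agg[["tn"]] + agg[["fp"]]))
  expect_equal(sum(tidy(cv2)$tp), agg[["tp"]])
  expect_equal(glance(cv2)$accuracy, cv2$accuracy)
})

test_that("chance level is the majority-class proportion", {
  tb <- make_feature_table(n_per_group = 24, n_features = 4, n_info = 0,
                           seed = 75)
  tb <- tb[1:40, ] # 24 ASD / 16 HC
  tb$subject_id <- sprintf("s%03d", seq_len(nrow(tb)))
  cv <- cross_validate(tb, feature_names(tb), folds = 4, seed = 76)
  expect_equal(cv$chance, 0.6)
})

test_that("every subject is predicted exactly once with stratified folds", {
  tb <- make_feature_table(n_per_group = 13, n_features = 5, n_info = 1,
                           shift = 2, seed = 77)
  cv <- cross_validate(tb, feature_names(tb), folds = 5, seed = 78)
  expect_equal(sum(cv$folds$tp + cv$folds$tn + cv$folds$fp + cv$folds$fn), 26)
  expect_equal(length(cv$fold_id), 26)
  expect_equal(sort(unique(cv$fold_id)), 1:5)
})

test_that("Welch statistics match the closed form, including degenerate
           branches", {
  a <- c(0.84, 0.80, 0.86, 0.78, 0.83, 0.85, 0.79, 0.81, 0.84, 0.82)
  b <- c(0.70, 0.74, 0.69, 0.73, 0.75, 0.68, 0.72, 0.71, 0.74, 0.70)
  got <- graphfc:::welch_t(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-9)

  same <- graphfc:::welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_warning(
    sep <- graphfc:::welch_t(rep(1, 10), rep(0.5, 10)),
    "Zero within-sample variance"
  )
  expect_equal(sep$p.value, 0)
})

test_that("BH correction follows the step-up arithmetic and caps at 1", {
  expect_equal(fdr_correct(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(fdr_correct(0.2), 0.2)
  expect_equal(fdr_correct(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9))
  withr::with_seed(79, {
    p <- runif(40)
    expect_equal(fdr_correct(p), oracle_bh(p))
    expect_true(all(fdr_correct(p) >= p))
    expect_true(all(fdr_correct(p) <= 1))
  })
})

test_that("pipeline comparison: self-comparison is null, tables are
           symmetric, corrected >= raw", {
  sim <- simulate_cohort(simulation_config(
    n_rois = 8, t_timepoints = 60, n_per_group = 8, module_sizes = c(4, 4),
    effect = effect_spec("densify_module", delta = 0.3), seed = 80
  ))
  ft <- fc_features(sim$cohort, "spearman")
  tabs <- list(one = ft, two = ft, noise = {
    ftn <- ft
    fn <- feature_names(ftn)
    ftn[fn] <- withr::with_seed(81, {
      as.data.frame(matrix(rnorm(nrow(ftn) * length(fn)), nrow(ftn)))
    })
    ftn
  })
  cmp <- repeated_cv_compare(
    tabs,
    features = list(one = feature_names(ft)[1:5],
                    two = feature_names(ft)[1:5],
                    noise = feature_names(ft)[1:5]),
    repeats = 4, folds = 4, seed = 82
  )
  expect_equal(cmp$accuracy[, "one"], cmp$accuracy[, "two"])
  expect_equal(cmp$statistic["one", "two"], 0)
  expect_equal(cmp$p.value["one", "two"], 1)
  expect_equal(cmp$p.value, t(cmp$p.value))
  expect_equal(cmp$p.adjusted, t(cmp$p.adjusted))
  expect_true(all(cmp$p.adjusted >= cmp$p.value - 1e-12))
  expect_true(all(cmp$p.adjusted <= 1))
  td <- tidy(cmp)
  expect_equal(nrow(td), 3)
  expect_error(repeated_cv_compare(tabs, repeats = 1), "2 repetitions")
})

test_that("fold-level comparison mode returns repeats x folds samples", {
  tb <- make_feature_table(n_per_group = 12, n_features = 6, n_info = 1,
                           shift = 2, seed = 83)
  cmp <- repeated_cv_compare(
    list(a = tb, b = tb),
    features = list(a = "f001", b = "f002"),
    repeats = 3, folds = 4, seed = 84, level = "fold"
  )
  expect_equal(nrow(cmp$accuracy), 12)
})

test_that("CV results serialize to JSON + per-fold CSV", {
  dir <- withr::local_tempdir()
  tb <- make_feature_table(n_per_group = 10, n_features = 4, n_info = 1,
                           shift = 3, seed = 85)
  cv <- cross_validate(tb, feature_names(tb), folds = 4, seed = 86)
  write_cv_result(cv, file.path(dir, "cv"))
  meta <- jsonlite::read_json(file.path(dir, "cv.json"))
  expect_equal(meta$accuracy, cv$accuracy)
  folds <- read.csv(file.path(dir, "cv_folds.csv"))
  expect_equal(nrow(folds), 4)
})
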