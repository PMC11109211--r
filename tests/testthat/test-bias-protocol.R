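test_that("stratified folds keep both classes in every test fold", {
  y <- rep(c(0L, 1L), c(40, 12))
  folds <- stratified_folds(y, n_folds = 5, seed = 3)
  expect_equal(sort(unlist(folds)), seq_along(y))
  for (f in folds) expect_setequal(unique(y[f]), c(0L, 1L))
  expect_identical(folds, stratified_folds(y, n_folds = 5, seed = 3))
  expect_error(stratified_folds(rep(c(0L, 1L), c(50, 3)), n_folds = 5),
               "stratify")
})

small_setup <- function(balance = 3, seed = 1) {
  tab <- preprocess(generate_radiomics_like(
    synthetic_spec(80, 20, balance = balance, seed = seed)))
  grid <- model_grid(scorers = "anova", n_features_grid = c(2L, 4L),
                     classifiers = "logistic_regression", lr_C_grid = c(0.1, 10))
  list(tab = tab, grid = grid, cv = cv_scheme(n_repeats = 3, base_seed = 9))
}

test_that("correct protocol never leaks synthetic rows into test folds", {
  s <- small_setup()
  for (m in c("smote", "random_oversampling", "random_undersampling")) {
    res <- run_correct(s$tab, resampler_spec(m, k = 5), s$grid, s$cv)
    expect_equal(sum(res$synthetic_test_rows), 0)
    expect_equal(nrow(res), 3)
    expect_true(all(res$auc >= 0 & res$auc <= 1))
  }
})

test_that("incorrect protocol leaks: synthetic test rows with parents in train", {
  s <- small_setup()
  res <- run_incorrect(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  expect_gt(sum(res$synthetic_test_rows), 0)
  expect_gt(sum(res$leaky_test_rows), 0)
  # undersampling creates nothing, so nothing can leak
  res_u <- run_incorrect(s$tab, "random_undersampling", s$grid, s$cv)
  expect_equal(sum(res_u$synthetic_test_rows), 0)
})

test_that("protocol runs are deterministic and arms share repeat seeds", {
  s <- small_setup()
  r1 <- run_correct(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  r2 <- run_correct(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  expect_identical(r1, r2)
  # identity resampler reduces both arms to the same plain repeated CV
  ci <- run_correct(s$tab, "none", s$grid, s$cv)
  ii <- run_incorrect(s$tab, "none", s$grid, s$cv)
  expect_equal(ci$auc, ii$auc)
})

test_that("on balanced data SMOTE is a no-op and bias vanishes", {
  s <- small_setup(balance = 1)
  co <- run_correct(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  inc <- run_incorrect(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  b <- compute_bias(co, inc)
  expect_equal(b$summary$mean_bias, rep(0, 5))
})

test_that("compute_bias is incorrect minus correct, per repeat and metric", {
  s <- small_setup()
  co <- run_correct(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  inc <- run_incorrect(s$tab, resampler_spec("smote", k = 5), s$grid, s$cv)
  b <- compute_bias(co, inc)
  expect_equal(b$records$bias_auc, inc$auc - co$auc, tolerance = 1e-12)
  expect_equal(b$records$bias_brier, inc$brier - co$brier, tolerance = 1e-12)
  expect_equal(b$summary$mean_bias[b$summary$metric == "auc"],
               mean(inc$auc) - mean(co$auc), tolerance = 1e-12)
  # identical scenarios give all-zero bias
  b0 <- compute_bias(co, co)
  expect_true(all(abs(b0$records[grep("bias_", names(b0$records))]) < 1e-15))
})

test_that("SMOTE leakage bias grows with class balance on pure-noise data", {
  mg <- model_grid(scorers = "anova", n_features_grid = 4L,
                   classifiers = "logistic_regression", lr_C_grid = 1)
  biases <- vapply(c(1, 2, 3, 4), function(b) {
    tb <- preprocess(generate_radiomics_like(
      synthetic_spec(80, 20, balance = b, seed = 50 + b)))
    cv <- cv_scheme(n_repeats = 5, base_seed = 77)
    co <- run_correct(tb, resampler_spec("smote", k = 5), mg, cv)
    inc <- run_incorrect(tb, resampler_spec("smote", k = 5), mg, cv)
    mean(inc$auc - co$auc)
  }, numeric(1))
  expect_equal(biases[1], 0)    # balanced: nothing generated
  expect_gt(stats::cor(biases, 1:4, method = "spearman"), 0)
  expect_gt(biases[4], 0)
})

test_that("balance association recovers a hand-computed 3-point OLS", {
  # oracle: x = (1, 2, 4), y = (0.1, 0.2, 0.3);
  # slope = Sxy/Sxx = 0.3/4.6667, intercept = ybar - slope * xbar
  x <- c(1, 2, 4); y <- c(0.1, 0.2, 0.3)
  out <- associate_with_balance(y, x)
  expect_equal(out$slope, 0.3 / (21 - 3 * (7 / 3)^2), tolerance = 1e-12)
  expect_equal(out$intercept, 0.2 - out$slope * 7 / 3, tolerance = 1e-12)
  expect_equal(out$r, stats::cor(x, y), tolerance = 1e-12)

  lin <- suppressWarnings(
    associate_with_balance(c(0.1, 0.2, 0.3, 0.4), c(1, 2, 3, 4)))
  expect_equal(lin$r, 1, tolerance = 1e-12)
  expect_lt(lin$p_value, 1e-6)
  flat <- suppressWarnings(associate_with_balance(rep(0.2, 4), c(1, 2, 3, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(associate_with_balance(c(1, 2), c(1, 2)), "3 datasets")
})
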