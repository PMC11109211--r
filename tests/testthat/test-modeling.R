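test_that("ANOVA F-scores match R's one-way ANOVA", {
  # hand/lm oracle on the 2+2 toy: SSB = 4, MSW = 0.5 -> F = 8
  f <- anova_score(matrix(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(f, 8)

  withr::with_seed(21, {
    X <- matrix(rnorm(40 * 6), ncol = 6)
    y <- rep(c(0L, 1L), each = 20)
  })
  ours <- anova_score(X, y)
  ref <- apply(X, 2, function(col)
    summary(stats::aov(col ~ factor(y)))[[1]][["F value"]][1])
  expect_equal(ours, ref, tolerance = 1e-10)

  # conventions: constant feature scores 0; label-equal feature caps and
  # ranks first
  Xc <- cbind(rep(1, 40), as.numeric(y), X[, 1])
  fc <- anova_score(Xc, y)
  expect_equal(fc[1], 0)
  expect_equal(fc[2], 1e12)
  expect_equal(select_top_k(fc, 1), 2L)
})

test_that("Bhattacharyya distance follows the Gaussian closed form", {
  # mu1 = 0, mu2 = 2, sd1 = sd2 = 1 -> BD = 0.5; build data with exact
  # sample moments
  base <- c(-1, 0, 1)   # mean 0, sample var exactly 1
  X <- matrix(c(base, base + 2))
  y <- rep(c(0L, 1L), each = 3)
  expect_equal(bhattacharyya_score(X, y), 0.5, tolerance = 1e-12)
  # symmetric under class swap, zero for identical distributions
  expect_equal(bhattacharyya_score(X, 1L - y), 0.5, tolerance = 1e-12)
  expect_equal(bhattacharyya_score(matrix(rep(base, 2)), y), 0,
               tolerance = 1e-9)
})

test_that("extra-trees importances are a normalized, reproducible ranking", {
  withr::with_seed(5, {
    X <- matrix(rnorm(100 * 8), ncol = 8)
    y <- as.integer(X[, 3] + 0.3 * rnorm(100) > 0)
  })
  s1 <- extratrees_score(X, y, seed = 7)
  s2 <- extratrees_score(X, y, seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1), 1)
  expect_true(all(s1 >= 0))
  expect_equal(which.max(s1), 3L)
})

test_that("LASSO scores shrink label-independent features to zero", {
  withr::with_seed(6, {
    X <- matrix(rnorm(150 * 10), ncol = 10)
    y <- as.integer(X[, 1] - X[, 2] + 0.5 * rnorm(150) > 0)
  })
  s <- lasso_score(X, y)
  expect_true(all(s >= 0))
  expect_equal(sort(select_top_k(s, 2)), 1:2)
  expect_lt(mean(s[3:10]), mean(s[1:2]) / 3)
  expect_identical(s, lasso_score(X, y))
})

test_that("select_top_k clamps k and breaks ties by lowest index", {
  expect_equal(select_top_k(c(0.1, 0.9, 0.5), 1), 2L)
  expect_equal(select_top_k(c(0.5, 0.5), 1), 1L)
  expect_equal(sort(select_top_k(c(0.1, 0.9, 0.5), 10)), 1:3)
})

test_that("classifiers return calibrated-scale probabilities and are seeded", {
  withr::with_seed(9, {
    Xtr <- rbind(matrix(rnorm(60, -2), ncol = 2),
                 matrix(rnorm(60, 2), ncol = 2))
    ytr <- rep(c(0L, 1L), each = 30)
    Xte <- rbind(matrix(rnorm(20, -2), ncol = 2),
                 matrix(rnorm(20, 2), ncol = 2))
    yte <- rep(c(0L, 1L), each = 10)
  })
  for (clf in c("logistic_regression", "naive_bayes", "rbf_svm",
                "random_forest", "knn")) {
    hp <- switch(clf, logistic_regression = list(C = 10),
                 rbf_svm = list(C = 100, gamma = "auto"),
                 knn = list(k = 3), list())
    p1 <- train_predict(Xtr, ytr, Xte, clf, hp, seed = 3)
    p2 <- train_predict(Xtr, ytr, Xte, clf, hp, seed = 3)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    # linearly separable toy: every classifier should separate it
    expect_equal(evaluate(p1, yte)$auc, 1, tolerance = 1e-9)
  }
  expect_error(train_predict(Xtr, rep(0L, 60), Xte, "naive_bayes"),
               "both classes")
})

test_that("naive Bayes drifts to the class prior on uninformative features", {
  withr::with_seed(10, {
    Xtr <- matrix(rnorm(400), ncol = 2)
    ytr <- rep(c(0L, 1L), c(150, 50))   # prior 0.25 for the positive class
    Xte <- matrix(rnorm(50), ncol = 2)
  })
  p <- train_predict(Xtr, ytr, Xte, "naive_bayes", seed = 1)
  expect_equal(mean(p), 0.25, tolerance = 0.1)
})

test_that("evaluate reproduces hand-counted metrics and identities", {
  y <- c(1L, 1L, 0L, 0L)
  perfect <- evaluate(c(1, 1, 0, 0), y)
  expect_equal(unlist(perfect[c("auc", "sensitivity", "specificity",
                                "balanced_accuracy", "brier")]),
               c(auc = 1, sensitivity = 1, specificity = 1,
                 balanced_accuracy = 1, brier = 0))

  m <- evaluate(c(0.9, 0.4, 0.6, 0.1), y)
  expect_equal(m$auc, 0.75)   # brute-force pair count: 3 of 4 pairs ordered
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$balanced_accuracy, 0.5)

  const <- evaluate(rep(0.5, 4), y)
  expect_equal(const$auc, 0.5)
  expect_equal(const$brier, 0.25)

  expect_error(evaluate(c(0.2, 0.8), c(1L, 1L)), "both classes")
})

test_that("AUC is rank-based: monotone-invariant, class-symmetric, pROC-equal", {
  withr::with_seed(13, {
    p <- runif(60)
    y <- rbinom(60, 1, 0.4)
  })
  a <- evaluate(p, y)$auc
  expect_equal(evaluate(plogis(5 * p - 2), y)$auc, a)     # monotone transform
  expect_equal(evaluate(1 - p, 1L - y)$auc, a)            # class symmetry
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("balanced accuracy identity holds across random predictions", {
  for (s in 1:10) {
    withr::with_seed(s, {
      p <- runif(30)
      y <- c(0L, 1L, rbinom(28, 1, 0.5))
    })
    m <- evaluate(p, y)
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2,
                 tolerance = 1e-12)
    expect_gte(m$brier, 0)
    expect_lte(m$brier, 1)
  }
})

test_that("Brier score favors the true conditional probability", {
  # Bernoulli toy: predicting the true p beats any mis-calibrated constant
  withr::with_seed(14, y <- rbinom(4000, 1, 0.3))
  true_p <- mean((0.3 - y)^2)
  off_p <- mean((0.6 - y)^2)
  expect_lt(true_p, off_p)
})
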