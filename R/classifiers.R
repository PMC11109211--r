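#' Train a classifier and predict positive-class probabilities
#'
#' One uniform entry point over the classifier grid. All classifiers return a
#' probability of the positive class for every test row; the RBF-SVM gets its
#' probabilities by Platt scaling fitted on out-of-fold decision values from
#' an internal stratified 3-fold split of the training data, so that the
#' Brier score is computed on calibrated probabilities and the AUC on the
#' same (rank-equivalent) values.
#'
#' @param train_features numeric matrix of training features.
#' @param train_labels 0/1 training labels (both classes required).
#' @param test_features numeric matrix with the same columns.
#' @param classifier one of `"logistic_regression"`, `"naive_bayes"`,
#'   `"rbf_svm"`, `"random_forest"`, `"knn"`.
#' @param hyperparams named list: `C` for logistic regression; `C` and
#'   `gamma` (`"auto"` = `1/d`) for the SVM; `n_trees` for the random forest
#'   (default 250); `k` for k-NN.
#' @param seed integer seed controlling every stochastic element.
#' @return numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
train_predict <- function(train_features, train_labels, test_features,
                          classifier, hyperparams = list(), seed = 1L) {
  if (length(unique(train_labels)) < 2L)
    stop("training data must contain both classes")
  train_features <- as.matrix(train_features)
  test_features <- matrix(as.numeric(test_features),
                          ncol = ncol(train_features))
  withr::with_seed(as.integer(seed), {
    switch(classifier,
      logistic_regression =
        .fit_logistic(train_features, train_labels, test_features,
                      C = hyperparams$C %||% 1),
      naive_bayes =
        .fit_naive_bayes(train_features, train_labels, test_features),
      rbf_svm =
        .fit_rbf_svm(train_features, train_labels, test_features,
                     C = hyperparams$C %||% 1,
                     gamma = hyperparams$gamma %||% "auto"),
      random_forest =
        .fit_random_forest(train_features, train_labels, test_features,
                           n_trees = hyperparams$n_trees %||% 250L,
                           seed = seed),
      knn =
        .fit_knn(train_features, train_labels, test_features,
                 k = hyperparams$k %||% 5L),
      stop(sprintf("unknown classifier '%s'", classifier))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# L2-penalized logistic regression; C is the inverse regularization strength,
# mapped to the glmnet penalty as lambda = 1 / (n * C)
.fit_logistic <- function(Xtr, ytr, Xte, C) {
  if (ncol(Xtr) == 1L) { Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0) }
  fit <- glmnet::glmnet(Xtr, factor(ytr, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / (nrow(Xtr) * C), standardize = FALSE,
                        maxit = 1e6)
  as.numeric(stats::predict(fit, Xte, type = "response"))
}

.fit_naive_bayes <- function(Xtr, ytr, Xte) {
  colnames(Xtr) <- colnames(Xte) <- paste0("f", seq_len(ncol(Xtr)))
  fit <- e1071::naiveBayes(Xtr, factor(ytr, levels = c(0, 1)))
  p <- stats::predict(fit, Xte, type = "raw")[, "1"]
  p[is.na(p)] <- mean(ytr)    # degenerate densities fall back to the prior
  pmin(pmax(p, 0), 1)
}

.fit_rbf_svm <- function(Xtr, ytr, Xte, C, gamma) {
  if (identical(gamma, "auto")) gamma <- 1 / ncol(Xtr)
  y <- factor(ytr, levels = c(0, 1))
  fit <- e1071::svm(Xtr, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  dv_test <- .svm_decision(fit, Xte)
  # Platt scaling on out-of-fold decision values (internal 3-fold)
  folds <- stratified_folds(ytr, n_folds = 3L,
                            seed = sample.int(.Machine$integer.max, 1L))
  oof <- numeric(length(ytr))
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_along(ytr), te)
    if (length(unique(ytr[tr])) < 2L) { oof[te] <- NA_real_; next }
    sub <- e1071::svm(Xtr[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    oof[te] <- .svm_decision(sub, Xtr[te, , drop = FALSE])
  }
  ok <- !is.na(oof)
  platt <- suppressWarnings(
    stats::glm(ytr[ok] ~ oof[ok], family = stats::binomial()))
  co <- stats::coef(platt)
  if (anyNA(co)) co[is.na(co)] <- 0
  as.numeric(stats::plogis(co[1] + co[2] * dv_test))
}

# decision values oriented so larger = more positive-class
.svm_decision <- function(fit, X) {
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  v <- as.numeric(dv)
  if (colnames(dv)[1] == "0/1") -v else v
}

.fit_random_forest <- function(Xtr, ytr, Xte, n_trees, seed) {
  colnames(Xtr) <- colnames(Xte) <- paste0("f", seq_len(ncol(Xtr)))
  fit <- ranger::ranger(x = Xtr, y = factor(ytr, levels = c(0, 1)),
                        num.trees = as.integer(n_trees), probability = TRUE,
                        seed = as.integer(seed), num.threads = 1L)
  stats::predict(fit, Xte, num.threads = 1L)$predictions[, "1"]
}

.fit_knn <- function(Xtr, ytr, Xte, k) {
  pred <- class::knn(Xtr, Xte, factor(ytr, levels = c(0, 1)),
                     k = as.integer(k), prob = TRUE)
  win <- attr(pred, "prob")
  ifelse(pred == "1", win, 1 - win)
}
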