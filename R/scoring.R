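#' One-way ANOVA F-score per feature
#'
#' The classic univariate filter: between-class over within-class variance
#' ratio, computed for every feature at once. Constant features score 0;
#' features with zero within-class variance but distinct class means (e.g. a
#' feature equal to the label) would have an infinite F and are capped at
#' `1e12` so that ranking stays well defined.
#'
#' @param features numeric matrix (n x d), no missing values.
#' @param labels 0/1 vector.
#' @return numeric vector of length d; higher = more relevant.
#' @export
anova_score <- function(features, labels) {
  g0 <- labels == 0L; g1 <- !g0
  n0 <- sum(g0); n1 <- sum(g1)
  if (n0 < 2L || n1 < 2L) stop("each class needs at least 2 samples")
  n <- n0 + n1
  m0 <- colMeans(features[g0, , drop = FALSE])
  m1 <- colMeans(features[g1, , drop = FALSE])
  grand <- (n0 * m0 + n1 * m1) / n
  ssb <- n0 * (m0 - grand)^2 + n1 * (m1 - grand)^2
  ssw <- colSums((features[g0, , drop = FALSE] -
                    matrix(m0, n0, length(m0), byrow = TRUE))^2) +
         colSums((features[g1, , drop = FALSE] -
                    matrix(m1, n1, length(m1), byrow = TRUE))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- 1e12
  f[ssb == 0] <- 0
  f
}

#' Bhattacharyya distance per feature
#'
#' Distance between the two class-conditional Gaussians of each feature:
#' `BD = (mu1 - mu2)^2 / (4 * (s1^2 + s2^2)) + log((s1^2 + s2^2) / (2 * s1 * s2)) / 2`.
#' Zero variances are floored at `1e-12` so degenerate features score finitely.
#'
#' @inheritParams anova_score
#' @return numeric vector of length d; symmetric under class swap.
#' @export
bhattacharyya_score <- function(features, labels) {
  g0 <- labels == 0L; g1 <- !g0
  m0 <- colMeans(features[g0, , drop = FALSE])
  m1 <- colMeans(features[g1, , drop = FALSE])
  v0 <- pmax(apply(features[g0, , drop = FALSE], 2L, stats::var), 1e-12)
  v1 <- pmax(apply(features[g1, , drop = FALSE], 2L, stats::var), 1e-12)
  (m0 - m1)^2 / (4 * (v0 + v1)) + 0.5 * log((v0 + v1) / (2 * sqrt(v0 * v1)))
}

#' Extremely-randomized-trees importance per feature
#'
#' Impurity-based variable importance from a 100-tree extra-trees ensemble,
#' normalized to sum to 1.
#'
#' @inheritParams anova_score
#' @param seed integer seed for the ensemble.
#' @return nonnegative numeric vector of length d summing to 1.
#' @export
extratrees_score <- function(features, labels, seed = 1L) {
  X <- features
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = X, y = factor(labels), num.trees = 100L,
                        splitrule = "extratrees", num.random.splits = 1L,
                        replace = FALSE, sample.fraction = 1,
                        importance = "impurity", seed = as.integer(seed),
                        num.threads = 1L)
  imp <- unname(pmax(fit$variable.importance, 0))
  s <- sum(imp)
  if (s == 0) rep(1 / length(imp), length(imp)) else imp / s
}

#' L1-penalized logistic-regression score per feature
#'
#' Absolute coefficients of a LASSO logistic regression at a single fixed
#' penalty (inverse regularization strength `C`, default 1). Features whose
#' coefficients are shrunk to zero rank last. Inputs are expected to be
#' z-scored; the score is not scale-invariant.
#'
#' @inheritParams anova_score
#' @param C inverse regularization strength (default 1.0).
#' @return nonnegative numeric vector of length d.
#' @export
lasso_score <- function(features, labels, C = 1.0) {
  X <- features
  if (ncol(X) == 1L) X <- cbind(X, 0)   # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, factor(labels), family = "binomial", alpha = 1,
                        lambda = 1 / (nrow(X) * C), standardize = FALSE,
                        maxit = 1e6)
  abs(as.numeric(fit$beta))[seq_len(ncol(features))]
}

#' Indices of the top-k scoring features
#'
#' Ties are broken by lowest index; `k` is clamped to the number of features.
#'
#' @param scores numeric score vector.
#' @param k number of features to keep.
#' @return integer vector of feature indices, highest score first.
#' @export
select_top_k <- function(scores, k) {
  k <- min(k, length(scores))
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Score features with a named scorer
#'
#' @param scorer one of `"anova"`, `"bhattacharyya"`, `"extra_trees"`,
#'   `"lasso"`.
#' @inheritParams anova_score
#' @param seed seed for stochastic scorers.
#' @return numeric score vector.
#' @export
score_features <- function(scorer, features, labels, seed = 1L) {
  switch(scorer,
    anova = anova_score(features, labels),
    bhattacharyya = bhattacharyya_score(features, labels),
    extra_trees = extratrees_score(features, labels, seed = seed),
    lasso = lasso_score(features, labels),
    stop(sprintf("unknown scorer '%s'", scorer))
  )
}
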