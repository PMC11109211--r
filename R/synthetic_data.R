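#' Specification for a radiomics-like synthetic dataset
#'
#' Describes the statistical shape of a tabular radiomics dataset: sample
#' size, dimensionality (d >> n allowed), class balance, a small informative
#' feature subset with a class-mean shift, equicorrelated nuisance features
#' mimicking the heavy feature redundancy of radiomic exports, and optional
#' missing cells.
#'
#' @param n_samples total number of samples (>= 4).
#' @param n_features number of features.
#' @param n_informative number of label-associated features (may be 0 for a
#'   pure-noise dataset).
#' @param effect_size class-mean shift of the informative features, in SD
#'   units, before normalization.
#' @param balance majority/minority ratio (>= 1); the minority class is the
#'   positive class and gets `round(n_samples / (1 + balance))` samples.
#' @param missing_rate fraction of cells set to missing, in `[0, 1)`.
#' @param correlation equicorrelation among nuisance features, in `[0, 1)`.
#' @param seed integer seed; all randomness of the generator flows through it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples, n_features, n_informative = 0L,
                           effect_size = 0, balance = 1, missing_rate = 0,
                           correlation = 0.5, seed = 1L) {
  stopifnot(n_samples >= 4, n_features >= 1, n_informative >= 0,
            n_informative <= n_features, effect_size >= 0, balance >= 1,
            missing_rate >= 0, missing_rate < 1,
            correlation >= 0, correlation < 1)
  n_min <- round(n_samples / (1 + balance))
  if (n_min < 2)
    stop("invalid spec: minority class would have fewer than 2 samples")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, balance = balance,
                 missing_rate = missing_rate, correlation = correlation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a radiomics-like labeled table
#'
#' Emulates the statistical shape of tabular radiomic datasets. The minority
#' (positive) class count is `round(n / (1 + balance))`. The first
#' `n_informative` features are independent unit-variance Gaussians whose
#' class means differ by `effect_size`; the remaining features are
#' label-independent draws from an equicorrelated Gaussian (pairwise
#' correlation `correlation`), emulating redundant texture features. With
#' `effect_size = 0` the label carries no information about any feature, so a
#' correctly cross-validated classifier can only reach AUC 0.5 on average.
#'
#' @param spec a [synthetic_spec()].
#' @return a [labeled_table()] with all-original provenance and exact class
#'   counts implied by `balance`.
#' @export
generate_radiomics_like <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  d <- spec$n_features
  n_min <- round(n / (1 + spec$balance))
  n_maj <- n - n_min
  withr::with_seed(spec$seed, {
    y <- sample(rep(c(0L, 1L), c(n_maj, n_min)))
    X <- matrix(0, n, d)
    k <- spec$n_informative
    if (k > 0) {
      X[, seq_len(k)] <- matrix(stats::rnorm(n * k), n, k) +
        outer(ifelse(y == 1L, spec$effect_size, 0), rep(1, k))
    }
    if (d > k) {
      rho <- spec$correlation
      shared <- stats::rnorm(n)   # one latent factor per sample
      noise <- matrix(stats::rnorm(n * (d - k)), n, d - k)
      X[, (k + 1):d] <- sqrt(rho) * shared + sqrt(1 - rho) * noise
    }
    if (spec$missing_rate > 0) {
      n_miss <- round(spec$missing_rate * n * d)
      X[sample(n * d, n_miss)] <- NA_real_
    }
    colnames(X) <- c(if (k > 0) paste0("inf_", seq_len(k)),
                     if (d > k) paste0("tex_", seq_len(d - k)))
    labeled_table(X, y)
  })
}

#' Specification for one random-label simulation point
#'
#' Parameters of the random-data experiment: 2-D features drawn uniformly on
#' \[-1, 1\], `N` negative samples plus `N * B / 100` positive samples with
#' labels independent of the coordinates by construction, a repeated
#' stratified train/test split, SMOTE on the training data (or, in the leaky
#' arm, on everything), and a deliberately overfitting-prone RBF-SVM.
#'
#' @param B balance in percent, in (0, 100]: positives = `round(N * B / 100)`.
#' @param N negative-class count.
#' @param n_repeats number of repeated splits (default 100).
#' @param test_fraction held-out fraction of each split (default 0.2).
#' @param smote_k SMOTE neighborhood size (default 5).
#' @param svm_C,svm_gamma RBF-SVM hyperparameters; the defaults (50, 500) are
#'   intentionally large so the classifier can memorize local structure.
#' @param seed base seed; repeat `r` uses `seed + r`.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(B, N, n_repeats = 100L, test_fraction = 0.2,
                     smote_k = 5L, svm_C = 50, svm_gamma = 500, seed = 1L) {
  stopifnot(B > 0, B <= 100, N >= 1, n_repeats >= 1,
            test_fraction > 0, test_fraction < 1,
            smote_k >= 1, svm_C > 0, svm_gamma > 0)
  if (round(N * B / 100) < 2)
    stop("invalid spec: positive count N*B/100 must round to at least 2")
  structure(list(B = B, N = as.integer(N), n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, smote_k = as.integer(smote_k),
                 svm_C = svm_C, svm_gamma = svm_gamma, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate one random-label simulation dataset
#'
#' `N` negative samples, then `round(N * B / 100)` positive samples, each with
#' two coordinates drawn i.i.d. uniformly on \[-1, 1\]. Labels are assigned by
#' position in the draw order, so they are independent of the features by
#' construction: no classifier can genuinely beat AUC 0.5 on such data.
#'
#' @param B balance in percent (positives = `round(N * B / 100)`).
#' @param N negative-class count.
#' @param seed integer seed.
#' @return a [labeled_table()] with `d = 2`.
#' @export
generate_sim_data <- function(B, N, seed) {
  n_pos <- round(N * B / 100)
  if (n_pos < 2) stop("positive count N*B/100 must round to at least 2")
  withr::with_seed(as.integer(seed), {
    X <- matrix(stats::runif((N + n_pos) * 2, -1, 1), ncol = 2)
    colnames(X) <- c("x1", "x2")
    labeled_table(X, rep(c(0L, 1L), c(N, n_pos)))
  })
}
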