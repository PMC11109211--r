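#' Stratified fold assignment
#'
#' Shuffles each class independently and deals it into `n_folds` near-equal
#' parts, so every test fold contains both classes whenever each class has at
#' least `n_folds` members.
#'
#' @param labels 0/1 vector.
#' @param n_folds number of folds.
#' @param seed integer seed for the shuffle.
#' @return list of integer vectors, the test indices of each fold.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  classes <- unique(labels)
  if (any(tabulate(factor(labels)) < n_folds) ||
      min(table(labels)) < n_folds)
    stop("cannot stratify: a class has fewer members than folds")
  assign <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lapply(seq_len(n_folds), function(f) which(assign == f))
}

#' Stratified train/test holdout split
#'
#' @param labels 0/1 vector.
#' @param test_fraction fraction held out, per class (rounded, at least 1).
#' @param seed integer seed.
#' @return integer vector of test indices.
#' @export
stratified_holdout <- function(labels, test_fraction = 0.2, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(length(idx) * test_fraction)))
    }))
  })
}

#' Cross-validation scheme
#'
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 30; scale down for quick runs).
#' @param base_seed integer; repeat `r` uses `base_seed + r` for the fold
#'   shuffle, the resampler, and any stochastic scorer or classifier, in both
#'   protocol arms, so the correct/incorrect comparison is matched.
#' @return a `cv_scheme` list.
#' @export
cv_scheme <- function(n_folds = 5L, n_repeats = 30L, base_seed = 0L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = TRUE, base_seed = as.integer(base_seed)),
            class = "cv_scheme")
}

#' Model search grid
#'
#' The feature-scorer x feature-count x classifier x hyperparameter grid
#' searched inside each protocol arm. `default_model_grid(full = TRUE)` gives
#' the full benchmark grid (4 scorers; 1, 2, 4, ..., 64 features; LR / naive
#' Bayes / RBF-SVM / random forest with `C` in powers of two from 2^-10 to
#' 2^10); the default is a coarse grid (2 fast scorers, 3 feature counts,
#' LR + naive Bayes, 3 C values) that preserves the best-of-grid selection
#' structure at a fraction of the cost. k-NN is available but off by default.
#'
#' @param scorers subset of `"anova"`, `"bhattacharyya"`, `"extra_trees"`,
#'   `"lasso"`.
#' @param n_features_grid feature counts to try (clamped to d at fit time).
#' @param classifiers subset of `"logistic_regression"`, `"naive_bayes"`,
#'   `"rbf_svm"`, `"random_forest"`, `"knn"`.
#' @param lr_C_grid,svm_C_grid inverse-regularization grids.
#' @param svm_gamma `"auto"` (= 1/d) or numeric.
#' @param rf_n_trees random-forest size (default 250).
#' @param knn_k_grid neighbor counts for k-NN.
#' @param lasso_C penalty for the LASSO scorer.
#' @return a `model_grid` list.
#' @export
model_grid <- function(scorers = c("anova", "bhattacharyya"),
                       n_features_grid = c(1L, 4L, 16L),
                       classifiers = c("logistic_regression", "naive_bayes"),
                       lr_C_grid = 2^c(-5, 0, 5),
                       svm_C_grid = 2^c(-5, 0, 5),
                       svm_gamma = "auto",
                       rf_n_trees = 250L,
                       knn_k_grid = c(1L, 3L, 5L, 7L, 9L),
                       lasso_C = 1.0) {
  stopifnot(length(scorers) >= 1, length(classifiers) >= 1,
            length(n_features_grid) >= 1)
  structure(list(scorers = scorers,
                 n_features_grid = sort(unique(as.integer(n_features_grid))),
                 classifiers = classifiers, lr_C_grid = lr_C_grid,
                 svm_C_grid = svm_C_grid, svm_gamma = svm_gamma,
                 rf_n_trees = as.integer(rf_n_trees),
                 knn_k_grid = as.integer(knn_k_grid), lasso_C = lasso_C),
            class = "model_grid")
}

#' @rdname model_grid
#' @param full if `TRUE`, the full benchmark grid.
#' @export
default_model_grid <- function(full = FALSE) {
  if (!full) return(model_grid())
  model_grid(
    scorers = c("anova", "bhattacharyya", "extra_trees", "lasso"),
    n_features_grid = c(1L, 2L, 4L, 8L, 16L, 32L, 64L),
    classifiers = c("logistic_regression", "naive_bayes", "rbf_svm",
                    "random_forest"),
    lr_C_grid = 2^(-10:10), svm_C_grid = 2^(-10:10)
  )
}

# classifier -> list of hyperparameter settings implied by the grid
.classifier_settings <- function(grid) {
  out <- list()
  for (clf in grid$classifiers) {
    hps <- switch(clf,
      logistic_regression = lapply(grid$lr_C_grid, function(C) list(C = C)),
      naive_bayes = list(list()),
      rbf_svm = lapply(grid$svm_C_grid,
                       function(C) list(C = C, gamma = grid$svm_gamma)),
      random_forest = list(list(n_trees = grid$rf_n_trees)),
      knn = lapply(grid$knn_k_grid, function(k) list(k = k)),
      stop(sprintf("unknown classifier '%s'", clf))
    )
    for (h in hps) out[[length(out) + 1L]] <- list(classifier = clf, hp = h)
  }
  out
}

.hp_label <- function(hp) {
  if (length(hp) == 0L) return("")
  paste(names(hp), vapply(hp, function(v) paste(format(v), collapse = ","),
                          character(1)),
        sep = "=", collapse = ";")
}

#' Run one arm of the paired leakage experiment
#'
#' `run_correct()` applies the resampler inside the cross-validation: each
#' repeat splits the *original* data into stratified folds, resamples only
#' the training part of each fold, fits every configuration of the model grid
#' on the resampled training data and evaluates it on the untouched test
#' fold. `run_incorrect()` reproduces the leaky protocol: the resampler is
#' applied once to *all* the data, and the folds are drawn from the resampled
#' (already balanced) dataset, so test folds may contain synthetic rows whose
#' parents sit in the training fold.
#'
#' Within each repeat, per-configuration metrics are averaged over the folds
#' and the configuration with the highest mean AUC — searched over scorer,
#' feature count, classifier, classifier hyperparameters and the resampling
#' method's own hyperparameter variants — is that repeat's best model; its
#' full metric set is returned. Equal AUCs resolve to the first configuration
#' in deterministic grid order. Both arms consume identical per-repeat seeds
#' so the comparison is matched.
#'
#' Every run also audits provenance: `synthetic_test_rows` counts synthetic
#' rows that ended up in a test fold (necessarily 0 in the correct arm) and
#' `leaky_test_rows` counts those with at least one parent in the paired
#' training fold — the leakage mechanism itself.
#'
#' @param table a preprocessed [labeled_table()].
#' @param resampler a method name (expanded to its hyperparameter variants
#'   via [resampler_variants()]), a single [resampler_spec()], or a list of
#'   specs.
#' @param grid a [model_grid()].
#' @param cv a [cv_scheme()].
#' @return a data frame with one row per repeat: the best model's five
#'   metrics, its configuration, and the audit counts.
#' @export
run_correct <- function(table, resampler, grid = default_model_grid(),
                        cv = cv_scheme()) {
  .run_protocol(table, resampler, grid, cv, leak = FALSE)
}

#' @rdname run_correct
#' @export
run_incorrect <- function(table, resampler, grid = default_model_grid(),
                          cv = cv_scheme()) {
  .run_protocol(table, resampler, grid, cv, leak = TRUE)
}

.run_protocol <- function(table, resampler, grid, cv, leak) {
  variants <- if (is.character(resampler)) resampler_variants(resampler)
              else if (inherits(resampler, "resampler_spec")) list(resampler)
              else resampler
  settings <- .classifier_settings(grid)
  metric_names <- c("auc", "sensitivity", "specificity", "balanced_accuracy",
                    "brier")
  rows <- vector("list", cv$n_repeats)

  for (r in seq_len(cv$n_repeats)) {
    seed_r <- cv$base_seed + r
    best <- NULL
    n_synth_test <- 0L
    n_leaky_test <- 0L

    for (vi in seq_along(variants)) {
      v <- variants[[vi]]
      if (leak) {
        data_v <- resample(table, v, seed_r)
        folds <- stratified_folds(data_v$labels, cv$n_folds, seed_r)
      } else {
        data_v <- table
        folds <- stratified_folds(table$labels, cv$n_folds, seed_r)
      }

      # accumulate fold-mean metrics per configuration
      acc <- NULL
      for (f in seq_along(folds)) {
        te <- folds[[f]]
        tr <- setdiff(seq_len(length(data_v$labels)), te)
        test_tab <- lt_subset(data_v, te)
        train_tab <- lt_subset(data_v, tr)
        if (!leak)
          train_tab <- resample(train_tab, v, seed_r)

        syn_te <- test_tab$provenance == "synthetic"
        n_synth_test <- n_synth_test + sum(syn_te)
        if (any(syn_te)) {
          train_ids <- train_tab$row_ids
          n_leaky_test <- n_leaky_test + sum(vapply(
            test_tab$parent_ids[syn_te],
            function(p) any(p %in% train_ids), logical(1)))
        }

        cfg_i <- 0L
        fold_metrics <- list()
        for (sc in grid$scorers) {
          scores <- score_features(sc, train_tab$features, train_tab$labels,
                                   seed = seed_r)
          for (k in grid$n_features_grid) {
            sel <- select_top_k(scores, k)
            Xtr <- train_tab$features[, sel, drop = FALSE]
            Xte <- test_tab$features[, sel, drop = FALSE]
            for (st in settings) {
              cfg_i <- cfg_i + 1L
              probs <- train_predict(Xtr, train_tab$labels, Xte,
                                     st$classifier, st$hp, seed = seed_r)
              fold_metrics[[cfg_i]] <- evaluate(probs, test_tab$labels)
            }
          }
        }
        m <- vapply(fold_metrics, function(ms) unlist(ms[metric_names]),
                    numeric(5))
        acc <- if (is.null(acc)) m else acc + m
      }
      acc <- acc / length(folds)

      # configuration labels in the same deterministic order
      cfg_i <- 0L
      for (sc in grid$scorers) for (k in grid$n_features_grid)
        for (st in settings) {
          cfg_i <- cfg_i + 1L
          # strict improvement required, so earlier configurations win ties
          if (!is.null(best) && acc["auc", cfg_i] <= best$auc) next
          best <- c(as.list(acc[, cfg_i]),
                    list(scorer = sc, n_features = min(k, ncol(table$features)),
                         classifier = st$classifier,
                         hyperparams = .hp_label(st$hp),
                         variant = paste0(v$method,
                           if (v$method %in% c("smote", "smote_tomek"))
                             paste0("(k=", v$k, ")")
                           else if (v$method == "polyfit_smote")
                             paste0("(", v$topology, ")"))))
        }
    }

    rows[[r]] <- data.frame(
      repeat_id = r, auc = best$auc, sensitivity = best$sensitivity,
      specificity = best$specificity,
      balanced_accuracy = best$balanced_accuracy, brier = best$brier,
      scorer = best$scorer, n_features = best$n_features,
      classifier = best$classifier, hyperparams = best$hyperparams,
      variant = best$variant, synthetic_test_rows = n_synth_test,
      leaky_test_rows = n_leaky_test, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!leak && any(out$synthetic_test_rows > 0))
    stop("internal leakage audit failed: synthetic rows in a correct-protocol test fold")
  out
}

#' Per-repeat bias between the two protocol arms
#'
#' Bias is defined empirically as incorrect minus correct, per metric and per
#' repeat (so a positive AUC bias is inflation and a negative Brier bias is
#' an apparent improvement in calibration), then averaged over repeats.
#'
#' @param correct,incorrect data frames from [run_correct()] /
#'   [run_incorrect()] with matching repeats.
#' @return list with `records` (per-repeat correct, incorrect and bias
#'   values) and `summary` (mean bias per metric, plus the mean correct and
#'   incorrect values).
#' @export
compute_bias <- function(correct, incorrect) {
  stopifnot(nrow(correct) == nrow(incorrect),
            all(correct$repeat_id == incorrect$repeat_id))
  metric_names <- c("auc", "sensitivity", "specificity", "balanced_accuracy",
                    "brier")
  records <- data.frame(repeat_id = correct$repeat_id)
  for (mn in metric_names) {
    records[[paste0("correct_", mn)]] <- correct[[mn]]
    records[[paste0("incorrect_", mn)]] <- incorrect[[mn]]
    records[[paste0("bias_", mn)]] <- incorrect[[mn]] - correct[[mn]]
  }
  summary <- data.frame(metric = metric_names,
                        mean_correct = vapply(metric_names, function(mn)
                          mean(correct[[mn]]), numeric(1)),
                        mean_incorrect = vapply(metric_names, function(mn)
                          mean(incorrect[[mn]]), numeric(1)))
  summary$mean_bias <- summary$mean_incorrect - summary$mean_correct
  list(records = records, summary = summary)
}

#' Association between mean bias and class balance
#'
#' Ordinary least squares of the per-dataset mean bias on the class balance
#' (majority/minority ratio), with the Pearson correlation and the two-sided
#' t-test p-value of the slope. This is the scatter-plot association used to
#' show that more imbalanced datasets suffer more leakage bias.
#'
#' @param mean_biases numeric vector, one mean bias per dataset.
#' @param balances numeric vector of the datasets' class balances.
#' @return list with `slope`, `intercept`, `r`, `p_value` and the `lm` fit.
#' @export
associate_with_balance <- function(mean_biases, balances) {
  stopifnot(length(mean_biases) == length(balances))
  if (length(mean_biases) < 3L)
    stop("association requires at least 3 datasets")
  fit <- stats::lm(mean_biases ~ balances)
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = if (stats::sd(mean_biases) == 0 || stats::sd(balances) == 0) 0
           else stats::cor(balances, mean_biases),
       p_value = unname(sm["balances", "Pr(>|t|)"]),
       fit = fit)
}
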