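#' One point of the random-label simulation
#'
#' Quantifies the leakage bias of SMOTE on data that carries no signal at
#' all. Each repeat draws a fresh 2-D dataset with labels independent of the
#' coordinates, then evaluates two arms with shared seeds:
#'
#' * **correct** — stratified 80/20 split of the original data, SMOTE on the
#'   training 80% only, RBF-SVM fit, AUC on the untouched 20%;
#' * **incorrect** — SMOTE applied to *all* the data first, then the split,
#'   so the test part contains synthetic points interpolated between
#'   originals that mostly sit in the training part.
#'
#' The SVM is deliberately overfitting-prone (default C = 50, gamma = 500):
#' with a kernel length-scale far smaller than the data range it can memorize
#' the training points, which is exactly what turns synthetic test points
#' into leaked information. No classifier can genuinely beat AUC 0.5 here, so
#' any excess of the incorrect arm over 0.5 is pure leakage bias.
#'
#' @param spec a [sim_spec()].
#' @return one-row data frame: `B`, `N`, `imbalance` (= 100/B),
#'   `mean_auc_correct`, `mean_auc_incorrect`, their SDs over repeats, and
#'   `n_repeats`.
#' @export
run_sim_point <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  auc_c <- auc_i <- numeric(spec$n_repeats)
  hp <- list(C = spec$svm_C, gamma = spec$svm_gamma)
  for (r in seq_len(spec$n_repeats)) {
    seed_r <- spec$seed + r
    data <- generate_sim_data(spec$B, spec$N, seed_r)

    # correct arm: split first, resample the training part only
    te <- stratified_holdout(data$labels, spec$test_fraction, seed_r)
    tr <- setdiff(seq_along(data$labels), te)
    train_tab <- smote(lt_subset(data, tr), k = spec$smote_k, seed = seed_r)
    probs <- train_predict(train_tab$features, train_tab$labels,
                           data$features[te, , drop = FALSE],
                           "rbf_svm", hp, seed = seed_r)
    auc_c[r] <- evaluate(probs, data$labels[te])$auc

    # incorrect arm: resample everything, then split
    all_res <- smote(data, k = spec$smote_k, seed = seed_r)
    te2 <- stratified_holdout(all_res$labels, spec$test_fraction, seed_r)
    tr2 <- setdiff(seq_along(all_res$labels), te2)
    probs2 <- train_predict(all_res$features[tr2, , drop = FALSE],
                            all_res$labels[tr2],
                            all_res$features[te2, , drop = FALSE],
                            "rbf_svm", hp, seed = seed_r)
    auc_i[r] <- evaluate(probs2, all_res$labels[te2])$auc
  }
  data.frame(B = spec$B, N = spec$N, imbalance = 100 / spec$B,
             mean_auc_correct = mean(auc_c), mean_auc_incorrect = mean(auc_i),
             sd_auc_correct = stats::sd(auc_c),
             sd_auc_incorrect = stats::sd(auc_i),
             n_repeats = spec$n_repeats)
}

#' Sweep the simulation over a balance and sample-size grid
#'
#' Runs [run_sim_point()] at every combination of balance `B` (percent) and
#' negative-class size `N`, then fits an ordinary least-squares line of the
#' incorrect-arm mean AUC on the imbalance ratio over the pre-saturation
#' range (imbalance <= 4), pooled over `N`. Because the correct arm stays at
#' 0.5, this slope is the leakage bias accrued per unit increase in
#' imbalance. The default grid spans imbalance 1–5 at three sample sizes.
#'
#' @param B_grid balances in percent (default `c(100, 50, 100/3, 25, 20)`,
#'   i.e. imbalance 1–5).
#' @param N_grid negative-class counts (default `c(50, 100, 200)`).
#' @param n_repeats repeats per grid point (default 100).
#' @param seed base seed; grid point `g` uses `seed + 100000 * (g - 1)`.
#' @param ... further arguments passed to [sim_spec()] (e.g. `svm_C`).
#' @return list with `results` (one row per grid point), `slope`, `slope_ci`
#'   (95%), and the `lm` fit.
#' @export
sweep_simulation <- function(B_grid = c(100, 50, 100 / 3, 25, 20),
                             N_grid = c(50, 100, 200),
                             n_repeats = 100L, seed = 1L, ...) {
  pts <- expand.grid(B = B_grid, N = N_grid)
  rows <- lapply(seq_len(nrow(pts)), function(g) {
    run_sim_point(sim_spec(B = pts$B[g], N = pts$N[g], n_repeats = n_repeats,
                           seed = as.integer(seed + 100000 * (g - 1)), ...))
  })
  results <- do.call(rbind, rows)
  pre_sat <- results[results$imbalance <= 4 + 1e-9, ]
  fit <- stats::lm(mean_auc_incorrect ~ imbalance, data = pre_sat)
  list(results = results,
       slope = unname(stats::coef(fit)[2]),
       slope_ci = unname(stats::confint(fit)["imbalance", ]),
       fit = fit)
}
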