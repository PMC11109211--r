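#!/usr/bin/env Rscript
# Bias-balance association report over the benchmark output, mirroring the
# scatter-plot analyses: OLS of per-dataset mean bias on class balance, per
# resampling method and metric.

suppressMessages(library(resbias))

summ <- utils::read.csv("results/summary_by_dataset.csv")
if (nrow(summ) == 0) stop("run analysis/02_benchmark.R first")

assoc <- do.call(rbind, lapply(split(summ, summ$resampler), function(g) {
  a_auc <- associate_with_balance(g$mean_bias_auc, g$balance)
  a_bri <- associate_with_balance(g$mean_bias_brier, g$balance)
  data.frame(resampler = g$resampler[1],
             slope_auc = a_auc$slope, r_auc = a_auc$r, p_auc = a_auc$p_value,
             slope_brier = a_bri$slope, r_brier = a_bri$r,
             p_brier = a_bri$p_value)
}))
rownames(assoc) <- NULL
print(assoc, digits = 3)
utils::write.csv(assoc, "results/association.csv", row.names = FALSE)
message("wrote results/association.csv")

over <- assoc[assoc$resampler %in% c("smote", "mwmote", "random_oversampling"), ]
under <- assoc[assoc$resampler %in% c("random_undersampling", "tomek_links"), ]
message(sprintf(
  "oversamplers: AUC-bias slope per unit balance %.3f-%.3f; undersamplers: %.3f-%.3f",
  min(over$slope_auc), max(over$slope_auc),
  min(under$slope_auc), max(under$slope_auc)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  library(ggplot2)
  p <- ggplot(summ, aes(balance, mean_bias_auc, colour = resampler)) +
    geom_point() + geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
    labs(x = "class balance (majority / minority)",
         y = "mean AUC bias (incorrect - correct)") +
    theme_minimal()
  ggsave("results/figures/bias_vs_balance.pdf", p, width = 6, height = 4)
  message("wrote results/figures/bias_vs_balance.pdf")
}
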