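#!/usr/bin/env Rscript
# Analyzes the simulated trial from 03_simulate_trial.R with the stratified
# win ratio: closed-form large-sample inference and the provider-cluster
# bootstrap as a robustness check.

suppressPackageStartupMessages(library(echotrial))
if (!file.exists("results/synthetic_trial.csv"))
  stop("run analysis/03_simulate_trial.R first")

trial <- read_outcomes("results/synthetic_trial.csv")

cf <- win_ratio_stratified(trial)
print(cf)
bs <- cluster_bootstrap(trial, B = 1000, seed = 20260904)
message(sprintf(
  "cluster bootstrap (B=%d): CI %.3f-%.3f, p = %.4f (closed form p = %.4f)",
  bs$B, bs$ci_low, bs$ci_high, bs$p_value, cf$p_value))

report <- list(
  n = nrow(trial),
  counts = list(wins = cf$n_wins_total, losses = cf$n_losses_total,
                ties = cf$n_ties_total),
  categories = cf$strata[["1"]]$categories,
  closed_form = list(win_ratio = cf$win_ratio, se_log = cf$log_wr_se,
                     ci = c(cf$ci_low, cf$ci_high), p = cf$p_value),
  cluster_bootstrap = list(B = bs$B, seed = bs$seed,
                           ci = c(bs$ci_low, bs$ci_high), p = bs$p_value))
jsonlite::write_json(report, "results/win_ratio_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/win_ratio_report.json")
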