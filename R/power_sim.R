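#' Monte-Carlo power (or type-I error) of the stratified win-ratio test
#'
#' For each replicate: generate a synthetic trial from the design, run the
#' stratified win-ratio test, and reject when the two-sided p-value falls
#' below `design$alpha`.  With `effect_abs = 0` the rejection fraction
#' estimates the type-I error; with the design effect it estimates power.
#' Per-replicate seeds are drawn once from `seed` and recorded, so any single
#' replicate can be reproduced in isolation.
#'
#' @param design A [trial_design()].
#' @param reps Number of simulated trials (>= 100).
#' @param seed Integer master seed.
#' @param weighting Passed to [win_ratio_stratified()].
#' @return A `power_result`: `design`, `replicates`, `rejections`, `power`,
#'   `mc_se` (binomial Monte-Carlo standard error), `replicate_seeds`.
#' @export
run_power <- function(design, reps = 1000, seed = 1,
                      weighting = "pooled_counts") {
  stopifnot(inherits(design, "trial_design"), reps >= 100)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  reject <- logical(reps)
  for (r in seq_len(reps))
    reject[r] <- run_power_replicate(design, rep_seeds[r], weighting)
  p <- mean(reject)
  structure(list(design = design, replicates = reps,
                 rejections = sum(reject), power = p,
                 mc_se = sqrt(p * (1 - p) / reps),
                 replicate_seeds = rep_seeds, seed = seed),
            class = "power_result")
}

#' Run a single power-simulation replicate
#'
#' Generates one trial with the given replicate seed and returns the
#' rejection decision of the stratified win-ratio test at the design's
#' alpha.  Exposed so any replicate of [run_power()] can be re-executed from
#' its recorded seed.
#'
#' @inheritParams run_power
#' @param rep_seed The replicate's own seed.
#' @return `TRUE` iff the null of win ratio = 1 is rejected.
#' @export
run_power_replicate <- function(design, rep_seed,
                                weighting = "pooled_counts") {
  d <- design
  d$seed <- as.integer(rep_seed)
  trial <- generate_trial(d)
  est <- win_ratio_stratified(trial, weighting = weighting,
                              alpha = design$alpha)
  !is.na(est$p_value) && est$p_value < design$alpha
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power: %.3f (MC se %.3f) from %d replicates, %d rejections\n",
    x$power, x$mc_se, x$replicates, x$rejections))
  invisible(x)
}

#' Power over a grid of designs
#'
#' Runs [run_power()] for each design in a list (e.g. a sweep over the
#' copula dependence `theta` or the effect size) and returns a tidy table,
#' one row per design, for sensitivity reporting.  Each design gets its own
#' sub-seed derived from `seed`, so rows are individually reproducible.
#'
#' @param design_grid Nonempty list of [trial_design()] objects.
#' @param reps Replicates per design.
#' @param seed Integer master seed.
#' @param weighting Passed to [win_ratio_stratified()].
#' @return Data frame: design parameters, `replicates`, `rejections`,
#'   `power`, `mc_se`, `sub_seed`.
#' @export
power_sweep <- function(design_grid, reps = 1000, seed = 1,
                        weighting = "pooled_counts") {
  stopifnot(is.list(design_grid), length(design_grid) > 0)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(design_grid))
  rows <- lapply(seq_along(design_grid), function(i) {
    d <- design_grid[[i]]
    res <- run_power(d, reps = reps, seed = sub_seeds[i],
                     weighting = weighting)
    data.frame(n_patients = d$n_patients, n_clusters = d$n_clusters,
               window = d$window, p_valve_control = d$p_valve_control,
               p_mht_control = d$p_mht_control, effect_abs = d$effect_abs,
               theta = d$theta, alpha = d$alpha, replicates = res$replicates,
               rejections = res$rejections, power = res$power,
               mc_se = res$mc_se, sub_seed = sub_seeds[i])
  })
  do.call(rbind, rows)
}
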