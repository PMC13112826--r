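pt <- function(arm, tv, dv, tm, dm, cens = 90) {
  list(arm = arm, t_valve = tv, d_valve = dv, t_mht = tm, d_mht = dm,
       censor_time = cens)
}

test_that("single-pair comparison follows the five-category hierarchy", {
  # notified valve intervention first
  expect_identical(
    compare_pair(pt("notification", 10, 1, 90, 0),
                 pt("control", 30, 1, 90, 0))$category, 1L)
  # both event-free: tie
  expect_identical(
    compare_pair(pt("notification", 90, 0, 90, 0),
                 pt("control", 90, 0, 90, 0))$category, 5L)
  # no valve events, notified heart-team visit first
  expect_identical(
    compare_pair(pt("notification", 90, 0, 20, 1),
                 pt("control", 90, 0, 50, 1))$category, 3L)
  # event beyond the pair's shared follow-up cannot establish priority
  expect_identical(
    compare_pair(pt("notification", 80, 1, 90, 0),
                 pt("control", 60, 0, 60, 0, cens = 60))$category, 5L)
  # control valve intervention first
  expect_identical(
    compare_pair(pt("notification", 90, 0, 40, 1),
                 pt("control", 25, 1, 90, 0))$result, "loss")
  # exact valve-time tie falls through to the heart-team level
  expect_identical(
    compare_pair(pt("notification", 30, 1, 10, 1),
                 pt("control", 30, 1, 40, 1))$category, 3L)
  expect_error(compare_pair(pt("control", 1, 1, 1, 1),
                            pt("control", 1, 1, 1, 1)), "expects")
})

test_that("a hand-enumerable 2v2 dataset reproduces exact counts", {
  out <- rbind(
    data.frame(patient_id = 1, cluster_id = 1, stratum = 1,
               arm = "notification", t_valve = 10, d_valve = 1L,
               t_mht = 90, d_mht = 0L, censor_time = 90),
    data.frame(patient_id = 2, cluster_id = 2, stratum = 1,
               arm = "notification", t_valve = 90, d_valve = 0L,
               t_mht = 70, d_mht = 1L, censor_time = 90),
    data.frame(patient_id = 3, cluster_id = 3, stratum = 1,
               arm = "control", t_valve = 30, d_valve = 1L,
               t_mht = 90, d_mht = 0L, censor_time = 90),
    data.frame(patient_id = 4, cluster_id = 4, stratum = 1,
               arm = "control", t_valve = 90, d_valve = 0L,
               t_mht = 20, d_mht = 1L, censor_time = 90))
  # by hand: (1,3) valve 10<30 win; (1,4) valve win; (2,3) control valve loss;
  # (2,4) no valve events, MHT 70>20 loss
  est <- win_ratio_stratified(out)
  expect_identical(est$n_wins_total, 2)
  expect_identical(est$n_losses_total, 2)
  expect_identical(est$n_ties_total, 0)
  expect_identical(est$win_ratio, 1)
  expect_identical(unname(est$strata[["1"]]$categories),
                   c(2, 1, 0, 1, 0))
})

test_that("production counts equal the brute-force oracle on random small datasets", {
  for (k in 1:30) {
    out <- random_small_outcomes(n = sample(6:30, 1), seed = 1000 + k)
    want <- oracle_win_ratio_counts(out)
    est <- suppressWarnings(try(win_ratio_stratified(out), silent = TRUE))
    comparable <- Filter(function(x) x$n1 > 0 && x$n0 > 0, want)
    if (length(comparable) == 0) next
    for (s in names(comparable)) {
      expect_identical(est$strata[[s]]$wins, as.numeric(comparable[[s]]$wins))
      expect_identical(est$strata[[s]]$losses,
                       as.numeric(comparable[[s]]$losses))
      expect_identical(est$strata[[s]]$ties, as.numeric(comparable[[s]]$ties))
      expect_identical(unname(est$strata[[s]]$categories),
                       as.numeric(comparable[[s]]$categories))
    }
  }
})

test_that("swapping arms gives the exact reciprocal with the same p-value", {
  for (k in 1:10) {
    out <- random_small_outcomes(25, seed = 2000 + k)
    if (!all(c("notification", "control") %in% out$arm)) next
    a <- suppressWarnings(win_ratio_stratified(out))
    b <- suppressWarnings(win_ratio_stratified(swap_arms(out)))
    expect_identical(a$n_wins_total, b$n_losses_total)
    expect_identical(a$n_losses_total, b$n_wins_total)
    if (is.finite(a$win_ratio) && a$win_ratio > 0) {
      expect_equal(b$win_ratio, 1 / a$win_ratio)
      expect_equal(b$p_value, a$p_value)
      expect_equal(b$log_wr_se, a$log_wr_se)
    }
  }
})

test_that("wins, losses and ties account for every cross-arm pair in every stratum", {
  for (k in 1:10) {
    out <- random_small_outcomes(30, seed = 3000 + k, n_strata = 3)
    est <- suppressWarnings(win_ratio_stratified(out))
    for (s in est$strata) {
      expect_identical(s$wins + s$losses + s$ties,
                       as.numeric(s$n1) * as.numeric(s$n0))
    }
  }
})

test_that("mh-type weighting reduces to pooled counts for a single stratum", {
  out <- generate_trial(trial_design(n_patients = 300, n_clusters = 60,
                                     seed = 5))
  a <- win_ratio_stratified(out, weighting = "pooled_counts")
  b <- win_ratio_stratified(out, weighting = "mh_type")
  expect_equal(a$win_ratio, b$win_ratio)
  expect_equal(a$p_value, b$p_value)
})

test_that("under no effect the estimate concentrates near 1", {
  out <- generate_trial(trial_design(n_patients = 20000, n_clusters = 500,
                                     effect_abs = 0, seed = 12))
  est <- win_ratio_stratified(out)
  expect_lt(abs(log(est$win_ratio)), 0.12)
  expect_true(est$ci_low <= est$win_ratio & est$win_ratio <= est$ci_high)
})

test_that("degenerate inputs are handled explicitly", {
  # all-win dataset: infinite ratio with a finite continuity CI
  out <- data.frame(patient_id = 1:4, cluster_id = 1:4, stratum = 1,
                    arm = rep(c("notification", "control"), each = 2),
                    t_valve = c(5, 6, 90, 90), d_valve = c(1L, 1L, 0L, 0L),
                    t_mht = 90, d_mht = 0L, censor_time = 90)
  est <- win_ratio_stratified(out)
  expect_identical(est$win_ratio, Inf)
  expect_true(is.finite(est$ci_low) && is.finite(est$ci_high))
  expect_true(is.finite(est$p_value))
  # a stratum with one empty arm is skipped with a warning
  out2 <- rbind(out, data.frame(patient_id = 5, cluster_id = 5, stratum = 2,
                                arm = "control", t_valve = 90, d_valve = 0L,
                                t_mht = 90, d_mht = 0L, censor_time = 90))
  expect_warning(win_ratio_stratified(out2), "empty arm")
})

test_that("cluster bootstrap is reproducible and refuses degenerate clustering", {
  out <- generate_trial(trial_design(n_patients = 120, n_clusters = 24,
                                     seed = 9))
  b1 <- cluster_bootstrap(out, B = 200, seed = 4)
  b2 <- cluster_bootstrap(out, B = 200, seed = 4)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_identical(b1$method, "cluster_bootstrap")
  expect_true(b1$ci_low <= b1$ci_high)

  solo <- out
  solo$cluster_id[solo$arm == "notification"] <- 999L
  expect_error(cluster_bootstrap(solo, B = 200, seed = 1), "at least 2")
})
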