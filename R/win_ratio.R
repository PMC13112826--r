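#' Compare one cross-arm patient pair
#'
#' Applies the hierarchical pairwise rule to a single
#' notification-arm/control-arm pair.  With `tau` the pair's shared follow-up
#' (the smaller of the two censoring times), an event counts only if it
#' occurs by `tau`.  Valve intervention is compared first; if neither patient
#' can be established as having valve intervention first (including exact
#' time ties), the heart-team visit times are compared by the same rule;
#' otherwise the pair is a tie.
#'
#' Categories: 1 notified valve first (win), 2 control valve first (loss),
#' 3 notified MHT visit first (win), 4 control MHT visit first (loss),
#' 5 neither (tie).
#'
#' @param a Notification-arm patient: list/row with `t_valve`, `d_valve`,
#'   `t_mht`, `d_mht`, `censor_time`, `arm`.
#' @param b Control-arm patient, same fields.
#' @return List with `category` (1-5) and `result`
#'   (`"win"`/`"loss"`/`"tie"`), from the notification patient's viewpoint.
#' @export
compare_pair <- function(a, b) {
  if (!identical(as.character(a$arm), "notification") ||
      !identical(as.character(b$arm), "control"))
    stop("compare_pair expects a notification-arm and a control-arm patient")
  tau <- min(a$censor_time, b$censor_time)
  level <- function(ta, da, tb, db) {
    ea <- da == 1 && ta <= tau
    eb <- db == 1 && tb <= tau
    if (ea && (!eb || tb > ta)) return(1L)   # a first
    if (eb && (!ea || ta > tb)) return(-1L)  # b first
    0L
  }
  v <- level(a$t_valve, a$d_valve, b$t_valve, b$d_valve)
  if (v == 1L) return(list(category = 1L, result = "win"))
  if (v == -1L) return(list(category = 2L, result = "loss"))
  m <- level(a$t_mht, a$d_mht, b$t_mht, b$d_mht)
  if (m == 1L) return(list(category = 3L, result = "win"))
  if (m == -1L) return(list(category = 4L, result = "loss"))
  list(category = 5L, result = "tie")
}

# All-pairs counts plus Hajek projections for one stratum, via the compiled
# kernel.  `g1` = notification rows, `g0` = control rows.
.stratum_counts <- function(g1, g0) {
  .pairwise_counts_cpp(g1$t_valve, as.integer(g1$d_valve),
                       g1$t_mht, as.integer(g1$d_mht), g1$censor_time,
                       g0$t_valve, as.integer(g0$d_valve),
                       g0$t_mht, as.integer(g0$d_mht), g0$censor_time)
}

# U-statistic variance/covariance of the per-stratum win and loss
# proportions, from the per-patient projections.
.stratum_moments <- function(cnt, n1, n0) {
  pw <- cnt$row_win / n0;  pl <- cnt$row_loss / n0
  qw <- cnt$col_win / n1;  ql <- cnt$col_loss / n1
  vrow <- function(x) if (length(x) > 1) stats::var(x) else 0
  cvr <- function(x, y) if (length(x) > 1) stats::cov(x, y) else 0
  list(theta_w = cnt$wins / (n1 * n0),
       theta_l = cnt$losses / (n1 * n0),
       var_w = vrow(pw) / n1 + vrow(qw) / n0,
       var_l = vrow(pl) / n1 + vrow(ql) / n0,
       cov_wl = cvr(pw, pl) / n1 + cvr(qw, ql) / n0)
}

#' Stratified win ratio for the hierarchical composite endpoint
#'
#' Compares every notification-arm patient with every control-arm patient
#' within each stratum, classifies each pair by [compare_pair()]'s
#' five-category rule, and estimates the win ratio: total wins for the
#' notification arm divided by total wins for the control arm.
#'
#' With `weighting = "pooled_counts"` (the default) stratum wins and losses
#' are summed before taking the ratio.  With `weighting = "mh_type"` stratum
#' win/loss *proportions* are combined with Mantel-Haenszel-type weights
#' `n1s*n0s/(n1s+n0s)`.  Both use a closed-form large-sample variance of the
#' log win ratio built from per-patient Hajek projections of the pairwise
#' U-statistics, giving a normal-theory CI and a two-sided test of win ratio
#' = 1.
#'
#' If either total is zero the point estimate is 0 or `Inf` and the CI and
#' p-value use a 0.5 continuity adjustment to both totals.
#'
#' @param outcomes Patient-outcome data frame (schema of [generate_trial()]).
#' @param stratum_field Name of the stratum column (default `"stratum"`).
#' @param weighting `"pooled_counts"` or `"mh_type"`.
#' @param alpha Two-sided level for the CI (default 0.05).
#' @return A `win_ratio` object: per-stratum counts, totals, `win_ratio`,
#'   `log_wr_se`, `ci_low`, `ci_high`, `p_value`, `method`.
#' @export
win_ratio_stratified <- function(outcomes, stratum_field = "stratum",
                                 weighting = c("pooled_counts", "mh_type"),
                                 alpha = 0.05) {
  weighting <- match.arg(weighting)
  stopifnot(stratum_field %in% names(outcomes),
            all(outcomes$arm %in% c("notification", "control")))
  strata <- unique(outcomes[[stratum_field]])
  per <- list()
  for (s in strata) {
    sub <- outcomes[outcomes[[stratum_field]] == s, ]
    g1 <- sub[sub$arm == "notification", ]
    g0 <- sub[sub$arm == "control", ]
    if (nrow(g1) == 0 || nrow(g0) == 0) {
      warning("stratum ", s, " has an empty arm; skipped")
      next
    }
    cnt <- .stratum_counts(g1, g0)
    mom <- .stratum_moments(cnt, nrow(g1), nrow(g0))
    per[[as.character(s)]] <- list(
      stratum = s, n1 = nrow(g1), n0 = nrow(g0),
      wins = cnt$wins, losses = cnt$losses, ties = cnt$ties,
      categories = cnt$categories, moments = mom)
  }
  if (length(per) == 0)
    stop("no stratum with at least one patient per arm")

  w_s <- vapply(per, function(x) switch(weighting,
    pooled_counts = x$n1 * x$n0,
    mh_type = x$n1 * x$n0 / (x$n1 + x$n0)), numeric(1))
  tw <- vapply(per, function(x) x$moments$theta_w, numeric(1))
  tl <- vapply(per, function(x) x$moments$theta_l, numeric(1))
  vw <- vapply(per, function(x) x$moments$var_w, numeric(1))
  vl <- vapply(per, function(x) x$moments$var_l, numeric(1))
  cw <- vapply(per, function(x) x$moments$cov_wl, numeric(1))

  A <- sum(w_s * tw)  # weighted win mass
  B <- sum(w_s * tl)  # weighted loss mass
  n_wins <- sum(vapply(per, function(x) x$wins, numeric(1)))
  n_losses <- sum(vapply(per, function(x) x$losses, numeric(1)))
  wr <- if (B > 0) A / B else if (A > 0) Inf else NaN

  degenerate <- (A == 0 || B == 0)
  if (!degenerate) {
    var_log <- sum(w_s^2 * vw) / A^2 + sum(w_s^2 * vl) / B^2 -
      2 * sum(w_s^2 * cw) / (A * B)
    se <- sqrt(max(var_log, 0))
    z <- stats::qnorm(1 - alpha / 2)
    ci <- exp(log(wr) + c(-1, 1) * z * se)
    p <- if (se > 0) 2 * stats::pnorm(-abs(log(wr)) / se) else NA_real_
  } else {
    # continuity adjustment on the totals for interval and test only
    Wc <- n_wins + 0.5; Lc <- n_losses + 0.5
    se <- sqrt(1 / Wc + 1 / Lc)
    z <- stats::qnorm(1 - alpha / 2)
    ci <- exp(log(Wc / Lc) + c(-1, 1) * z * se)
    p <- 2 * stats::pnorm(-abs(log(Wc / Lc)) / se)
  }

  structure(list(
    strata = lapply(per, function(x) x[c("stratum", "n1", "n0", "wins",
                                         "losses", "ties", "categories")]),
    n_wins_total = n_wins, n_losses_total = n_losses,
    n_ties_total = sum(vapply(per, function(x) x$ties, numeric(1))),
    weighting = weighting, win_ratio = wr, log_wr_se = se,
    ci_low = ci[1], ci_high = ci[2], p_value = p, alpha = alpha,
    method = "closed_form"), class = "win_ratio")
}

#' @export
print.win_ratio <- function(x, ...) {
  cat("Stratified win ratio (", x$method, ", ", x$weighting, ")\n", sep = "")
  for (s in x$strata)
    cat(sprintf("  stratum %s: n = %d vs %d, wins %d, losses %d, ties %d\n",
                s$stratum, s$n1, s$n0, as.integer(s$wins),
                as.integer(s$losses), as.integer(s$ties)))
  cat(sprintf("  win ratio %.4f  (%.0f%% CI %.4f-%.4f)  p = %.4g\n",
              x$win_ratio, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              x$p_value))
  invisible(x)
}

#' Provider-cluster bootstrap for the win ratio
#'
#' Resamples provider clusters with replacement, independently within each
#' arm-by-stratum cell, recomputes the win ratio on each replicate, and
#' reports a percentile confidence interval with a p-value by interval
#' inversion.  Clusters must be nested within strata.
#'
#' @param outcomes Patient-outcome data frame with `cluster_id`.
#' @param B Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param stratum_field Stratum column name.
#' @param weighting Passed to [win_ratio_stratified()].
#' @param alpha Two-sided level.
#' @return A `win_ratio` object with `method = "cluster_bootstrap"`.
#' @export
cluster_bootstrap <- function(outcomes, B = 1000, seed = 1,
                              stratum_field = "stratum",
                              weighting = "pooled_counts", alpha = 0.05) {
  stopifnot("cluster_id" %in% names(outcomes), B >= 100)
  cl <- unique(outcomes[, c("cluster_id", "arm", stratum_field)])
  if (any(duplicated(cl$cluster_id)))
    stop("clusters must be nested within arm and stratum")
  for (a in c("notification", "control"))
    if (sum(cl$arm == a) < 2)
      stop("need at least 2 clusters in the ", a, " arm to bootstrap")

  point <- win_ratio_stratified(outcomes, stratum_field, weighting, alpha)
  cells <- split(cl$cluster_id, list(cl$arm, cl[[stratum_field]]),
                 drop = TRUE)
  by_cluster <- split(seq_len(nrow(outcomes)), outcomes$cluster_id)

  set.seed(seed)
  log_wr <- numeric(B)
  for (b in seq_len(B)) {
    take <- unlist(lapply(cells, function(ids)
      sample(as.character(ids), length(ids), replace = TRUE)),
      use.names = FALSE)
    rows <- unlist(by_cluster[take], use.names = FALSE)
    est <- suppressWarnings(
      win_ratio_stratified(outcomes[rows, ], stratum_field, weighting, alpha))
    log_wr[b] <- log(est$win_ratio)
  }
  qs <- stats::quantile(exp(log_wr), c(alpha / 2, 1 - alpha / 2),
                        na.rm = TRUE, names = FALSE)
  f <- (sum(log_wr <= 0) + 1) / (B + 1)
  p <- 2 * min(f, 1 - f)
  point$method <- "cluster_bootstrap"
  point$ci_low <- qs[1]
  point$ci_high <- qs[2]
  point$p_value <- min(p, 1)
  point$B <- B
  point$seed <- seed
  point
}
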