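#' Trial design parameters
#'
#' Bundles every parameter of the synthetic cluster-randomized trial: cohort
#' and cluster counts, the 90-day follow-up window, control-arm 90-day
#' incidences of the two endpoint components, the absolute effect of
#' notification on both, and the Gumbel-Hougaard dependence parameter.
#'
#' Defaults are the design's planning assumptions: 1246 patients in 500
#' provider clusters, control 90-day incidence 5% for valve intervention and
#' 10% for heart-team (MHT) visit, +5 absolute percentage points on both
#' under notification, and copula `theta = 2` (Kendall's tau 0.5).
#'
#' @param n_patients Total patients (default 1246).
#' @param n_clusters Provider clusters, allocated 1:1 to arms (default 500).
#' @param window Follow-up window in days (default 90).
#' @param p_valve_control,p_mht_control Control-arm probabilities of each
#'   event within `window`.
#' @param effect_abs Absolute increment added to both probabilities under
#'   notification (default 0.05).
#' @param theta Copula dependence, >= 1; `theta = 1` is independence.
#' @param cluster_size_model `"equal"` (near-equal sizes, remainder spread
#'   over the first clusters) or `"multinomial"` (patients dropped into
#'   clusters uniformly at random).
#' @param strata Number of analysis strata patients are spread over
#'   (default 1).
#' @param alpha Two-sided test level (default 0.05).
#' @param frailty_sd Standard deviation (log scale) of an optional lognormal
#'   cluster-shared rate multiplier inducing within-cluster correlation;
#'   0 (the default) disables it, so outcomes are independent across
#'   patients given the arm.
#' @param seed Integer seed.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_patients = 1246, n_clusters = 500, window = 90,
                         p_valve_control = 0.05, p_mht_control = 0.10,
                         effect_abs = 0.05, theta = 2,
                         cluster_size_model = c("equal", "multinomial"),
                         strata = 1, alpha = 0.05, frailty_sd = 0, seed = 1) {
  cluster_size_model <- match.arg(cluster_size_model)
  stopifnot(n_patients >= 2, n_clusters >= 2, window > 0, theta >= 1,
            strata >= 1, alpha > 0, alpha < 1, frailty_sd >= 0)
  if (n_clusters > n_patients)
    stop("n_clusters exceeds n_patients")
  for (p in c(p_valve_control, p_mht_control)) {
    if (p <= 0 || p + effect_abs >= 1 || p + effect_abs <= 0)
      stop("event probabilities (with effect) must lie strictly in (0, 1)")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_clusters = as.integer(n_clusters), window = window,
                 p_valve_control = p_valve_control,
                 p_mht_control = p_mht_control, effect_abs = effect_abs,
                 theta = theta, cluster_size_model = cluster_size_model,
                 strata = as.integer(strata), alpha = alpha,
                 frailty_sd = frailty_sd, seed = as.integer(seed)),
            class = "trial_design")
}

#' Exponential rate from a window incidence
#'
#' Solves `1 - exp(-lambda * window) = p_window` for the daily hazard, so
#' that exponential event times reproduce the stated cumulative incidence by
#' the end of the observation window.
#'
#' @param p_window Probability of the event within the window, in (0, 1).
#' @param window Window length in days.
#' @return Rate lambda per day.
#' @export
calibrate_rate <- function(p_window, window) {
  if (any(p_window <= 0 | p_window >= 1))
    stop("p_window must lie strictly in (0, 1)")
  stopifnot(window > 0)
  -log(1 - p_window) / window
}

#' Sample from the Gumbel-Hougaard copula
#'
#' Draws pairs `(u1, u2)` with uniform margins and joint CDF
#' `C(u1, u2) = exp(-[(-log u1)^theta + (-log u2)^theta]^(1/theta))`, via the
#' Marshall-Olkin construction: a positive stable frailty `V` with index
#' `1/theta` (Chambers-Mallows-Stuck), then `u_i = exp(-(E_i / V)^(1/theta))`
#' with `E_i` standard exponential.  `theta = 1` gives independence;
#' Kendall's tau is `1 - 1/theta`.
#'
#' @param theta Dependence parameter, >= 1.
#' @param n Number of pairs.
#' @param seed Optional integer seed (set only when supplied).
#' @return An `n` x 2 matrix of uniforms.
#' @export
sample_gumbel_copula <- function(theta, n, seed = NULL) {
  if (theta < 1) stop("theta must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  e <- matrix(stats::rexp(2 * n), ncol = 2)
  if (theta == 1) return(exp(-e))
  alpha <- 1 / theta
  # Positive stable St(alpha, 1, cos(pi*alpha/2)^(1/alpha), 0; 1): CMS sampler.
  u <- stats::runif(n, 0, pi)
  w <- stats::rexp(n)
  v <- (sin(alpha * u) / sin(u)^(1 / alpha)) *
    (sin((1 - alpha) * u) / w)^((1 - alpha) / alpha)
  exp(-(e / v)^alpha)
}

#' Generate a synthetic cluster-randomized trial
#'
#' Allocates clusters 1:1 to arms (balanced permutation), spreads patients
#' over clusters per the design's cluster-size model, and draws each
#' patient's pair of event times — valve intervention and heart-team visit —
#' from exponential margins joined by the Gumbel-Hougaard copula.  Arm rates
#' are calibrated so the 90-day incidences equal the control probabilities
#' (control arm) or those plus `effect_abs` (notification arm).  Both times
#' are administratively censored at the window.
#'
#' @param design A [trial_design()].
#' @return Data frame of patient outcomes: `patient_id, cluster_id, stratum,
#'   arm, t_valve, d_valve, t_mht, d_mht, censor_time`, sorted by
#'   `patient_id`.
#' @export
generate_trial <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(design$seed)
  K <- design$n_clusters
  n <- design$n_patients

  cluster_arm <- .balanced_arms(K)

  sizes <- switch(design$cluster_size_model,
    equal = {
      base <- n %/% K
      sz <- rep(base, K)
      rem <- n - base * K
      if (rem > 0) sz[seq_len(rem)] <- sz[seq_len(rem)] + 1L
      sz
    },
    multinomial = {
      tab <- tabulate(sample.int(K, n, replace = TRUE), nbins = K)
      tab
    })
  cluster_id <- rep(seq_len(K), times = sizes)
  arm <- cluster_arm[cluster_id]
  m <- length(cluster_id)  # equals n for "equal"; multinomial keeps n too

  uu <- sample_gumbel_copula(design$theta, m)

  p_valve <- ifelse(arm == "notification",
                    design$p_valve_control + design$effect_abs,
                    design$p_valve_control)
  p_mht <- ifelse(arm == "notification",
                  design$p_mht_control + design$effect_abs,
                  design$p_mht_control)
  lam_valve <- calibrate_rate(p_valve, design$window)
  lam_mht <- calibrate_rate(p_mht, design$window)
  if (design$frailty_sd > 0) {
    # mean-one lognormal cluster frailty scaling both hazards
    fr <- exp(stats::rnorm(K, -design$frailty_sd^2 / 2, design$frailty_sd))
    lam_valve <- lam_valve * fr[cluster_id]
    lam_mht <- lam_mht * fr[cluster_id]
  }

  # u is the survival probability: T = -log(u)/lambda is exponential(lambda).
  t_valve <- -log(uu[, 1]) / lam_valve
  t_mht <- -log(uu[, 2]) / lam_mht

  w <- design$window
  out <- data.frame(
    patient_id = seq_len(m),
    cluster_id = cluster_id,
    stratum = ((seq_len(m) - 1L) %% design$strata) + 1L,
    arm = arm,
    t_valve = pmin(t_valve, w),
    d_valve = as.integer(t_valve <= w),
    t_mht = pmin(t_mht, w),
    d_mht = as.integer(t_mht <= w),
    censor_time = w,
    stringsAsFactors = FALSE)
  out[order(out$patient_id), ]
}

#' Censor observation periods at a repeat echocardiogram
#'
#' When a patient has a repeat echo at day `r` before the end of their
#' observation window, the repeat echo censors the first echo's period: the
#' censoring time becomes `r` and any event recorded after `r` is cleared and
#' its time truncated to `r`.
#'
#' @param outcomes Patient-outcome data frame (see [generate_trial()]).
#' @param repeat_times Named numeric vector or data frame
#'   (`patient_id`, `repeat_time`) of repeat-echo days; patients not listed
#'   are untouched.
#' @return The censored outcome data frame.
#' @export
apply_repeat_echo_censoring <- function(outcomes, repeat_times) {
  if (is.data.frame(repeat_times)) {
    stopifnot(all(c("patient_id", "repeat_time") %in% names(repeat_times)))
    rt <- stats::setNames(repeat_times$repeat_time,
                          repeat_times$patient_id)
  } else rt <- repeat_times
  if (length(rt) == 0) return(outcomes)
  stopifnot(all(rt > 0))
  idx <- match(outcomes$patient_id, as.numeric(names(rt)))
  r <- rt[idx]
  hit <- !is.na(r) & r < outcomes$censor_time
  outcomes$censor_time[hit] <- r[hit]
  for (ep in c("valve", "mht")) {
    tcol <- paste0("t_", ep); dcol <- paste0("d_", ep)
    late <- hit & outcomes[[tcol]] > outcomes$censor_time
    outcomes[[dcol]][late] <- 0L
    outcomes[[tcol]][late] <- outcomes$censor_time[late]
  }
  outcomes
}

#' Sample Kendall's tau for continuous pairs
#'
#' O(n log n) inversion-counting estimate of Kendall's tau, assuming
#' tie-free (continuous) data.  Used to verify the copula's dependence
#' calibration (`tau = 1 - 1/theta`) at large n, where the naive all-pairs
#' statistic is infeasible.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The sample tau.
#' @export
kendall_tau <- function(x, y) .kendall_tau_cpp(as.numeric(x), as.numeric(y))
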