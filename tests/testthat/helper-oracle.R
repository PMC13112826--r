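# Independent brute-force oracle for the hierarchical pairwise comparison.
# Written directly from the five-category description, sharing no code with
# the package's compiled kernel or compare_pair(): for each cross-arm pair
# the valve level is tried, then the heart-team level, events counting only
# up to the pair's shared follow-up.
oracle_pair_category <- function(tv_a, dv_a, tm_a, dm_a, c_a,
                                 tv_b, dv_b, tm_b, dm_b, c_b) {
  shared <- min(c_a, c_b)
  a_valve <- dv_a == 1 && tv_a <= shared
  b_valve <- dv_b == 1 && tv_b <= shared
  if (a_valve && b_valve) {
    if (tv_a < tv_b) return(1)
    if (tv_b < tv_a) return(2)
    # simultaneous valve interventions: fall through to the next level
  } else if (a_valve) {
    return(1)
  } else if (b_valve) {
    return(2)
  }
  a_mht <- dm_a == 1 && tm_a <= shared
  b_mht <- dm_b == 1 && tm_b <= shared
  if (a_mht && b_mht) {
    if (tm_a < tm_b) return(3)
    if (tm_b < tm_a) return(4)
  } else if (a_mht) {
    return(3)
  } else if (b_mht) {
    return(4)
  }
  5
}

# Exhaustive per-stratum enumeration of wins/losses/ties and category
# counts over all notification x control pairs.
oracle_win_ratio_counts <- function(outcomes, stratum_field = "stratum") {
  res <- list()
  for (s in sort(unique(outcomes[[stratum_field]]))) {
    sub <- outcomes[outcomes[[stratum_field]] == s, ]
    a <- sub[sub$arm == "notification", ]
    b <- sub[sub$arm == "control", ]
    cats <- integer(5)
    if (nrow(a) > 0 && nrow(b) > 0) {
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        k <- oracle_pair_category(
          a$t_valve[i], a$d_valve[i], a$t_mht[i], a$d_mht[i], a$censor_time[i],
          b$t_valve[j], b$d_valve[j], b$t_mht[j], b$d_mht[j], b$censor_time[j])
        cats[k] <- cats[k] + 1L
      }
    }
    res[[as.character(s)]] <- list(
      stratum = s, n1 = nrow(a), n0 = nrow(b),
      wins = cats[1] + cats[3], losses = cats[2] + cats[4], ties = cats[5],
      categories = cats)
  }
  res
}

# Random small outcome dataset with integer-day times (so exact ties occur),
# varying censor times, and 2-4 strata.
random_small_outcomes <- function(n, seed, n_strata = 2) {
  set.seed(seed)
  censor <- sample(c(30, 60, 90), n, replace = TRUE)
  draw_ep <- function() {
    t_raw <- sample(1:100, n, replace = TRUE)
    d <- as.integer(t_raw <= censor & stats::runif(n) < 0.6)
    list(t = ifelse(d == 1, pmin(t_raw, censor), censor), d = d)
  }
  v <- draw_ep(); m <- draw_ep()
  data.frame(
    patient_id = seq_len(n),
    cluster_id = sample(seq_len(max(2, n %/% 3)), n, replace = TRUE),
    stratum = sample(seq_len(n_strata), n, replace = TRUE),
    arm = sample(c("notification", "control"), n, replace = TRUE),
    t_valve = v$t, d_valve = v$d, t_mht = m$t, d_mht = m$d,
    censor_time = censor, stringsAsFactors = FALSE)
}

# swap arm labels, for antisymmetry checks
swap_arms <- function(outcomes) {
  outcomes$arm <- ifelse(outcomes$arm == "notification",
                         "control", "notification")
  outcomes
}
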