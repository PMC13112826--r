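#' Read a patient-outcome table
#'
#' Reads the CSV schema written by [write_outcomes()] (and
#' [generate_trial()]): `patient_id, cluster_id, stratum, arm, t_valve,
#' d_valve, t_mht, d_mht, censor_time`, comma-separated, UTF-8, header
#' required, empty cell = absent.  Every record is validated; errors name the
#' offending row and field.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame of outcomes (possibly zero rows).
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "cluster_id", "stratum", "arm", "t_valve",
                "d_valve", "t_mht", "d_mht", "censor_time")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(df)
  bad_arm <- which(!df$arm %in% c("notification", "control"))
  if (length(bad_arm) > 0)
    stop("row ", bad_arm[1], ", field 'arm': invalid value '",
         df$arm[bad_arm[1]], "'")
  for (col in c("t_valve", "t_mht", "censor_time")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad) > 0)
      stop("row ", bad[1], ", field '", col,
           "': missing, non-numeric or non-positive time")
    df[[col]] <- v
  }
  for (col in c("d_valve", "d_mht")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | !v %in% c(0L, 1L))
    if (length(bad) > 0)
      stop("row ", bad[1], ", field '", col, "': event flag must be 0 or 1")
    df[[col]] <- v
  }
  for (ep in c("valve", "mht")) {
    tcol <- paste0("t_", ep); dcol <- paste0("d_", ep)
    bad <- which((df[[dcol]] == 1L & df[[tcol]] > df$censor_time) |
                   (df[[dcol]] == 0L & df[[tcol]] != df$censor_time))
    if (length(bad) > 0)
      stop("row ", bad[1], ", field '", tcol,
           "': time inconsistent with event flag and censor_time")
  }
  df
}

#' Write a patient-outcome table
#'
#' CSV companion of [read_outcomes()]; writing then reading any valid
#' outcome set is the identity.
#'
#' @param outcomes Outcome data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an eligibility screening report
#'
#' Writes [screen_cohort()] output either as CSV (semicolon-joined reasons)
#' or as JSON lines for pipeline use.
#'
#' @param results Data frame from [screen_cohort()].
#' @param path Destination path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_screening <- function(results, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(results)), function(i) {
      rec <- as.list(results[i, ])
      rec$reasons <- strsplit(results$reasons[i], ";", fixed = TRUE)[[1]]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

# Independent re-encoding of the inclusion/exclusion tables as one nested
# boolean expression, used only to label generated fixtures.  Deliberately
# written straight off the rule tables, sharing no code with classify_as()
# and screen().
.fixture_expected <- function(ava, di, mg, pg, jv, mr, age,
                              prior_ao, prior_mi, mht_orderer, scheduled,
                              same_stay) {
  crit <- "none"
  if ((!is.na(ava) && ava <= 1.0) || (!is.na(di) && di <= 0.25)) {
    if ((!is.na(mg) && mg >= 15) || (!is.na(pg) && pg >= 30) ||
        (!is.na(jv) && jv >= 2.75)) crit <- "CRIT1_AVA_DI"
  }
  if (crit == "none" && !is.na(ava) && ava > 1.0 && ava <= 1.2) {
    if ((!is.na(mg) && mg >= 40) || (!is.na(pg) && pg >= 64) ||
        (!is.na(jv) && jv >= 4.0)) crit <- "CRIT2_AVA_PLUS"
  }
  if (crit == "none" && (is.na(ava) || ava > 1.2)) {
    if ((!is.na(mg) && mg >= 40) || (!is.na(pg) && pg >= 64) ||
        (!is.na(jv) && jv >= 4.0)) crit <- "POSSIBLE"
  }
  if (crit == "none" &&
      ((!is.na(ava) && ava <= 1.0) || (!is.na(di) && di <= 0.25)) &&
      !(is.na(mg) && is.na(pg) && is.na(jv)) &&
      (is.na(mg) || mg < 15) && (is.na(pg) || pg < 30) &&
      (is.na(jv) || jv < 2.75)) crit <- "POSSIBLE"

  mr_ok <- !is.na(mr) && mr %in% c("moderate_to_severe", "severe")
  if (crit == "none" && !mr_ok)
    return(list(status = "EXCLUDED", as_criterion = "none"))
  target_prior <- if (crit != "none") prior_ao else prior_mi
  excluded <- age < 18 || target_prior || mht_orderer || scheduled ||
    same_stay
  status <- if (excluded) "EXCLUDED"
    else if (crit == "POSSIBLE") "AS_POSSIBLE"
    else if (crit != "none") "AS_ELIGIBLE"
    else "MR_ELIGIBLE"
  list(status = status, as_criterion = crit)
}

#' Generate boundary-straddling eligibility fixtures
#'
#' Builds a seeded fixture set for regression-testing the screening engine:
#' measurement values straddling every decision threshold (a small offset on
#' either side plus the exact threshold), crossed with MR grades, ages around
#' 18, and exclusion flags.  The expected label of every fixture is computed
#' by an independent re-encoding of the rule tables written as plain nested
#' boolean logic, not by the engine under test.
#'
#' @param n Number of fixtures (>= 1); rows are drawn from the full threshold
#'   grid, cycling deterministically if `n` exceeds the grid.
#' @param seed Integer seed.
#' @return Data frame of inputs plus `expected_status` and
#'   `expected_criterion`.
#' @export
make_echo_fixtures <- function(n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  eps <- 0.01
  around <- function(x, scale = 1) c(NA, x - eps * scale, x, x + eps * scale)
  ava_v <- c(around(1.0), around(1.2), 0.5, 2.0)
  di_v <- c(NA, 0.24, 0.25, 0.26)
  mg_v <- c(around(15, 10), around(40, 10))
  pg_v <- c(around(30, 10), around(64, 10))
  jv_v <- c(around(2.75), around(4.0))
  mr_v <- c(NA, "moderate", "moderate_to_severe", "severe")
  age_v <- c(17, 18, 70)
  flag_v <- c(FALSE, TRUE)

  draw <- function(pool, k) pool[1 + (sample.int(length(pool), k,
                                                 replace = TRUE) - 1)]
  df <- data.frame(
    ava = draw(ava_v, n), di = draw(di_v, n), mean_gradient = draw(mg_v, n),
    peak_gradient = draw(pg_v, n), jet_velocity = draw(jv_v, n),
    mr_severity = draw(mr_v, n), age = draw(age_v, n),
    prior_aortic_prosthesis = draw(flag_v, n),
    prior_mitral_prosthesis = draw(flag_v, n),
    orderer_is_mht_or_surgeon = draw(flag_v, n),
    scheduled_mht_visit_or_intervention = draw(flag_v, n),
    same_stay_valve_intervention = draw(flag_v, n),
    stringsAsFactors = FALSE)
  # pin exact-threshold and precedence cases so small n still covers them
  pins <- data.frame(
    ava = c(1.0, 1.2, NA, 0.9, NA, 0.8),
    di = c(NA, NA, 0.25, NA, NA, NA),
    mean_gradient = c(15, 40, 15, 20, NA, 10),
    peak_gradient = c(NA, NA, NA, NA, NA, 25),
    jet_velocity = c(NA, NA, NA, NA, NA, 2.5),
    mr_severity = c(NA, NA, NA, "severe", "moderate_to_severe", NA),
    age = c(70, 70, 70, 70, 70, 70),
    prior_aortic_prosthesis = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    prior_mitral_prosthesis = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    orderer_is_mht_or_surgeon = FALSE,
    scheduled_mht_visit_or_intervention = FALSE,
    same_stay_valve_intervention = FALSE,
    stringsAsFactors = FALSE)
  k <- min(nrow(pins), n)
  df[seq_len(k), ] <- pins[seq_len(k), ]

  exp_status <- character(n); exp_crit <- character(n)
  for (i in seq_len(n)) {
    e <- .fixture_expected(df$ava[i], df$di[i], df$mean_gradient[i],
                           df$peak_gradient[i], df$jet_velocity[i],
                           df$mr_severity[i], df$age[i],
                           df$prior_aortic_prosthesis[i],
                           df$prior_mitral_prosthesis[i],
                           df$orderer_is_mht_or_surgeon[i],
                           df$scheduled_mht_visit_or_intervention[i],
                           df$same_stay_valve_intervention[i])
    exp_status[i] <- e$status
    exp_crit[i] <- e$as_criterion
  }
  df$expected_status <- exp_status
  df$expected_criterion <- exp_crit
  df
}
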