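#' Echocardiogram report record
#'
#' Constructs a validated single-echo record holding the quantitative aortic
#' measurements and the qualitative mitral regurgitation grade used by the
#' screening rules.  Absent measurements are passed as `NA`.
#'
#' @param ava Aortic valve area in cm^2, or `NA`.
#' @param di Dimensionless index (velocity-integral ratio) in (0, 1], or `NA`.
#' @param mean_gradient Aortic mean gradient in mm Hg, or `NA`.
#' @param peak_gradient Aortic peak gradient in mm Hg, or `NA`.
#' @param jet_velocity Aortic jet (peak) velocity in m/s, or `NA`.
#' @param mr_severity Qualitative MR grade: one of `"none"`, `"mild"`,
#'   `"moderate"`, `"moderate_to_severe"`, `"severe"`, or `NA` when the report
#'   does not grade MR.
#' @param setting `"inpatient"` or `"outpatient"`.
#' @param echo_date Calendar date of the echocardiogram (`Date` or coercible).
#' @param discharge_date Discharge date; required for inpatients, must be `NA`
#'   for outpatients, and may not precede `echo_date`.
#' @return An object of class `echo_report` (a named list).
#' @export
echo_report <- function(ava = NA_real_, di = NA_real_,
                        mean_gradient = NA_real_, peak_gradient = NA_real_,
                        jet_velocity = NA_real_, mr_severity = NA_character_,
                        setting = "outpatient",
                        echo_date = Sys.Date(), discharge_date = NA) {
  num <- c(ava = ava, di = di, mean_gradient = mean_gradient,
           peak_gradient = peak_gradient, jet_velocity = jet_velocity)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.na(v)) {
      if (!is.numeric(v) || v <= 0)
        stop("measurement '", nm, "' must be strictly positive, got ", v)
    }
  }
  if (!is.na(di) && di > 1) stop("di must be <= 1, got ", di)
  setting <- match.arg(setting, c("outpatient", "inpatient"))
  if (!is.na(mr_severity))
    mr_severity <- match.arg(mr_severity, mr_levels())
  echo_date <- as.Date(echo_date)
  discharge_date <- as.Date(discharge_date)
  if (setting == "inpatient") {
    if (is.na(discharge_date))
      stop("inpatient echo requires a discharge_date")
    if (discharge_date < echo_date)
      stop("discharge_date precedes echo_date")
  } else if (!is.na(discharge_date)) {
    stop("discharge_date is only meaningful for inpatient echoes")
  }
  structure(list(ava = as.numeric(ava), di = as.numeric(di),
                 mean_gradient = as.numeric(mean_gradient),
                 peak_gradient = as.numeric(peak_gradient),
                 jet_velocity = as.numeric(jet_velocity),
                 mr_severity = mr_severity, setting = setting,
                 echo_date = echo_date, discharge_date = discharge_date),
            class = "echo_report")
}

mr_levels <- function() {
  c("none", "mild", "moderate", "moderate_to_severe", "severe")
}

#' Patient context for exclusion screening
#'
#' Non-echo facts about the patient and the ordering encounter that drive the
#' exclusion rules.  The "recent or already-scheduled heart-team visit or
#' intervention" condition is a single boolean: the calendar lookback against
#' the site study start date is the caller's responsibility.
#'
#' @param age Age in years (>= 0).
#' @param prior_aortic_prosthesis,prior_mitral_prosthesis Prior transcatheter
#'   or surgical repair/replacement of the aortic / mitral valve.
#' @param orderer_is_mht_or_surgeon Echo ordered by a heart-team cardiologist
#'   or cardiac surgeon.
#' @param scheduled_mht_visit_or_intervention Recent or scheduled heart-team
#'   visit, or scheduled valve intervention.
#' @param same_stay_valve_intervention Valve intervention during the same
#'   hospital stay (inpatients).
#' @return An object of class `patient_context`.
#' @export
patient_context <- function(age,
                            prior_aortic_prosthesis = FALSE,
                            prior_mitral_prosthesis = FALSE,
                            orderer_is_mht_or_surgeon = FALSE,
                            scheduled_mht_visit_or_intervention = FALSE,
                            same_stay_valve_intervention = FALSE) {
  if (!is.numeric(age) || is.na(age) || age < 0)
    stop("age must be a nonnegative number")
  structure(list(
    age = as.numeric(age),
    prior_aortic_prosthesis = isTRUE(prior_aortic_prosthesis),
    prior_mitral_prosthesis = isTRUE(prior_mitral_prosthesis),
    orderer_is_mht_or_surgeon = isTRUE(orderer_is_mht_or_surgeon),
    scheduled_mht_visit_or_intervention =
      isTRUE(scheduled_mht_visit_or_intervention),
    same_stay_valve_intervention = isTRUE(same_stay_valve_intervention)),
    class = "patient_context")
}

## Threshold constants for the aortic stenosis inclusion rules.  Criterion 1
## pairs a small valve area (or low dimensionless index) with at least one
## concordant hemodynamic measure; criterion 2 admits a borderline area when
## the hemodynamics are unambiguously severe; POSSIBLE captures discordant
## patterns that need human review.
.as_thresholds <- list(
  ava_low = 1.0, ava_borderline = 1.2, di_low = 0.25,
  mg_min = 15, pg_min = 30, jv_min = 2.75,
  mg_severe = 40, pg_severe = 64, jv_severe = 4.0)

# NA-safe clause helpers: an absent measurement never satisfies a clause.
.ge <- function(x, cut) !is.na(x) & x >= cut
.le <- function(x, cut) !is.na(x) & x <= cut
.lt <- function(x, cut) !is.na(x) & x < cut

#' Classify a report against the aortic stenosis inclusion criteria
#'
#' Evaluates the three-tier AS inclusion logic.  Criterion 1
#' (`"CRIT1_AVA_DI"`): AVA <= 1.0 cm^2 or DI <= 0.25, with at least one
#' hemodynamic measure at or above the minimum thresholds (mean gradient 15,
#' peak gradient 30, jet velocity 2.75).  Criterion 2 (`"CRIT2_AVA_PLUS"`):
#' 1.0 < AVA <= 1.2 with severe hemodynamics (mean 40 / peak 64 / velocity
#' 4.0).  `"POSSIBLE"` (requires human review): either AVA absent or > 1.2
#' with severe hemodynamics, or small AVA / low DI with every present
#' hemodynamic measure below the minimum thresholds (at least one present).
#' Tiers are evaluated in that order and the first match is returned.
#'
#' Absent measurements satisfy no numeric clause, except the POSSIBLE
#' branch's explicit "AVA absent" alternative.
#'
#' @param echo An [echo_report()].
#' @return One of `"CRIT1_AVA_DI"`, `"CRIT2_AVA_PLUS"`, `"POSSIBLE"`,
#'   `"none"`.
#' @export
classify_as <- function(echo) {
  stopifnot(inherits(echo, "echo_report"))
  th <- .as_thresholds
  small_valve <- .le(echo$ava, th$ava_low) | .le(echo$di, th$di_low)
  hemo_min <- .ge(echo$mean_gradient, th$mg_min) |
    .ge(echo$peak_gradient, th$pg_min) |
    .ge(echo$jet_velocity, th$jv_min)
  hemo_severe <- .ge(echo$mean_gradient, th$mg_severe) |
    .ge(echo$peak_gradient, th$pg_severe) |
    .ge(echo$jet_velocity, th$jv_severe)

  if (small_valve && hemo_min) return("CRIT1_AVA_DI")

  borderline <- !is.na(echo$ava) &&
    echo$ava > th$ava_low && echo$ava <= th$ava_borderline
  if (borderline && hemo_severe) return("CRIT2_AVA_PLUS")

  ava_null_or_large <- is.na(echo$ava) || echo$ava > th$ava_borderline
  if (ava_null_or_large && hemo_severe) return("POSSIBLE")

  # Discordant branch: low-flow pattern with all present hemodynamics below
  # the minimum thresholds; undefined over fully absent hemodynamics.
  hemo_present <- !is.na(echo$mean_gradient) || !is.na(echo$peak_gradient) ||
    !is.na(echo$jet_velocity)
  all_below <- (is.na(echo$mean_gradient) | .lt(echo$mean_gradient, th$mg_min)) &
    (is.na(echo$peak_gradient) | .lt(echo$peak_gradient, th$pg_min)) &
    (is.na(echo$jet_velocity) | .lt(echo$jet_velocity, th$jv_min))
  if (small_valve && hemo_present && all_below) return("POSSIBLE")

  "none"
}

#' Classify a report against the mitral regurgitation inclusion criterion
#'
#' The MR rule is purely qualitative: a mention of moderate-to-severe or
#' severe MR qualifies; moderate or lesser grades, or no mention, do not.
#' Quantitative MR measurements are never consulted.
#'
#' @param echo An [echo_report()].
#' @return `TRUE` iff `mr_severity` is `"moderate_to_severe"` or `"severe"`.
#' @export
classify_mr <- function(echo) {
  stopifnot(inherits(echo, "echo_report"))
  !is.na(echo$mr_severity) &&
    echo$mr_severity %in% c("moderate_to_severe", "severe")
}

#' Exclusion rules against a target valve
#'
#' Returns the machine-readable codes of every triggered exclusion.  A
#' prosthesis on the *non*-target valve does not exclude: a patient flagged
#' for aortic stenosis with a mitral prosthesis remains eligible, and vice
#' versa.
#'
#' @param ctx A [patient_context()].
#' @param target_valve `"aortic"` or `"mitral"` — the valve whose disease
#'   criterion fired.
#' @return Character vector of triggered codes, in stable order, possibly
#'   empty.
#' @export
apply_exclusions <- function(ctx, target_valve = c("aortic", "mitral")) {
  stopifnot(inherits(ctx, "patient_context"))
  target_valve <- match.arg(target_valve)
  prior_target <- if (target_valve == "aortic")
    ctx$prior_aortic_prosthesis else ctx$prior_mitral_prosthesis
  codes <- c(
    UNDER_18 = ctx$age < 18,
    PRIOR_TARGET_VALVE_TREATMENT = prior_target,
    ORDERED_BY_MHT_OR_SURGEON = ctx$orderer_is_mht_or_surgeon,
    ALREADY_SCHEDULED_OR_RECENT_MHT_OR_INTERVENTION =
      ctx$scheduled_mht_visit_or_intervention,
    SAME_STAY_INTERVENTION = ctx$same_stay_valve_intervention)
  names(codes)[codes]
}

#' Screen one echo report
#'
#' Full eligibility decision for a single report.  Aortic stenosis is
#' evaluated first: if any AS tier fires the target valve is aortic and an MR
#' finding is ignored for this result.  The POSSIBLE tier yields
#' `"AS_POSSIBLE"` — flagged for manual review, never an automatic
#' notification.  Exclusions are applied against the target valve; any
#' triggered exclusion makes the status `"EXCLUDED"`.  A report matching no
#' disease criterion is `"EXCLUDED"` with reason `"NO_QUALIFYING_FINDINGS"`.
#'
#' @param echo An [echo_report()].
#' @param ctx A [patient_context()].
#' @return An `eligibility_result`: list with `status` (one of
#'   `"AS_ELIGIBLE"`, `"AS_POSSIBLE"`, `"MR_ELIGIBLE"`, `"EXCLUDED"`),
#'   `as_criterion`, `target_valve`, and `reasons` (inclusion codes first,
#'   then exclusion codes, in stable order).
#' @export
screen <- function(echo, ctx) {
  stopifnot(inherits(echo, "echo_report"), inherits(ctx, "patient_context"))
  crit <- classify_as(echo)
  mr <- classify_mr(echo)

  if (crit != "none") {
    target <- "aortic"
    inclusion <- paste0("AS_", crit)
  } else if (mr) {
    target <- "mitral"
    inclusion <- "MR_QUALITATIVE"
  } else {
    return(structure(list(status = "EXCLUDED", as_criterion = "none",
                          target_valve = NA_character_,
                          reasons = "NO_QUALIFYING_FINDINGS"),
                     class = "eligibility_result"))
  }

  excl <- apply_exclusions(ctx, target)
  status <- if (length(excl) > 0) "EXCLUDED"
    else if (crit == "POSSIBLE") "AS_POSSIBLE"
    else if (crit != "none") "AS_ELIGIBLE"
    else "MR_ELIGIBLE"
  structure(list(
    status = status,
    as_criterion = if (crit == "none") "none" else crit,
    target_valve = target,
    reasons = c(inclusion, excl)),
    class = "eligibility_result")
}

#' Screen a cohort table
#'
#' Vectorized wrapper around [screen()] for delimited-text input: one row per
#' echo, columns named after the [echo_report()] and [patient_context()]
#' fields, empty/`NA` cells meaning absent.  Missing context columns default
#' to `FALSE` flags.
#'
#' @param df A data frame with at least an `age` column; measurement and flag
#'   columns are optional.
#' @return `df`'s identifier column (or row index) with `status`,
#'   `as_criterion` and semicolon-joined `reasons` appended.
#' @export
screen_cohort <- function(df) {
  stopifnot(is.data.frame(df), "age" %in% names(df))
  get_col <- function(nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  n <- nrow(df)
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) df$patient_id else seq_len(n),
    status = character(n), as_criterion = character(n),
    reasons = character(n), stringsAsFactors = FALSE)
  ava <- as.numeric(get_col("ava", NA_real_))
  di <- as.numeric(get_col("di", NA_real_))
  mg <- as.numeric(get_col("mean_gradient", NA_real_))
  pg <- as.numeric(get_col("peak_gradient", NA_real_))
  jv <- as.numeric(get_col("jet_velocity", NA_real_))
  mr <- as.character(get_col("mr_severity", NA_character_))
  mr[!is.na(mr) & mr == ""] <- NA_character_
  for (i in seq_len(n)) {
    echo <- echo_report(ava = ava[i], di = di[i], mean_gradient = mg[i],
                        peak_gradient = pg[i], jet_velocity = jv[i],
                        mr_severity = mr[i])
    ctx <- patient_context(
      age = df$age[i],
      prior_aortic_prosthesis = isTRUE(get_col("prior_aortic_prosthesis", FALSE)[i]),
      prior_mitral_prosthesis = isTRUE(get_col("prior_mitral_prosthesis", FALSE)[i]),
      orderer_is_mht_or_surgeon = isTRUE(get_col("orderer_is_mht_or_surgeon", FALSE)[i]),
      scheduled_mht_visit_or_intervention =
        isTRUE(get_col("scheduled_mht_visit_or_intervention", FALSE)[i]),
      same_stay_valve_intervention =
        isTRUE(get_col("same_stay_valve_intervention", FALSE)[i]))
    res <- screen(echo, ctx)
    out$status[i] <- res$status
    out$as_criterion[i] <- res$as_criterion
    out$reasons[i] <- paste(res$reasons, collapse = ";")
  }
  out
}
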