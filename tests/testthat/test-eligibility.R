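test_that("aortic stenosis tiers classify per the rule table, including exact thresholds", {
  cases <- list(
    # low AVA + concordant hemodynamics
    list(args = list(ava = 0.9, mean_gradient = 20), want = "CRIT1_AVA_DI"),
    # borderline AVA needs severe hemodynamics
    list(args = list(ava = 1.1, jet_velocity = 4.2), want = "CRIT2_AVA_PLUS"),
    # discordant low-gradient pattern: review
    list(args = list(ava = 0.8, mean_gradient = 10, peak_gradient = 25,
                     jet_velocity = 2.5), want = "POSSIBLE"),
    # severe hemodynamics without a measured AVA: review
    list(args = list(mean_gradient = 45), want = "POSSIBLE"),
    # nothing measured matches nothing
    list(args = list(), want = "none"),
    # boundary inclusivity at each printed threshold
    list(args = list(ava = 1.0, mean_gradient = 15), want = "CRIT1_AVA_DI"),
    list(args = list(di = 0.25, jet_velocity = 2.75), want = "CRIT1_AVA_DI"),
    list(args = list(ava = 1.0, peak_gradient = 30), want = "CRIT1_AVA_DI"),
    list(args = list(ava = 1.2, mean_gradient = 40), want = "CRIT2_AVA_PLUS"),
    list(args = list(ava = 1.2, peak_gradient = 64), want = "CRIT2_AVA_PLUS"),
    list(args = list(ava = 1.21, jet_velocity = 4.0), want = "POSSIBLE"),
    # tier precedence: values satisfying tier 1 never fall to tier 2
    list(args = list(ava = 0.9, di = 0.2, mean_gradient = 50), want = "CRIT1_AVA_DI"),
    # borderline AVA with sub-severe hemodynamics matches nothing
    list(args = list(ava = 1.1, mean_gradient = 20), want = "none"),
    # low DI alone with no hemodynamic measurement matches nothing
    list(args = list(di = 0.2), want = "none"))
  for (cs in cases) {
    echo <- do.call(echo_report, cs$args)
    expect_identical(classify_as(echo), cs$want,
                     info = paste(deparse(cs$args), collapse = ""))
  }
})

test_that("MR rule is qualitative and only moderate-to-severe or worse qualifies", {
  expect_true(classify_mr(echo_report(mr_severity = "severe")))
  expect_true(classify_mr(echo_report(mr_severity = "moderate_to_severe")))
  expect_false(classify_mr(echo_report(mr_severity = "moderate")))
  expect_false(classify_mr(echo_report(mr_severity = "mild")))
  expect_false(classify_mr(echo_report()))
})

test_that("measurement validation rejects non-positive values and bad DI", {
  expect_error(echo_report(ava = -0.5), "strictly positive")
  expect_error(echo_report(mean_gradient = 0), "strictly positive")
  expect_error(echo_report(di = 1.4), "di must be")
  expect_error(echo_report(setting = "inpatient"), "discharge_date")
})

test_that("exclusions trigger only against the target valve", {
  expect_identical(apply_exclusions(patient_context(age = 17), "aortic"),
                   "UNDER_18")
  # prosthesis on the non-target valve does not exclude
  ctx <- patient_context(age = 70, prior_mitral_prosthesis = TRUE)
  expect_identical(apply_exclusions(ctx, "aortic"), character(0))
  expect_identical(apply_exclusions(ctx, "mitral"),
                   "PRIOR_TARGET_VALVE_TREATMENT")
  expect_identical(
    apply_exclusions(patient_context(age = 70,
                                     orderer_is_mht_or_surgeon = TRUE),
                     "aortic"),
    "ORDERED_BY_MHT_OR_SURGEON")
  # multiple triggers reported together, in stable order
  busy <- patient_context(age = 16, prior_aortic_prosthesis = TRUE,
                          scheduled_mht_visit_or_intervention = TRUE)
  expect_identical(apply_exclusions(busy, "aortic"),
                   c("UNDER_18", "PRIOR_TARGET_VALVE_TREATMENT",
                     "ALREADY_SCHEDULED_OR_RECENT_MHT_OR_INTERVENTION"))
})

test_that("screening applies AS before MR and carries reason codes", {
  clean <- patient_context(age = 70)
  both <- screen(echo_report(ava = 0.9, mean_gradient = 20,
                             mr_severity = "severe"), clean)
  expect_identical(both$status, "AS_ELIGIBLE")
  expect_identical(both$target_valve, "aortic")
  expect_identical(both$as_criterion, "CRIT1_AVA_DI")

  mr_only <- screen(echo_report(mr_severity = "moderate_to_severe"), clean)
  expect_identical(mr_only$status, "MR_ELIGIBLE")
  expect_identical(mr_only$as_criterion, "none")

  minor <- screen(echo_report(ava = 0.9, mean_gradient = 20),
                  patient_context(age = 17))
  expect_identical(minor$status, "EXCLUDED")
  expect_true("UNDER_18" %in% minor$reasons)

  possible <- screen(echo_report(ava = 0.8, mean_gradient = 10), clean)
  expect_identical(possible$status, "AS_POSSIBLE")

  nothing <- screen(echo_report(), clean)
  expect_identical(nothing$status, "EXCLUDED")
  expect_identical(nothing$reasons, "NO_QUALIFYING_FINDINGS")
})

test_that("no input is simultaneously AS- and MR-eligible, and screening is deterministic", {
  fx <- make_echo_fixtures(400, seed = 9)
  for (i in seq_len(nrow(fx))) {
    echo <- echo_report(ava = fx$ava[i], di = fx$di[i],
                        mean_gradient = fx$mean_gradient[i],
                        peak_gradient = fx$peak_gradient[i],
                        jet_velocity = fx$jet_velocity[i],
                        mr_severity = fx$mr_severity[i])
    ctx <- patient_context(
      age = fx$age[i],
      prior_aortic_prosthesis = fx$prior_aortic_prosthesis[i],
      prior_mitral_prosthesis = fx$prior_mitral_prosthesis[i],
      orderer_is_mht_or_surgeon = fx$orderer_is_mht_or_surgeon[i],
      scheduled_mht_visit_or_intervention =
        fx$scheduled_mht_visit_or_intervention[i],
      same_stay_valve_intervention = fx$same_stay_valve_intervention[i])
    r1 <- screen(echo, ctx)
    expect_length(r1$status, 1)
    if (r1$status == "MR_ELIGIBLE") expect_identical(r1$as_criterion, "none")
    # byte-identical rerun
    expect_identical(r1, screen(echo, ctx))
  }
})

test_that("engine agrees with the independent rule re-encoding on a boundary grid", {
  fx <- make_echo_fixtures(2000, seed = 4)
  got <- screen_cohort(fx)
  expect_identical(got$status, fx$expected_status)
  expect_identical(got$as_criterion, fx$expected_criterion)
})
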