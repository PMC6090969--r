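test_that("packaged fixtures carry the printed source values exactly", {
  for (pop in c("conventional_care_failure", "tnf_failure")) {
    raw <- read_raw_fixture(pop)
    inp <- published_baseline_inputs(pop)

    pp <- published_populations[[pop]]
    expect_identical(raw$population$mean_age, pp$mean_age)
    expect_identical(raw$population$proportion_female, pp$proportion_female)
    expect_identical(unlist(raw$population$weight_bands), pp$weight_bands)
    expect_identical(raw$population$gamma_mod_sev_remainder, pp$gamma)

    expect_identical(unlist(raw$costs$state_direct_2wk),
                     published_state_costs$direct)
    expect_identical(unlist(raw$costs$state_indirect_2wk),
                     published_state_costs$indirect)
    expect_identical(raw$costs$iv_admin, 257L)
    expect_identical(raw$costs$sc_inhospital_admin, 124L)
    expect_identical(raw$costs$concomitant_soc_fraction, 0.5)
    expect_identical(raw$currency$sek_to_eur, 0.1057)
    expect_identical(unlist(raw$utilities$state), published_utilities)
    expect_identical(unlist(raw$utilities$ae_disutility),
                     published_disutilities)

    expect_identical(raw$structural$induction_surgery_prob, 0.02)
    expect_identical(raw$structural$annual_surgery_prob, 0.07)
    expect_identical(raw$structural$discount_rate_costs, 0.03)
    expect_identical(raw$structural$horizon_years, 60L)
    expect_identical(raw$structural$treatment_duration_years, 2L)
    expect_identical(raw$structural$wtp_reference, 63000L)

    for (arm in c("intervention", "comparator")) {
      t_raw <- raw$treatments[[arm]]
      nm <- t_raw$name
      expect_identical(t_raw$drug$pack_cost,
                       as.integer(published_drug_prices[[nm]]))
      expect_identical(unlist(t_raw$ae_cycle_rates), published_ae_rates[[nm]])
      expect_identical(t_raw$discontinuation_cycle_prob_standard,
                       unname(published_discontinuation[[nm]]["standard"]))
      expect_identical(t_raw$discontinuation_cycle_prob_escalated,
                       unname(published_discontinuation[[nm]]["escalated"]))
      eff <- published_efficacy[published_efficacy$population == pop &
                                  published_efficacy$treatment == nm, ]
      for (k in seq_len(nrow(eff))) {
        stage <- t_raw$efficacy$CDAI100[[eff$stage[k]]]
        expect_identical(stage$response, eff$response[k])
        expect_identical(stage$remission, eff$remission[k])
      }
    }

    # loaded object carries the same values through validation
    expect_equal(inp$treatments$intervention$drug$pack_cost, 3546)
    expect_equal(inp$utilities$state$remission, 0.80)
  }
})

test_that("dosing schedules and escalation rates match the printed regimens", {
  conv <- read_raw_fixture("conventional_care_failure")
  tnf <- read_raw_fixture("tnf_failure")

  ust <- conv$treatments$intervention
  expect_identical(unlist(ust$induction$first$weight_band_mg),
                   c(260L, 390L, 520L))
  expect_identical(ust$induction$first$route, "IV")
  expect_identical(unlist(ust$induction$second$weeks), 8L)
  expect_identical(ust$maintenance$interval_weeks, 12L)
  expect_identical(ust$escalation_cycle_prob, 0.02)

  ada <- conv$treatments$comparator
  expect_identical(unlist(ada$induction$first$doses_mg), c(160L, 80L))
  expect_identical(unlist(ada$induction$first$weeks), c(0L, 2L))
  expect_identical(ada$maintenance$interval_weeks, 2L)
  expect_identical(ada$escalation_cycle_prob, 0.03)

  ved <- tnf$treatments$comparator
  expect_identical(unlist(ved$induction$first$weeks), c(0L, 2L, 6L))
  expect_identical(ved$maintenance$route, "IV")
  expect_identical(ved$maintenance$interval_weeks, 8L)
  expect_identical(ved$escalation_cycle_prob, 0.02)
})

test_that("synthetic stand-in fields are declared in the provenance record", {
  inp <- published_baseline_inputs("conventional_care_failure")
  expect_true("unpublished" %in% inp$provenance)
  expect_true("costs.ae_unit_costs" %in% inp$provenance)
  expect_true(any(grepl("soc_drug_cost", inp$provenance)))
})

test_that("validation rejects corrupted documents, naming the field", {
  base <- read_raw_fixture("conventional_care_failure")

  bad <- base
  bad$population$weight_bands <- c(0.5, 0.6, 0.1)
  expect_error(as_model_inputs(bad), "weight_bands sum != 1")

  bad <- base
  bad$costs$iv_admin <- -5
  expect_error(as_model_inputs(bad), "costs.iv_admin")

  bad <- base
  bad$treatments$intervention$efficacy$CDAI100$first$remission <- 0.9
  expect_error(as_model_inputs(bad), "remission rate cannot exceed response")

  bad <- base
  bad$utilities$state$mild <- 1.4
  expect_error(as_model_inputs(bad), "utilities.state")

  # remission below response but infeasible once the moderate-to-severe
  # responder fraction is carved out
  bad <- base
  bad$treatments$intervention$efficacy$CDAI100$first$remission <- 0.54
  expect_error(as_model_inputs(bad), "net of the moderate-to-severe")

  bad <- base
  bad$structural <- NULL
  expect_error(as_model_inputs(bad), "structural")

  # all failures reported at once, not just the first
  bad <- base
  bad$costs$iv_admin <- -5
  bad$utilities$state$mild <- 1.4
  err <- tryCatch(as_model_inputs(bad), error = conditionMessage)
  expect_match(err, "costs.iv_admin")
  expect_match(err, "utilities.state")
})

test_that("model inputs survive a write/reload round trip", {
  inp <- published_baseline_inputs("tnf_failure")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_inputs(inp, path)
  back <- load_model_inputs(path)
  expect_equal(back$population, inp$population)
  expect_equal(back$costs, inp$costs)
  expect_equal(back$utilities, inp$utilities)
  expect_equal(back$treatments, inp$treatments)
  expect_equal(.as_matrix_cmp(back$unpublished$soc_transition_matrix),
               .as_matrix_cmp(inp$unpublished$soc_transition_matrix))
  expect_equal(unlist(back$unpublished$post_surgery_distribution),
               unlist(inp$unpublished$post_surgery_distribution))
  expect_equal(back$unpublished$maintenance_targets,
               inp$unpublished$maintenance_targets)
})

test_that("loading a missing file fails cleanly", {
  expect_error(load_model_inputs("no_such_file.yaml"), "not found")
})
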