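zero_discount <- function(inputs) {
  tweak_inputs(inputs, function(x) {
    x$structural$discount_rate_costs <- 0
    x$structural$discount_rate_effects <- 0
    x
  })
}

make_strategy <- function(cost, qalys, name = "X", rc = 0.03, re = 0.03,
                          h = 60) {
  structure(list(treatment = name, components = c(total = cost),
                 total_cost = cost, total_qalys = qalys,
                 discount_rate_costs = rc, discount_rate_effects = re,
                 horizon_years = h), class = "cdcem_strategy")
}

test_that("discount factors follow the compound formula", {
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(2, 0.05), 1 / 1.05^2)
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(10, 0), 1)
  expect_error(discount_factor(1, -0.01))
})

test_that("one undiscounted cycle in moderate-to-severe accrues the printed tariffs", {
  inp <- zero_discount(published_baseline_inputs("conventional_care_failure"))
  tr <- make_stub_trace("moderate_severe.soc", n_cycles = 1)
  st <- accumulate_strategy(tr, make_stub_induction(), inp)
  expect_equal(st$components[["health_state"]], 108)
  expect_equal(st$components[["indirect"]], 374)
  # off biologic: standard-of-care drug only, no administration or AE costs
  expect_equal(st$components[["drug"]], inp$costs$soc_drug_cost_2wk)
  expect_equal(st$components[["administration"]], 0)
  expect_equal(st$components[["adverse_event"]], 0)
  expect_equal(st$total_qalys, 0.55 * 2 * 7 / 365.25, tolerance = 1e-12)
})

test_that("a cycle in the surgery state accrues surgical tariffs and complications", {
  inp <- zero_discount(published_baseline_inputs("conventional_care_failure"))
  tr <- make_stub_trace("surgery", n_cycles = 1)
  st <- accumulate_strategy(tr, make_stub_induction(), inp)
  expect_equal(st$components[["health_state"]], 7123)
  expect_equal(st$components[["indirect"]], 1326)
  expect_equal(st$components[["surgery_complication"]],
               inp$unpublished$surgery_complication_prob *
                 inp$costs$surgery_complication_cost)
  expect_equal(st$components[["drug"]], 0)
  expect_equal(st$total_qalys, 0.55 * 2 * 7 / 365.25, tolerance = 1e-12)
})

test_that("full health accrues exactly the elapsed time in QALYs", {
  inp <- zero_discount(tweak_inputs(
    published_baseline_inputs("conventional_care_failure"),
    function(x) { x$utilities$state$remission <- 1; x }))
  tr <- make_stub_trace("remission.soc", n_cycles = 10)
  st <- accumulate_strategy(tr, make_stub_induction(), inp)
  expect_equal(st$total_qalys, 10 * 2 * 7 / 365.25, tolerance = 1e-12)
})

test_that("intravenous maintenance administration is lumped at dosing cycles", {
  # the comparator regimen doses every 8 weeks, i.e. every 4th cycle
  inp <- zero_discount(published_baseline_inputs("tnf_failure"))
  ind <- make_stub_induction(arm = "comparator")
  st4 <- accumulate_strategy(
    make_stub_trace("remission.bio_std", 4, arm = "comparator"), ind, inp)
  expect_equal(st4$components[["administration"]], 257)
  st8 <- accumulate_strategy(
    make_stub_trace("remission.bio_std", 8, arm = "comparator"), ind, inp)
  expect_equal(st8$components[["administration"]], 2 * 257)
  # on-biologic cycles also accrue the per-cycle AE expectation
  rates <- unlist(inp$treatments$comparator$ae_cycle_rates)
  units <- unlist(inp$costs$ae_unit_costs)[names(rates)]
  expect_equal(st4$components[["adverse_event"]], 4 * sum(rates * units),
               tolerance = 1e-9)
})

test_that("excluding indirect costs removes exactly the indirect component", {
  inp <- tweak_inputs(published_baseline_inputs("conventional_care_failure"),
                      function(x) {
                        x$structural$horizon_years <- 3L
                        x$structural$treatment_duration_years <- 1L
                        x
                      })
  inp_off <- tweak_inputs(inp, function(x) {
    x$structural$include_indirect_costs <- FALSE
    x
  })
  m_bio <- matrix(c(0.9, 0.1, 0, 0.2, 0.7, 0.1, 0.05, 0.15, 0.8),
                  3, 3, byrow = TRUE)
  mats <- list(biologic = m_bio,
               soc = inp$unpublished$soc_transition_matrix)
  ind_on <- run_induction(inp, "intervention")
  tr <- run_maintenance(ind_on, inp, mats)
  st_on <- accumulate_strategy(tr, ind_on, inp)
  ind_off <- run_induction(inp_off, "intervention")
  st_off <- accumulate_strategy(tr, ind_off, inp_off)

  expect_equal(st_off$components[["indirect"]], 0)
  expect_equal(st_off$total_cost,
               st_on$total_cost - st_on$components[["indirect"]],
               tolerance = 1e-9)
  expect_equal(st_off$total_qalys, st_on$total_qalys, tolerance = 1e-12)
  expect_equal(st_on$total_cost, sum(st_on$components), tolerance = 1e-9)
})

test_that("steeper discounting strictly lowers both totals", {
  base <- published_baseline_inputs("conventional_care_failure")
  inp3 <- tweak_inputs(base, function(x) {
    x$structural$horizon_years <- 3L
    x
  })
  mats <- list(biologic = inp3$unpublished$soc_transition_matrix,
               soc = inp3$unpublished$soc_transition_matrix)
  ind <- run_induction(inp3, "intervention")
  tr <- run_maintenance(ind, inp3, mats)
  totals <- lapply(c(0, 0.03, 0.08), function(r) {
    inp_r <- tweak_inputs(inp3, function(x) {
      x$structural$discount_rate_costs <- r
      x$structural$discount_rate_effects <- r
      x
    })
    st <- accumulate_strategy(tr, ind, inp_r)
    c(st$total_cost, st$total_qalys)
  })
  expect_true(totals[[1]][1] > totals[[2]][1])
  expect_true(totals[[2]][1] > totals[[3]][1])
  expect_true(totals[[1]][2] > totals[[2]][2])
  expect_true(totals[[2]][2] > totals[[3]][2])
})

test_that("incremental analysis reproduces hand-computed published-style examples", {
  # cheaper and more effective: dominance, no ICER
  conv <- incremental_analysis(make_strategy(232225, 14.275, "A"),
                               make_strategy(239209, 14.043, "B"))
  expect_equal(conv$delta_cost, -6984)
  expect_equal(conv$delta_qalys, 0.232, tolerance = 1e-9)
  expect_identical(conv$classification, "intervention_dominates")
  expect_true(is.na(conv$icer))

  # dearer and more effective: ICER reported
  tnf <- incremental_analysis(make_strategy(244721 + 4023, 14.047 + 0.133,
                                            "A"),
                              make_strategy(244721, 14.047, "B"))
  expect_identical(tnf$classification, "icer_reported")
  expect_equal(tnf$icer, 4023 / 0.133, tolerance = 1e-9)
  expect_equal(tnf$icer, 30248.12, tolerance = 1e-6)
})

test_that("incremental analysis classifies dominance and degenerate cases", {
  dom <- incremental_analysis(make_strategy(100, 1), make_strategy(50, 2))
  expect_identical(dom$classification, "comparator_dominates")
  expect_true(is.na(dom$icer))

  tie <- incremental_analysis(make_strategy(100, 1), make_strategy(50, 1))
  expect_identical(tie$classification, "icer_reported")
  expect_true(is.na(tie$icer))

  # scaling all costs scales the ICER linearly
  a <- incremental_analysis(make_strategy(300, 2), make_strategy(100, 1))
  b <- incremental_analysis(make_strategy(600, 2), make_strategy(200, 1))
  expect_equal(b$icer, 2 * a$icer)
})

test_that("strategies run under different settings cannot be compared", {
  expect_error(incremental_analysis(make_strategy(1, 1, rc = 0.03),
                                    make_strategy(1, 1, rc = 0.05)),
               "refusing to compare")
  expect_error(incremental_analysis(make_strategy(1, 1, h = 60),
                                    make_strategy(1, 1, h = 15)),
               "refusing to compare")
})
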