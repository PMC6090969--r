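# independent brute-force CEAC: explicit loop over draws
brute_force_ceac <- function(draws, wtp) {
  vapply(wtp, function(w) {
    hits <- 0
    for (k in seq_len(nrow(draws))) {
      if (w * draws$delta_qalys[k] - draws$delta_cost[k] > 0) hits <- hits + 1
    }
    hits / nrow(draws)
  }, numeric(1))
}

test_that("an empty scenario reproduces the base inputs exactly", {
  base <- published_baseline_inputs("conventional_care_failure")
  expect_equal(apply_scenario(base, scenario("base case", list())), base)
})

test_that("scenario overrides apply and revert cleanly", {
  base <- published_baseline_inputs("tnf_failure")
  scn <- scenario("no discounting",
                  list(structural.discount_rate_costs = 0,
                       structural.discount_rate_effects = 0))
  mod <- apply_scenario(base, scn)
  expect_equal(mod$structural$discount_rate_costs, 0)
  expect_equal(mod$structural$discount_rate_effects, 0)
  back <- apply_scenario(mod, scenario("revert", list(
    structural.discount_rate_costs = 0.03,
    structural.discount_rate_effects = 0.03)))
  expect_equal(back, base)
})

test_that("unknown override paths are rejected", {
  base <- published_baseline_inputs("conventional_care_failure")
  expect_error(apply_scenario(base, scenario("x", list(
    structural.no_such_field = 1))), "unknown override path")
  expect_error(apply_scenario(base, scenario("x", list(
    nowhere.at_all = 1))), "unknown override path")
})

test_that("the packaged scenario grid loads and starts from the base case", {
  scns <- owsa_scenarios()
  expect_gte(length(scns), 10)
  expect_length(scns[[1]]$overrides, 0)
  expect_true(all(vapply(scns, inherits, logical(1), "cdcem_scenario")))
  # every packaged scenario must be applicable to both populations
  for (pop in c("conventional_care_failure", "tnf_failure")) {
    base <- published_baseline_inputs(pop)
    for (scn in scns) {
      expect_s3_class(apply_scenario(base, scn), "cdcem_inputs")
    }
  }
})

test_that("the sensitivity sweep's base row matches a direct run", {
  inp <- generate_random_scenario(12)
  sweep <- run_owsa(inp, list(scenario("base", list()),
                              scenario("no discounting", list(
                                structural.discount_rate_costs = 0,
                                structural.discount_rate_effects = 0))),
                    n_restarts = 1, seed = 7)
  direct <- run_comparison(inp, n_restarts = 1, seed = 7)
  expect_equal(sweep$delta_cost[1], direct$incremental$delta_cost)
  expect_equal(sweep$delta_qalys[1], direct$incremental$delta_qalys)
  expect_equal(nrow(sweep), 2)
  expect_false(sweep$delta_cost[2] == sweep$delta_cost[1])
})

test_that("net monetary benefit follows the defining identity", {
  expect_equal(nmb(4023, 0.133, 63000), 63000 * 0.133 - 4023)
  expect_equal(nmb(4023, 0.133, 63000), 4356, tolerance = 1e-9)
  expect_equal(nmb(500, 0, c(0, 1e5)), c(-500, -500))
  expect_equal(nmb(0, 0.1, c(0, 10, 20)), c(0, 1, 2))
  expect_error(nmb(1, 1, -5))
})

test_that("method-of-moments samplers hit their requested moments", {
  set.seed(88)
  b <- replicate(20000, cdcem:::.rbeta_mom(0.3, 0.05))
  expect_equal(mean(b), 0.3, tolerance = 0.01)
  expect_equal(stats::sd(b), 0.05, tolerance = 0.01)
  g <- replicate(20000, cdcem:::.rgamma_mom(200, 30))
  expect_equal(mean(g), 200, tolerance = 0.02 * 200)
  expect_equal(stats::sd(g), 30, tolerance = 0.05 * 30)
  # degenerate SE returns the mean untouched
  expect_identical(cdcem:::.rbeta_mom(0.3, 0), 0.3)
  expect_identical(cdcem:::.rgamma_mom(5, 0), 5)
})

test_that("PSA draws are valid, seed-reproducible, and identity at zero spread", {
  base <- generate_random_scenario(9)
  expect_identical(draw_psa_inputs(base, rel_se = 0), base)
  d1 <- cdcem:::.with_seed(42, draw_psa_inputs(base, rel_se = 0.1))
  d2 <- cdcem:::.with_seed(42, draw_psa_inputs(base, rel_se = 0.1))
  expect_equal(d1, d2)
  expect_s3_class(d1, "cdcem_inputs")
  soc <- cdcem:::.as_matrix3(d1$unpublished$soc_transition_matrix)
  expect_equal(unname(rowSums(soc)), rep(1, 3), tolerance = 1e-9)
  e <- d1$treatments$intervention$efficacy$CDAI100$first
  expect_lte(e$remission, e$response)
  expect_false(isTRUE(all.equal(d1$costs$soc_drug_cost_2wk,
                                base$costs$soc_drug_cost_2wk)))
})

test_that("a PSA run is exactly reproducible from its seed", {
  base <- generate_random_scenario(9)
  p1 <- run_psa(base, n_iterations = 3, seed = 15, n_restarts = 1)
  p2 <- run_psa(base, n_iterations = 3, seed = 15, n_restarts = 1)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 3)
  expect_true(all(is.finite(p1$draws$delta_cost)))
  expect_true(all(is.finite(p1$draws$delta_qalys)))
  # iterations differ from one another (parameters were actually sampled)
  expect_gt(stats::sd(p1$draws$delta_cost), 0)
})

test_that("the acceptability curve matches a brute-force recount", {
  draws <- data.frame(delta_cost = c(10, -5, 20, 1, -3),
                      delta_qalys = c(0.001, 0.0001, -0.001, 0, 0.0005))
  wtp <- c(0, 1000, 20000, 63000, 200000)
  got <- ceac(draws, wtp)
  expect_equal(got$prob_cost_effective, brute_force_ceac(draws, wtp))
  expect_equal(got$wtp, wtp)
  # hand check at wtp = 0: only strictly cost-saving draws count
  expect_equal(got$prob_cost_effective[1], 2 / 5)
})

test_that("acceptability limits behave: dominance gives 1, sign flip complements", {
  dominant <- data.frame(delta_cost = c(-10, -2, -7),
                         delta_qalys = c(0.1, 0.2, 0.05))
  expect_equal(ceac(dominant, c(0, 63000))$prob_cost_effective, c(1, 1))

  set.seed(3)
  draws <- data.frame(delta_cost = stats::rnorm(200, 5, 10),
                      delta_qalys = stats::rnorm(200, 0.01, 0.05))
  wtp <- c(1000, 63000, 150000)
  p <- ceac(draws, wtp)$prob_cost_effective
  flipped <- data.frame(delta_cost = -draws$delta_cost,
                        delta_qalys = -draws$delta_qalys)
  q <- ceac(flipped, wtp)$prob_cost_effective
  expect_equal(p + q, rep(1, 3), tolerance = 1e-12)
  # very large willingness to pay: the QALY sign decides
  expect_equal(ceac(draws, 1e12)$prob_cost_effective,
               mean(draws$delta_qalys > 0))
})

test_that("ceac rejects empty input", {
  expect_error(ceac(data.frame(delta_cost = numeric(0),
                               delta_qalys = numeric(0))), "non-empty")
})
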