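# Frozen printed source values for the packaged fixtures, asserted field by
# field in the fixture-fidelity tests. Layout: one row per (population,
# treatment, stage) efficacy entry, plus scalar tables.

published_efficacy <- data.frame(
  population = rep(c("conventional_care_failure", "tnf_failure"), each = 4),
  treatment = c("ustekinumab", "ustekinumab", "adalimumab", "adalimumab",
                "ustekinumab", "ustekinumab", "vedolizumab", "vedolizumab"),
  stage = rep(c("first", "second"), 4),
  response = c(0.555, 0.649, 0.548, 0.430, 0.337, 0.411, 0.327, 0.160),
  remission = c(0.349, 0.449, 0.456, 0.280, 0.185, 0.184, 0.129, 0.068),
  stringsAsFactors = FALSE
)

published_state_costs <- list(
  direct = c(remission = 26L, mild = 69L, moderate_severe = 108L,
             surgery = 7123L),
  indirect = c(remission = 79L, mild = 281L, moderate_severe = 374L,
               surgery = 1326L)
)

published_utilities <- c(remission = 0.80, mild = 0.68, moderate_severe = 0.55,
                         surgery = 0.55)

published_disutilities <- c(serious_infection = -0.52, tuberculosis = -0.55,
                            lymphoma = -0.20, hypersensitivity = -0.11,
                            skin_reaction = -0.03)

published_ae_rates <- list(
  ustekinumab = c(serious_infection = 0.0034, tuberculosis = 0, lymphoma = 0,
                  hypersensitivity = 0.0001, skin_reaction = 0.0075),
  adalimumab = c(serious_infection = 0.0032, tuberculosis = 0, lymphoma = 0,
                 hypersensitivity = 0, skin_reaction = 0.1037),
  vedolizumab = c(serious_infection = 0.0032, tuberculosis = 0, lymphoma = 0,
                  hypersensitivity = 0, skin_reaction = 0.0059)
)

published_discontinuation <- list(
  ustekinumab = c(standard = 0.106, escalated = 0.114),
  adalimumab = c(standard = 0.081, escalated = 0.081),
  vedolizumab = c(standard = 0.377, escalated = 0.312)
)

published_drug_prices <- c(ustekinumab = 3546, adalimumab = 533,
                           vedolizumab = 2334)

published_populations <- list(
  conventional_care_failure = list(mean_age = 39.2, proportion_female = 0.529,
                                   weight_bands = c(0.194, 0.597, 0.209),
                                   gamma = 0.047),
  tnf_failure = list(mean_age = 37.3, proportion_female = 0.572,
                     weight_bands = c(0.229, 0.588, 0.184),
                     gamma = 0.060)
)

# raw fixture document (pre-validation), for field-exactness checks before
# any internal renormalisation
read_raw_fixture <- function(population) {
  fname <- switch(population,
                  conventional_care_failure = "conventional_care.yaml",
                  tnf_failure = "tnf_failure.yaml")
  yaml::read_yaml(system.file("extdata", fname, package = "cdcem"))
}

# minimal strategy/trace stubs for unit-testing the accrual arithmetic in
# isolation from the engine
make_stub_induction <- function(arm = "intervention", duration_weeks = 0) {
  structure(list(
    arm = arm, treatment = "stub",
    distribution = list(biologic = c(remission = 0, mild = 0,
                                     moderate_severe = 1),
                        soc_moderate_severe = 0, surgery = 0),
    to_soc_fraction = 0,
    costs = c(drug = 0, administration = 0, health_state = 0, indirect = 0,
              adverse_event = 0),
    qalys = 0, duration_weeks = duration_weeks,
    first_assessment_week = duration_weeks
  ), class = "cdcem_induction")
}

make_stub_trace <- function(state_label, n_cycles, arm = "intervention",
                            induction_weeks = 0) {
  es <- expanded_states()
  occ <- matrix(0, n_cycles + 1, nrow(es), dimnames = list(NULL, es$state))
  occ[, state_label] <- 1
  structure(list(occupancy = occ, age = rep(40, n_cycles + 1),
                 week = induction_weeks + (0:n_cycles) * 2,
                 n_cycles = n_cycles, switch_cycle = n_cycles + 1L,
                 induction_weeks = induction_weeks, arm = arm),
            class = "cdcem_trace")
}

.as_matrix_cmp <- function(x) unname(cdcem:::.as_matrix3(x))

# independent oracle: element-wise propagation with explicit loops, no
# shared code with calibration_objective
oracle_objective <- function(m, start, target_rem, target_mild, n_cycles) {
  v <- start
  for (cyc in seq_len(n_cycles)) {
    nxt <- numeric(3)
    for (j in 1:3) {
      acc <- 0
      for (i in 1:3) acc <- acc + v[i] * m[i, j]
      nxt[j] <- acc
    }
    v <- nxt
  }
  (v[1] - target_rem)^2 + (v[2] - target_mild)^2
}

random_row_stochastic <- function() {
  m <- matrix(stats::runif(9), 3, 3)
  m / rowSums(m)
}

# rebuild a validated input object after targeted low-level edits
tweak_inputs <- function(inputs, edit) {
  x <- unclass(inputs)
  x <- edit(x)
  as_model_inputs(x)
}

# a published-style scenario with every stochastic event switched off, so the
# cohort admits closed-form behaviour
eventless_inputs <- function(horizon_years = 2) {
  tweak_inputs(published_baseline_inputs("conventional_care_failure"), function(x) {
    x$structural$horizon_years <- horizon_years
    x$structural$treatment_duration_years <- horizon_years
    x$structural$annual_surgery_prob <- 0
    x$structural$induction_surgery_prob <- 0
    x$structural$allow_dose_escalation <- FALSE
    for (arm in c("intervention", "comparator")) {
      x$treatments[[arm]]$discontinuation_cycle_prob_standard <- 0
      x$treatments[[arm]]$discontinuation_cycle_prob_escalated <- 0
      x$treatments[[arm]]$escalation_cycle_prob <- 0
    }
    x$unpublished$mortality_table$cycle_prob <-
      0 * x$unpublished$mortality_table$cycle_prob
    x
  })
}

# a valid small input set with every price and tariff set to zero
zero_cost_inputs <- function(base) {
  x <- unclass(base)
  for (arm in c("intervention", "comparator")) {
    x$treatments[[arm]]$drug$pack_cost <- 0
  }
  x$costs$iv_admin <- 0
  x$costs$sc_inhospital_admin <- 0
  x$costs$soc_drug_cost_2wk <- 0
  x$costs$surgery_complication_cost <- 0
  for (fld in c("state_direct_2wk", "state_indirect_2wk", "ae_unit_costs")) {
    x$costs[[fld]] <- lapply(x$costs[[fld]], function(v) 0)
  }
  as_model_inputs(x)
}
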