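#' Discount factor at an annual rate
#'
#' @param time_years Time from model entry, in years.
#' @param annual_rate Annual discount rate (>= 0).
#' @return `(1 + annual_rate)^(-time_years)`.
#' @export
#' @examples
#' discount_factor(1, 0.03)
discount_factor <- function(time_years, annual_rate) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-time_years)
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Societal-perspective accrual per cycle on start-of-cycle occupancy (no
#' half-cycle correction unless `structural$half_cycle_correction` is set, in
#' which case the mean of start- and end-of-cycle occupancy is used): drug
#' acquisition pro-rated over the dosing interval (escalated patients at the
#' escalation cost multiplier), standard-of-care drug for patients off
#' biologic and concomitantly for a fraction of biologic patients;
#' administration occasions for intravenous maintenance regimens, lumped at
#' dosing cycles; health-state direct and indirect (productivity) costs per
#' 2-week tariff; adverse-event costs and utility decrements on biologic
#' occupancy at per-cycle event rates; surgical complication costs on
#' surgery-state occupancy; QALYs as occupancy times state utility times
#' cycle length, death excluded. Everything is discounted at the cycle's
#' time from model entry; the induction-phase components are added at the
#' midpoint of the induction period.
#'
#' @param trace A [run_maintenance()] trace.
#' @param induction_result The matching [run_induction()] result.
#' @param inputs A `cdcem_inputs` object.
#' @return Object of class `cdcem_strategy` with the discounted cost
#'   components, total cost and total QALYs.
#' @export
accumulate_strategy <- function(trace, induction_result, inputs) {
  stopifnot(inherits(trace, "cdcem_trace"),
            inherits(induction_result, "cdcem_induction"),
            inherits(inputs, "cdcem_inputs"))
  if (trace$arm != induction_result$arm) {
    stop("trace and induction result come from different arms", call. = FALSE)
  }
  s <- inputs$structural
  trt <- inputs$treatments[[trace$arm]]
  costs <- inputs$costs
  util <- inputs$utilities
  es <- expanded_states()
  cdai <- health_states("cdai")

  n <- trace$n_cycles
  occ <- trace$occupancy
  occ_start <- occ[seq_len(n), , drop = FALSE]
  if (isTRUE(s$half_cycle_correction)) {
    occ_start <- (occ_start + occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  }

  scale <- s$cycle_length_weeks / 2  # state tariffs are per 2 weeks
  cyc_yr <- s$cycle_length_weeks * 7 / 365.25

  col_of <- function(status) es$state[!is.na(es$status) & es$status == status]
  on_std <- rowSums(occ_start[, col_of("bio_std"), drop = FALSE])
  on_esc <- rowSums(occ_start[, col_of("bio_esc"), drop = FALSE])
  on_post <- rowSums(occ_start[, col_of("post_bio"), drop = FALSE])
  on_soc <- rowSums(occ_start[, col_of("soc"), drop = FALSE])
  surg <- occ_start[, "surgery"]
  # total occupancy per CDAI state across statuses
  cdai_occ <- vapply(cdai, function(st) {
    rowSums(occ_start[, es$state[!is.na(es$cdai) & es$cdai == st],
                      drop = FALSE])
  }, numeric(n))
  if (n == 1L) cdai_occ <- matrix(cdai_occ, nrow = 1,
                                  dimnames = list(NULL, cdai))

  drug_cycle <- .maintenance_drug_per_cycle(trt, s$cycle_length_weeks)
  soc_cycle <- costs$soc_drug_cost_2wk * scale
  drug <- on_std * drug_cycle +
    on_esc * drug_cycle * trt$escalation_cost_multiplier +
    (on_post + on_soc) * soc_cycle +
    costs$concomitant_soc_fraction * soc_cycle * (on_std + on_esc)

  admin <- numeric(n)
  if (trt$maintenance$route == "IV") {
    k_int <- trt$maintenance$interval_weeks / s$cycle_length_weeks
    biologic <- on_std + on_esc * trt$escalation_cost_multiplier
    if (abs(k_int - round(k_int)) < 1e-9) {
      dose_cycle <- ((seq_len(n) - 1L) %% round(k_int)) == 0
      admin[dose_cycle] <- costs$iv_admin * biologic[dose_cycle]
    } else {
      admin <- costs$iv_admin / k_int * biologic
    }
  }

  sd <- unlist(costs$state_direct_2wk)[cdai]
  si <- unlist(costs$state_indirect_2wk)[cdai]
  direct <- (cdai_occ %*% sd) * scale +
    surg * costs$state_direct_2wk$surgery * scale
  indirect <- if (isTRUE(s$include_indirect_costs)) {
    (cdai_occ %*% si) * scale + surg * costs$state_indirect_2wk$surgery * scale
  } else rep(0, n)

  ae_rates <- unlist(trt$ae_cycle_rates)
  ae_cost_cycle <- 0
  ae_dis_cycle <- 0
  if (length(ae_rates)) {
    unit <- unlist(costs$ae_unit_costs)[names(ae_rates)]
    dis <- unlist(util$ae_disutility)[names(ae_rates)]
    if (anyNA(unit) || anyNA(dis)) {
      stop("adverse event unit costs/disutilities missing for: ",
           paste(names(ae_rates)[is.na(unit) | is.na(dis)], collapse = ", "),
           call. = FALSE)
    }
    ae_cost_cycle <- sum(ae_rates * unit)
    if (isTRUE(s$include_ae_effects)) {
      ae_dis_cycle <- sum(ae_rates * abs(dis))
    }
  }
  ae <- (on_std + on_esc) * ae_cost_cycle

  compl <- surg * inputs$unpublished$surgery_complication_prob *
    costs$surgery_complication_cost

  su <- unlist(util$state)[cdai]
  qalys <- (cdai_occ %*% su) * cyc_yr + surg * util$state$surgery * cyc_yr -
    (on_std + on_esc) * ae_dis_cycle * cyc_yr

  t_years <- (trace$induction_weeks +
                (seq_len(n) - 1L) * s$cycle_length_weeks) * 7 / 365.25
  dfc <- discount_factor(t_years, s$discount_rate_costs)
  dfe <- discount_factor(t_years, s$discount_rate_effects)

  ind_t <- induction_result$duration_weeks / 2 * 7 / 365.25
  ind_dfc <- discount_factor(ind_t, s$discount_rate_costs)
  ind_dfe <- discount_factor(ind_t, s$discount_rate_effects)

  components <- c(
    drug = sum(drug * dfc) + induction_result$costs[["drug"]] * ind_dfc,
    administration = sum(admin * dfc) +
      induction_result$costs[["administration"]] * ind_dfc,
    health_state = sum(direct * dfc) +
      induction_result$costs[["health_state"]] * ind_dfc,
    indirect = sum(indirect * dfc) +
      induction_result$costs[["indirect"]] * ind_dfc,
    adverse_event = sum(ae * dfc) +
      induction_result$costs[["adverse_event"]] * ind_dfc,
    surgery_complication = sum(compl * dfc)
  )

  structure(list(
    arm = trace$arm,
    treatment = trt$name,
    components = components,
    total_cost = sum(components),
    total_qalys = sum(qalys * dfe) + induction_result$qalys * ind_dfe,
    discount_rate_costs = s$discount_rate_costs,
    discount_rate_effects = s$discount_rate_effects,
    horizon_years = s$horizon_years
  ), class = "cdcem_strategy")
}

#' @export
print.cdcem_strategy <- function(x, ...) {
  cat("<cdcem_strategy>", x$treatment, "\n")
  cat(sprintf("  total cost: %0.0f; QALYs: %0.3f\n", x$total_cost,
              x$total_qalys))
  print(round(x$components))
  invisible(x)
}

#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes the cost and QALY increments (intervention minus comparator) and
#' classifies the result: the intervention dominates when it is cheaper and
#' more effective, is dominated when dearer and less effective, and
#' otherwise an incremental cost-effectiveness ratio (ICER) is reported.
#' The ICER is undefined when the QALY increment is numerically zero.
#'
#' @param intervention,comparator `cdcem_strategy` results computed under
#'   identical discount settings and horizon (enforced).
#' @return Object of class `cdcem_incremental` with `delta_cost`,
#'   `delta_qalys`, `icer` (NA when not reported) and `classification`.
#' @export
#' @examples
#' a <- structure(list(treatment = "A", total_cost = 232225,
#'                     total_qalys = 14.275, discount_rate_costs = 0.03,
#'                     discount_rate_effects = 0.03, horizon_years = 60),
#'                class = "cdcem_strategy")
#' b <- structure(list(treatment = "B", total_cost = 239209,
#'                     total_qalys = 14.043, discount_rate_costs = 0.03,
#'                     discount_rate_effects = 0.03, horizon_years = 60),
#'                class = "cdcem_strategy")
#' incremental_analysis(a, b)
incremental_analysis <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "cdcem_strategy"),
            inherits(comparator, "cdcem_strategy"))
  same <- isTRUE(all.equal(intervention$discount_rate_costs,
                           comparator$discount_rate_costs)) &&
    isTRUE(all.equal(intervention$discount_rate_effects,
                     comparator$discount_rate_effects)) &&
    isTRUE(all.equal(intervention$horizon_years, comparator$horizon_years))
  if (!same) {
    stop("strategies were run under different discount settings or horizon; ",
         "refusing to compare", call. = FALSE)
  }
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  if (dq > 0 && dc < 0) {
    cls <- "intervention_dominates"
    icer <- NA_real_
    note <- sprintf("%s dominates %s (cheaper and more effective)",
                    intervention$treatment, comparator$treatment)
  } else if (dq < 0 && dc > 0) {
    cls <- "comparator_dominates"
    icer <- NA_real_
    note <- sprintf("%s is dominated by %s", intervention$treatment,
                    comparator$treatment)
  } else if (abs(dq) < 1e-12) {
    cls <- "icer_reported"
    icer <- NA_real_
    note <- "ICER undefined: QALY increment is numerically zero"
  } else {
    cls <- "icer_reported"
    icer <- dc / dq
    note <- sprintf("ICER %0.0f per QALY", icer)
  }
  structure(list(intervention = intervention$treatment,
                 comparator = comparator$treatment,
                 delta_cost = dc, delta_qalys = dq, icer = icer,
                 classification = cls, note = note),
            class = "cdcem_incremental")
}

#' @export
print.cdcem_incremental <- function(x, ...) {
  cat("<cdcem_incremental>", x$intervention, "vs", x$comparator, "\n")
  cat(sprintf("  delta cost: %0.0f; delta QALYs: %0.3f\n",
              x$delta_cost, x$delta_qalys))
  cat(" ", x$note, "\n")
  invisible(x)
}
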