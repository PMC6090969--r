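#' Split induction responders across the CDAI states
#'
#' At an induction response assessment the cohort divides according to the
#' remission rate `alpha`, the response rate `beta`, and the fraction `gamma`
#' of responders who respond while remaining in the moderate-to-severe
#' state: remission `alpha`; mild `beta - (alpha + beta * gamma)`;
#' moderate-severe `beta * gamma`; non-response `1 - beta`.
#'
#' @param alpha Remission probability (remitters are a subset of responders,
#'   so `alpha <= beta`).
#' @param beta Response probability.
#' @param gamma Fraction of responders remaining moderate-to-severe.
#' @return Named numeric vector `(remission, mild, moderate_severe,
#'   non_response)` summing to 1.
#' @export
#' @examples
#' induction_transition_split(alpha = 0.349, beta = 0.555, gamma = 0.047)
induction_transition_split <- function(alpha, beta, gamma) {
  stopifnot(alpha >= 0, beta <= 1, gamma >= 0, gamma <= 1)
  if (alpha > beta) {
    stop("remission rate alpha exceeds response rate beta: remitters are a ",
         "subset of responders", call. = FALSE)
  }
  mild <- beta - (alpha + beta * gamma)
  if (mild < -1e-12) {
    stop(sprintf(paste0("infeasible induction split: beta - (alpha + beta*gamma) ",
                        "= %.6f < 0; remission plus the moderate-to-severe ",
                        "remainder exceeds the response rate"), mild),
         call. = FALSE)
  }
  out <- c(remission = alpha, mild = max(mild, 0),
           moderate_severe = beta * gamma, non_response = 1 - beta)
  out / sum(out) * 1  # components already sum to 1 analytically
}

.admin_unit_cost <- function(route, costs) {
  switch(route, IV = costs$iv_admin, SC = costs$sc_inhospital_admin,
         stop("unknown administration route: ", route, call. = FALSE))
}

# expected milligrams for one induction stage (weight-banded or fixed doses)
.stage_mg <- function(stage, weight_bands) {
  if (!is.null(stage$weight_band_mg)) {
    sum(unlist(stage$weight_band_mg) * weight_bands) * length(stage$weeks)
  } else {
    sum(unlist(stage$doses_mg))
  }
}

.per_mg_cost <- function(drug) {
  if (!is.null(drug$per_mg_cost)) drug$per_mg_cost else drug$pack_cost / drug$pack_mg
}

# per 2-week-cycle maintenance drug acquisition cost (pro-rated over the
# dosing interval; administration occasions are costed separately, lumped)
.maintenance_drug_per_cycle <- function(trt, cycle_weeks = 2) {
  dose_cost <- .per_mg_cost(trt$drug) * trt$maintenance$dose_mg
  dose_cost / (trt$maintenance$interval_weeks / cycle_weeks)
}

#' Run the induction-phase decision tree for one strategy arm
#'
#' All patients enter in the moderate-to-severe state and receive the first
#' induction dose. At the first assessment, responders split across the CDAI
#' states via [induction_transition_split()] and move to maintenance dosing;
#' non-responders receive the second induction dose and are re-assessed, with
#' second-dose responders splitting the same way and the remaining
#' non-responders routed to non-biologic standard of care. A one-off
#' induction surgery probability is then applied proportionally across all
#' states. Costs (drug, administration, health-state, indirect, adverse
#' event) and QALYs accrue undiscounted over the induction weeks: everyone at
#' the moderate-to-severe rate until their assessment, first-dose responders
#' thereafter at their achieved-state rates (plus maintenance drug cost)
#' until the arm's final assessment, when the maintenance phase begins for
#' the whole cohort.
#'
#' @param inputs A `cdcem_inputs` object.
#' @param arm `"intervention"` or `"comparator"`.
#' @return Object of class `cdcem_induction`: the start-of-maintenance
#'   distribution (biologic CDAI masses, standard-of-care mass, surgery
#'   mass), `to_soc_fraction`, the undiscounted induction cost breakdown,
#'   induction QALYs and the induction duration in weeks.
#' @export
run_induction <- function(inputs, arm = c("intervention", "comparator")) {
  stopifnot(inherits(inputs, "cdcem_inputs"))
  arm <- match.arg(arm)
  trt <- inputs$treatments[[arm]]
  crit <- inputs$structural$response_criterion
  eff <- trt$efficacy[[crit]]
  if (is.null(eff)) stop("no efficacy set for criterion ", crit, call. = FALSE)
  gamma <- inputs$population$gamma_mod_sev_remainder
  costs <- inputs$costs
  util <- inputs$utilities

  split1 <- induction_transition_split(eff$first$remission,
                                       eff$first$response, gamma)
  split2 <- induction_transition_split(eff$second$remission,
                                       eff$second$response, gamma)
  beta1 <- eff$first$response
  nonresp1 <- split1[["non_response"]]
  to_soc <- nonresp1 * split2[["non_response"]]

  cdai <- health_states("cdai")
  bio <- split1[cdai] + nonresp1 * split2[cdai]
  names(bio) <- cdai

  # one-off induction surgery, drawn proportionally from every state
  p_surg <- inputs$structural$induction_surgery_prob
  dist <- list(biologic = bio * (1 - p_surg),
               soc_moderate_severe = to_soc * (1 - p_surg),
               surgery = p_surg)

  d1 <- trt$induction$first_assessment_week
  d2 <- trt$induction$second_assessment_week
  cyc_wk <- inputs$structural$cycle_length_weeks
  wk_to_yr <- 7 / 365.25

  per_mg <- .per_mg_cost(trt$drug)
  wb <- inputs$population$weight_bands
  drug <- per_mg * .stage_mg(trt$induction$first, wb) +
    nonresp1 * per_mg * .stage_mg(trt$induction$second, wb)
  admin <- length(trt$induction$first$weeks) *
    .admin_unit_cost(trt$induction$first$route, costs) +
    nonresp1 * length(trt$induction$second$weeks) *
      .admin_unit_cost(trt$induction$second$route, costs)

  # bridge period: first-dose responders are on maintenance dosing between
  # the two assessments; pro-rated drug plus (for IV regimens) administration
  bridge_cycles <- (d2 - d1) / cyc_wk
  resp_mass <- sum(split1[cdai])
  drug <- drug + resp_mass * .maintenance_drug_per_cycle(trt, cyc_wk) *
    bridge_cycles
  if (trt$maintenance$route == "IV" && bridge_cycles > 0) {
    admin <- admin + resp_mass * costs$iv_admin *
      (d2 - d1) / trt$maintenance$interval_weeks
  }
  # concomitant standard of care alongside biologic treatment
  drug <- drug + costs$concomitant_soc_fraction * costs$soc_drug_cost_2wk *
    (d2 / cyc_wk)

  sd <- costs$state_direct_2wk
  si <- costs$state_indirect_2wk
  ms_cycles_all <- d1 / cyc_wk
  direct <- sd$moderate_severe * ms_cycles_all +
    bridge_cycles * (sum(split1[cdai] * unlist(sd[cdai])) +
                       nonresp1 * sd$moderate_severe)
  indirect <- si$moderate_severe * ms_cycles_all +
    bridge_cycles * (sum(split1[cdai] * unlist(si[cdai])) +
                       nonresp1 * si$moderate_severe)
  if (!inputs$structural$include_indirect_costs) indirect <- 0

  ae_rates <- unlist(trt$ae_cycle_rates)
  ae_cycles <- d2 / cyc_wk
  ae_cost <- 0
  ae_qaly_loss <- 0
  if (length(ae_rates)) {
    unit <- unlist(costs$ae_unit_costs)[names(ae_rates)]
    dis <- unlist(util$ae_disutility)[names(ae_rates)]
    if (anyNA(unit) || anyNA(dis)) {
      stop("adverse event unit costs/disutilities missing for: ",
           paste(names(ae_rates)[is.na(unit) | is.na(dis)], collapse = ", "),
           call. = FALSE)
    }
    ae_cost <- sum(ae_rates * unit) * ae_cycles
    if (inputs$structural$include_ae_effects) {
      ae_qaly_loss <- sum(ae_rates * abs(dis)) * ae_cycles *
        (cyc_wk * wk_to_yr)
    }
  }

  su <- util$state
  qalys <- su$moderate_severe * d1 * wk_to_yr +
    (d2 - d1) * wk_to_yr * (sum(split1[cdai] * unlist(su[cdai])) +
                              nonresp1 * su$moderate_severe) -
    ae_qaly_loss

  structure(list(
    arm = arm,
    treatment = trt$name,
    distribution = dist,
    to_soc_fraction = unname(to_soc),
    costs = c(drug = unname(drug), administration = unname(admin),
              health_state = unname(direct), indirect = unname(indirect),
              adverse_event = unname(ae_cost)),
    qalys = unname(qalys),
    duration_weeks = d2,
    first_assessment_week = d1
  ), class = "cdcem_induction")
}

#' @export
print.cdcem_induction <- function(x, ...) {
  cat("<cdcem_induction>", x$treatment, "\n")
  cat("  to maintenance (biologic):",
      sprintf("%.4f", sum(x$distribution$biologic)), "\n")
  cat("  to standard of care:", sprintf("%.4f", x$to_soc_fraction), "\n")
  cat("  induction cost (undiscounted):",
      sprintf("%.0f", sum(x$costs)), "\n")
  invisible(x)
}
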