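#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p_annual)^(cycle_weeks / 52)`.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycle_weeks Cycle length in weeks.
#' @return Per-cycle probability.
#' @export
#' @examples
#' annual_to_cycle_probability(0.07, 2)
annual_to_cycle_probability <- function(p_annual, cycle_weeks = 2) {
  stopifnot(p_annual >= 0, p_annual <= 1, cycle_weeks > 0)
  1 - (1 - p_annual)^(cycle_weeks / 52)
}

.mortality_lookup <- function(table, age) {
  i <- match(floor(age), table$age)
  if (is.na(i)) {
    stop(sprintf("mortality table exhausted: no entry for age %.0f", floor(age)),
         call. = FALSE)
  }
  table$cycle_prob[i]
}

# number of maintenance cycles needed to fill the horizon after induction
.maintenance_cycles <- function(structural, induction_weeks) {
  total_weeks <- structural$horizon_years * 365.25 / 7
  max(1L, as.integer(ceiling((total_weeks - induction_weeks) /
                               structural$cycle_length_weeks)))
}

# maintenance cycle index after which treatment stops (counted from model
# entry, so the induction weeks are part of the treatment duration)
.switch_cycle <- function(structural, induction_weeks) {
  dur_weeks <- structural$treatment_duration_years * 365.25 / 7
  max(0L, as.integer(ceiling((dur_weeks - induction_weeks) /
                               structural$cycle_length_weeks)))
}

#' Run the maintenance-phase Markov cohort simulation
#'
#' Propagates the start-of-maintenance cohort over 2-week cycles to the
#' horizon. Within each cycle events apply in a fixed order: (1) background
#' mortality at the cohort's current age, from every alive state; (2) surgery
#' -- last cycle's surgical patients exit to the post-surgery CDAI
#' distribution on standard of care, and a per-cycle surgery probability
#' (converted from the annual rate) draws new patients from every CDAI
#' state; (3) discontinuation for lack of efficacy, applied only to
#' moderate-to-severe patients on biologic at the dose-specific probability,
#' moving them to standard of care; (4) dose escalation (when enabled),
#' moving standard-dose biologic patients to the escalated stratum; (5) CDAI
#' transition by the status-appropriate matrix. At the end of the treatment
#' duration all biologic patients switch to standard-of-care therapy, their
#' transition matrix converging from the biologic to the standard-of-care
#' matrix over the treatment's convergence period via [blend_matrices()].
#'
#' @param induction_result A [run_induction()] result supplying the starting
#'   distribution.
#' @param inputs A `cdcem_inputs` object.
#' @param matrices List with elements `biologic` and `soc` (and optionally
#'   `escalated`, defaulting to `biologic`), each a [transition_matrix()].
#' @return Object of class `cdcem_trace`: per-cycle occupancy over the
#'   expanded state space (rows are cycles 0..N, row sums 1), cohort age and
#'   week stamps, and bookkeeping attributes used by [accumulate_strategy()].
#' @export
run_maintenance <- function(induction_result, inputs, matrices) {
  stopifnot(inherits(induction_result, "cdcem_induction"),
            inherits(inputs, "cdcem_inputs"))
  if (is.null(matrices$biologic) || is.null(matrices$soc)) {
    stop("matrices must provide 'biologic' and 'soc' transition matrices",
         call. = FALSE)
  }
  m_bio <- transition_matrix(matrices$biologic)
  m_soc <- transition_matrix(matrices$soc)
  m_esc <- if (!is.null(matrices$escalated))
    transition_matrix(matrices$escalated) else m_bio

  es <- expanded_states()
  n_states <- nrow(es)
  blk <- lapply(setNames(nm = treatment_statuses()), .status_block)
  i_surg <- .state_index("surgery")
  i_death <- .state_index("death")

  s <- inputs$structural
  trt <- inputs$treatments[[induction_result$arm]]
  u <- inputs$unpublished
  ind_wk <- induction_result$duration_weeks
  n_cycles <- .maintenance_cycles(s, ind_wk)
  s_switch <- .switch_cycle(s, ind_wk)
  conv <- trt$convergence_cycles
  p_surg <- annual_to_cycle_probability(s$annual_surgery_prob,
                                        s$cycle_length_weeks)
  post_surg <- unlist(u$post_surgery_distribution)
  d_std <- trt$discontinuation_cycle_prob_standard
  d_esc <- trt$discontinuation_cycle_prob_escalated
  p_esc <- if (isTRUE(s$allow_dose_escalation)) trt$escalation_cycle_prob else 0
  i_ms <- match("moderate_severe", health_states("cdai"))
  cyc_yr <- s$cycle_length_weeks * 7 / 365.25

  v <- numeric(n_states)
  v[blk$bio_std] <- induction_result$distribution$biologic
  v[blk$soc[i_ms]] <- v[blk$soc[i_ms]] +
    induction_result$distribution$soc_moderate_severe
  v[i_surg] <- induction_result$distribution$surgery
  if (abs(sum(v) - 1) > 1e-9) {
    stop("start-of-maintenance occupancy does not sum to 1", call. = FALSE)
  }

  occ <- matrix(NA_real_, n_cycles + 1L, n_states,
                dimnames = list(NULL, es$state))
  age0 <- inputs$population$mean_age + ind_wk * 7 / 365.25
  ages <- age0 + (0:n_cycles) * cyc_yr
  occ[1, ] <- v

  for (t in seq_len(n_cycles)) {
    # treatment stops: biologic strata become post-treatment strata
    if (t == s_switch + 1L) {
      for (b in c("bio_std", "bio_esc")) {
        v[blk$post_bio] <- v[blk$post_bio] + v[blk[[b]]]
        v[blk[[b]]] <- 0
      }
    }
    # (1) background mortality from every alive state
    q <- .mortality_lookup(u$mortality_table, ages[t])
    alive <- setdiff(seq_len(n_states), i_death)
    v[i_death] <- v[i_death] + q * sum(v[alive])
    v[alive] <- v[alive] * (1 - q)
    # (2) surgery: one-cycle residence, then the post-surgery distribution
    exiting <- v[i_surg]
    cdai_idx <- unlist(blk)
    intake <- sum(v[cdai_idx]) * p_surg
    v[cdai_idx] <- v[cdai_idx] * (1 - p_surg)
    v[i_surg] <- intake
    v[blk$soc] <- v[blk$soc] + exiting * post_surg
    # (3) discontinuation from moderate-to-severe on biologic
    for (pair in list(c("bio_std", d_std), c("bio_esc", d_esc))) {
      i_from <- blk[[pair[[1]]]][i_ms]
      moved <- v[i_from] * as.numeric(pair[[2]])
      v[i_from] <- v[i_from] - moved
      v[blk$soc[i_ms]] <- v[blk$soc[i_ms]] + moved
    }
    # (4) dose escalation
    if (p_esc > 0 && t <= s_switch) {
      moved <- v[blk$bio_std] * p_esc
      v[blk$bio_std] <- v[blk$bio_std] - moved
      v[blk$bio_esc] <- v[blk$bio_esc] + moved
    }
    # (5) CDAI transition by status
    if (t > s_switch && conv > 0 && (t - s_switch) < conv) {
      m_post <- blend_matrices(m_bio, m_soc, (t - s_switch) / conv)
    } else {
      m_post <- m_soc  # convergence complete (or immediate)
    }
    mats <- list(bio_std = m_bio, bio_esc = m_esc, post_bio = m_post,
                 soc = m_soc)
    for (b in names(blk)) {
      v[blk[[b]]] <- drop(matrix(v[blk[[b]]], 1) %*% mats[[b]])
    }

    if (abs(sum(v) - 1) > 1e-9) {
      stop(sprintf("mass conservation violated at cycle %d (sum = %.12f)",
                   t, sum(v)), call. = FALSE)
    }
    occ[t + 1L, ] <- v
  }

  structure(list(
    occupancy = occ,
    age = ages,
    week = ind_wk + (0:n_cycles) * s$cycle_length_weeks,
    n_cycles = n_cycles,
    switch_cycle = s_switch,
    induction_weeks = ind_wk,
    arm = induction_result$arm
  ), class = "cdcem_trace")
}

#' @export
print.cdcem_trace <- function(x, ...) {
  cat("<cdcem_trace>", x$n_cycles, "cycles,",
      ncol(x$occupancy), "expanded states\n")
  cat("  final death occupancy:",
      sprintf("%.4f", x$occupancy[nrow(x$occupancy), "death"]), "\n")
  invisible(x)
}

#' Export a cohort trace as a data frame
#'
#' @param x A `cdcem_trace`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return Wide data frame: one row per cycle, one column per expanded
#'   state, plus `cycle`, `week` and `age`.
#' @export
as.data.frame.cdcem_trace <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(cycle = 0:x$n_cycles, week = x$week, age = x$age,
             x$occupancy, check.names = FALSE, row.names = row.names)
}
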