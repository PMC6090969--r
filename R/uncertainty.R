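#' Define a named scenario as a set of parameter overrides
#'
#' A scenario is a named list of overrides, each keyed by a dotted path into
#' the model input tree (for example `"structural.discount_rate_costs"`).
#' Applying and then reverting a scenario restores the base inputs exactly;
#' overriding a path that does not exist in the base inputs is an error.
#'
#' @param name Scenario label.
#' @param overrides Named list mapping dotted parameter paths to replacement
#'   values (scalar or subtree).
#' @return Object of class `cdcem_scenario`.
#' @export
#' @examples
#' scenario("no discounting", list(structural.discount_rate_costs = 0,
#'                                 structural.discount_rate_effects = 0))
scenario <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1, is.list(overrides))
  if (length(overrides) && is.null(names(overrides))) {
    stop("overrides must be named by parameter path", call. = FALSE)
  }
  structure(list(name = name, overrides = overrides),
            class = "cdcem_scenario")
}

.assign_path <- function(x, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- x
  for (k in seq_along(parts)) {
    if (!is.list(ref) || is.null(ref[[parts[k]]])) {
      stop("unknown override path: ", path, call. = FALSE)
    }
    ref <- ref[[parts[k]]]
  }
  x[[parts]] <- value
  x
}

#' Apply a scenario's overrides to a base input set
#'
#' @param base A `cdcem_inputs` object.
#' @param scn A [scenario()].
#' @return A revalidated `cdcem_inputs` object with the overrides applied.
#' @export
apply_scenario <- function(base, scn) {
  stopifnot(inherits(base, "cdcem_inputs"), inherits(scn, "cdcem_scenario"))
  x <- unclass(base)
  for (path in names(scn$overrides)) {
    x <- .assign_path(x, path, scn$overrides[[path]])
  }
  as_model_inputs(x)
}

#' Load scenario definitions from a structured config file
#'
#' @param path YAML file: a list of entries with `name` and `overrides`.
#' @return List of [scenario()] objects.
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) scenario(e$name, e$overrides))
}

#' Packaged one-way and structural scenario grid
#'
#' The shipped scenario set varies, one at a time: the cost and effect
#' discount rates (0% and 5%, singly and jointly), the time horizon (15 and
#' 5 years), the treatment duration (5 years), exclusion of indirect costs,
#' no dose escalation, doubled moderate-to-severe resource-use cost, the
#' CDAI-70 response criterion, no adverse-event utility effect, and three
#' alternative health-state utility sets.
#'
#' @return List of [scenario()] objects.
#' @export
owsa_scenarios <- function() {
  load_scenarios(system.file("extdata", "scenarios_owsa.yaml",
                             package = "cdcem", mustWork = TRUE))
}

#' Run a one-way / structural sensitivity analysis
#'
#' Runs the full pipeline once per scenario and tabulates the incremental
#' results. A scenario with no overrides reproduces the base-case run
#' bit-for-bit.
#'
#' @param base A `cdcem_inputs` object.
#' @param scenarios List of [scenario()] objects (default: the packaged
#'   grid from [owsa_scenarios()]).
#' @param n_restarts,seed Passed to [run_comparison()].
#' @return Data frame with one row per scenario (`scenario`, `delta_cost`,
#'   `delta_qalys`, `icer`, `classification`); the full comparison objects
#'   are attached as attribute `"comparisons"`.
#' @export
run_owsa <- function(base, scenarios = owsa_scenarios(), n_restarts = 10,
                     seed = 1L) {
  stopifnot(inherits(base, "cdcem_inputs"))
  comparisons <- lapply(scenarios, function(scn) {
    run_comparison(apply_scenario(base, scn), n_restarts = n_restarts,
                   seed = seed)
  })
  out <- do.call(rbind, lapply(seq_along(scenarios), function(i) {
    inc <- comparisons[[i]]$incremental
    data.frame(scenario = scenarios[[i]]$name, delta_cost = inc$delta_cost,
               delta_qalys = inc$delta_qalys, icer = inc$icer,
               classification = inc$classification,
               stringsAsFactors = FALSE)
  }))
  attr(out, "comparisons") <- comparisons
  out
}

#' Net monetary benefit
#'
#' `wtp * delta_qalys - delta_cost`; positive values mean the intervention
#' is cost-effective at that willingness to pay.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qalys Incremental QALYs.
#' @param wtp Willingness to pay per QALY (vectorised).
#' @return Net monetary benefit, same length as `wtp`.
#' @export
#' @examples
#' nmb(4023, 0.133, 63000)
nmb <- function(delta_cost, delta_qalys, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_qalys - delta_cost
}

# method-of-moments beta draw around a mean; SE capped below the
# feasibility bound so the parameterisation always exists
.rbeta_mom <- function(mean, se) {
  if (se <= 0 || mean <= 0 || mean >= 1) return(mean)
  se <- min(se, 0.9 * sqrt(mean * (1 - mean)))
  nu <- mean * (1 - mean) / se^2 - 1
  stats::rbeta(1, mean * nu, (1 - mean) * nu)
}

.rgamma_mom <- function(mean, se) {
  if (se <= 0 || mean <= 0) return(mean)
  stats::rgamma(1, shape = (mean / se)^2, rate = mean / se^2)
}

.rdirichlet_conc <- function(p, conc) {
  drop_zero <- p <= 0
  a <- p * conc
  g <- ifelse(drop_zero, 0, stats::rgamma(length(a), shape = a, rate = 1))
  g / sum(g)
}

# lognormal draw on the odds scale, mapped back to a probability
.rprob_logodds <- function(p, sdlog) {
  if (sdlog <= 0 || p <= 0 || p >= 1) return(p)
  odds <- exp(stats::rnorm(1, log(p / (1 - p)), sdlog))
  odds / (1 + odds)
}

#' Draw one probabilistic-sensitivity-analysis input set
#'
#' Samples the uncertain parameters around their base values using standard
#' health-economic distribution families: beta for probabilities and
#' utilities (method of moments from mean and SE), gamma for costs,
#' Dirichlet for transition-matrix rows and target distributions, lognormal
#' on the odds scale for efficacy rates. The relative SE defaults to 10% of
#' the mean. Draws violating an input invariant (for example remission
#' exceeding response) are rejected and redrawn, up to a bounded number of
#' retries. Uses the current RNG state; with `rel_se = 0` the base inputs
#' are returned unchanged.
#'
#' @param base A `cdcem_inputs` object.
#' @param rel_se Relative standard error applied to every sampled parameter.
#' @param max_retries Redraw budget for invariant violations.
#' @return A validated `cdcem_inputs` draw.
#' @export
draw_psa_inputs <- function(base, rel_se = 0.1, max_retries = 50L) {
  stopifnot(inherits(base, "cdcem_inputs"), rel_se >= 0)
  if (rel_se == 0) return(base)
  for (attempt in seq_len(max_retries)) {
    draw <- tryCatch(as_model_inputs(.draw_once(unclass(base), rel_se)),
                     error = function(e) NULL)
    if (!is.null(draw)) return(draw)
  }
  stop("PSA redraw budget exhausted: could not produce a valid draw in ",
       max_retries, " attempts", call. = FALSE)
}

.draw_once <- function(x, rel_se) {
  gamma_pop <- x$population$gamma_mod_sev_remainder
  x$population$gamma_mod_sev_remainder <-
    .rbeta_mom(gamma_pop, rel_se * gamma_pop)

  for (st in names(x$utilities$state)) {
    m <- x$utilities$state[[st]]
    x$utilities$state[[st]] <- .rbeta_mom(m, rel_se * m)
  }
  # surgery utility tied to moderate-severe in the base case stays tied
  for (fld in c("state_direct_2wk", "state_indirect_2wk", "ae_unit_costs")) {
    for (st in names(x$costs[[fld]])) {
      m <- x$costs[[fld]][[st]]
      x$costs[[fld]][[st]] <- .rgamma_mom(m, rel_se * m)
    }
  }
  m <- x$costs$soc_drug_cost_2wk
  x$costs$soc_drug_cost_2wk <- .rgamma_mom(m, rel_se * m)
  m <- x$costs$surgery_complication_cost
  x$costs$surgery_complication_cost <- .rgamma_mom(m, rel_se * m)

  for (arm in c("intervention", "comparator")) {
    trt <- x$treatments[[arm]]
    for (set_name in names(trt$efficacy)) {
      for (stage in c("first", "second")) {
        e <- trt$efficacy[[set_name]][[stage]]
        beta <- .rprob_logodds(e$response, rel_se)
        alpha <- .rprob_logodds(e$remission, rel_se)
        trt$efficacy[[set_name]][[stage]] <-
          list(response = beta, remission = alpha)
      }
    }
    for (fld in c("discontinuation_cycle_prob_standard",
                  "discontinuation_cycle_prob_escalated",
                  "escalation_cycle_prob")) {
      trt[[fld]] <- .rbeta_mom(trt[[fld]], rel_se * trt[[fld]])
    }
    if (!is.null(trt$ae_cycle_rates)) {
      for (ev in names(trt$ae_cycle_rates)) {
        r <- trt$ae_cycle_rates[[ev]]
        trt$ae_cycle_rates[[ev]] <- .rbeta_mom(r, rel_se * r)
      }
    }
    x$treatments[[arm]] <- trt
  }

  conc <- 1 / rel_se^2  # Dirichlet concentration matched to the relative SE
  soc <- .as_matrix3(x$unpublished$soc_transition_matrix)
  for (i in 1:3) soc[i, ] <- .rdirichlet_conc(soc[i, ], conc)
  x$unpublished$soc_transition_matrix <- soc
  ps <- unlist(x$unpublished$post_surgery_distribution)
  x$unpublished$post_surgery_distribution <- .rdirichlet_conc(ps, conc)
  for (trt_name in names(x$unpublished$maintenance_targets)) {
    tg <- x$unpublished$maintenance_targets[[trt_name]]
    d <- .rdirichlet_conc(c(tg$remission, tg$mild,
                            max(1 - tg$remission - tg$mild, 0)), conc)
    x$unpublished$maintenance_targets[[trt_name]] <-
      list(remission = d[1], mild = d[2])
  }
  p <- x$unpublished$surgery_complication_prob
  x$unpublished$surgery_complication_prob <- .rbeta_mom(p, rel_se * p)
  x
}

#' Run a probabilistic sensitivity analysis
#'
#' Repeats the full pipeline `n_iterations` times with inputs drawn by
#' [draw_psa_inputs()], recording the incremental cost and QALYs of each
#' iteration. Each iteration uses a deterministically derived substream of
#' the master seed, so the analysis is exactly reproducible from
#' `(seed, n_iterations, rel_se)`.
#'
#' @param base A `cdcem_inputs` object.
#' @param n_iterations Number of iterations.
#' @param seed Master integer seed.
#' @param rel_se Relative SE of the sampled parameters.
#' @param n_restarts Calibration restarts per iteration (kept small: each
#'   iteration re-calibrates the maintenance matrices for its draw).
#' @return Object of class `cdcem_psa`: data frame `draws` with one row per
#'   iteration (`delta_cost`, `delta_qalys`, per-arm totals), plus the seed
#'   and settings.
#' @export
run_psa <- function(base, n_iterations = 1000, seed = 1L, rel_se = 0.1,
                    n_restarts = 2) {
  stopifnot(inherits(base, "cdcem_inputs"), n_iterations >= 1)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    sub_seed <- (as.numeric(seed) * 10007 + i) %% 2147483647
    drawn <- .with_seed(sub_seed, draw_psa_inputs(base, rel_se = rel_se))
    cmp <- run_comparison(drawn, n_restarts = n_restarts, seed = sub_seed)
    inc <- cmp$incremental
    rows[[i]] <- data.frame(
      iteration = i,
      delta_cost = inc$delta_cost,
      delta_qalys = inc$delta_qalys,
      cost_intervention = cmp$intervention$result$total_cost,
      qalys_intervention = cmp$intervention$result$total_qalys,
      cost_comparator = cmp$comparator$result$total_cost,
      qalys_comparator = cmp$comparator$result$total_qalys
    )
  }
  structure(list(draws = do.call(rbind, rows), seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations), rel_se = rel_se),
            class = "cdcem_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations with
#' strictly positive net monetary benefit (a zero benefit counts as not
#' cost-effective).
#'
#' @param psa A [run_psa()] result, or any list with a `draws` data frame
#'   holding `delta_cost` and `delta_qalys`.
#' @param wtp_grid Willingness-to-pay grid (default 0 to 200,000 in steps of
#'   1,000, which includes the 63,000 reference value exactly).
#' @return Data frame with `wtp` and `prob_cost_effective` in \[0, 1\].
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 1000)) {
  draws <- if (is.data.frame(psa)) psa else psa$draws
  if (is.null(draws) || nrow(draws) == 0 || length(wtp_grid) == 0) {
    stop("ceac needs non-empty PSA draws and a non-empty WTP grid",
         call. = FALSE)
  }
  prob <- vapply(wtp_grid, function(w) {
    mean(nmb(draws$delta_cost, draws$delta_qalys, w) > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}
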