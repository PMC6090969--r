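#' @importFrom stats setNames
NULL

# ---- validation machinery ---------------------------------------------------

# collects failures so a bad document reports every problem at once
.check <- function(failures, ok, path, msg) {
  if (!isTRUE(ok)) failures <- c(failures, sprintf("%s: %s", path, msg))
  failures
}

.is_prob <- function(x) is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
  all(x >= 0) && all(x <= 1)

.is_nonneg <- function(x) is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
  all(x >= 0)

.has <- function(x, field) !is.null(x[[field]])

.require_fields <- function(failures, x, fields, path) {
  for (f in fields) {
    if (!.has(x, f)) {
      failures <- c(failures, sprintf("%s.%s: required field missing", path, f))
    }
  }
  failures
}

# ---- constructors -----------------------------------------------------------

#' Construct and validate a full model input set
#'
#' Bundles the population, structural settings, costs, utilities and the two
#' treatment strategies (intervention and comparator) into a validated input
#' object. Fields that the published tables do not provide (standard-of-care
#' transition matrix, post-surgery destination distribution, background
#' mortality, end-of-maintenance calibration targets, surgical complication
#' probability) live in the `unpublished` component; when absent they are
#' filled from the deterministic synthetic defaults of
#' [generate_unpublished_inputs()] and flagged with `"synthetic"` provenance.
#'
#' @param x Named list mirroring the configuration document schema (see the
#'   packaged fixtures under `inst/extdata/` for the layout).
#' @return Object of class `cdcem_inputs`.
#' @seealso [load_model_inputs()], [published_baseline_inputs()]
#' @export
as_model_inputs <- function(x) {
  stopifnot(is.list(x))
  f <- character(0)
  f <- .require_fields(f, x, c("population", "structural", "costs",
                               "utilities", "treatments"), "inputs")
  if (length(f)) stop(.validation_message(f), call. = FALSE)

  f <- .validate_population(f, x$population)
  f <- .validate_structural(f, x$structural)
  f <- .validate_costs(f, x$costs)
  f <- .validate_utilities(f, x$utilities)
  f <- .validate_treatments(f, x$treatments, x$structural,
                            x$population$gamma_mod_sev_remainder)

  if (is.null(x$unpublished)) {
    trt <- vapply(x$treatments, function(t) t$name, character(1))
    x$unpublished <- generate_unpublished_inputs(synthetic_spec(
      population = x$population$name, treatments = unname(trt)))
    x$provenance <- unique(c(x$provenance, "unpublished"))
  }
  f <- .validate_unpublished(f, x$unpublished, x$treatments)

  if (length(f)) stop(.validation_message(f), call. = FALSE)

  # weight bands are printed as rounded percentages; renormalise internally
  wb <- x$population$weight_bands
  x$population$weight_bands <- wb / sum(wb)
  # canonical representation for the post-surgery destinations (documents may
  # carry them as a map or a bare sequence over the CDAI states)
  x$unpublished$post_surgery_distribution <-
    setNames(unlist(x$unpublished$post_surgery_distribution),
             health_states("cdai"))

  structure(x, class = "cdcem_inputs")
}

.validation_message <- function(failures) {
  paste0("invalid model inputs:\n", paste0("  - ", failures, collapse = "\n"))
}

.validate_population <- function(f, p, path = "population") {
  n0 <- length(f)
  f <- .require_fields(f, p, c("name", "mean_age", "proportion_female",
                               "weight_bands", "gamma_mod_sev_remainder"), path)
  if (length(f) > n0) return(f)
  f <- .check(f, is.character(p$name) && nzchar(p$name), paste0(path, ".name"),
              "must be a non-empty string")
  f <- .check(f, is.numeric(p$mean_age) && p$mean_age > 0 && p$mean_age < 110,
              paste0(path, ".mean_age"), "must be in (0, 110) years")
  f <- .check(f, .is_prob(p$proportion_female), paste0(path, ".proportion_female"),
              "must be a probability in [0, 1]")
  wb <- p$weight_bands
  f <- .check(f, is.numeric(wb) && length(wb) == 3 && all(wb >= 0) && all(wb <= 1),
              paste0(path, ".weight_bands"),
              "must be three fractions in [0, 1] for (<55, 56-84, >85 kg)")
  if (is.numeric(wb) && length(wb) == 3) {
    # tolerance 0.005 admits published percentages rounded to one decimal
    f <- .check(f, abs(sum(wb) - 1) <= 0.005, paste0(path, ".weight_bands"),
                sprintf("weight_bands sum != 1 (got %.4f)", sum(wb)))
  }
  f <- .check(f, .is_prob(p$gamma_mod_sev_remainder),
              paste0(path, ".gamma_mod_sev_remainder"),
              "must be a probability in [0, 1]")
  f
}

.validate_structural <- function(f, s, path = "structural") {
  n0 <- length(f)
  f <- .require_fields(f, s, c("cycle_length_weeks", "horizon_years",
                               "treatment_duration_years", "discount_rate_costs",
                               "discount_rate_effects", "induction_surgery_prob",
                               "annual_surgery_prob", "response_criterion",
                               "include_indirect_costs", "include_ae_effects",
                               "allow_dose_escalation", "wtp_reference"), path)
  if (length(f) > n0) return(f)
  f <- .check(f, is.numeric(s$cycle_length_weeks) && s$cycle_length_weeks > 0,
              paste0(path, ".cycle_length_weeks"), "must be positive")
  f <- .check(f, is.numeric(s$horizon_years) && s$horizon_years > 0,
              paste0(path, ".horizon_years"), "must be positive")
  f <- .check(f, is.numeric(s$treatment_duration_years) &&
                s$treatment_duration_years >= 0,
              paste0(path, ".treatment_duration_years"), "must be non-negative")
  if (is.numeric(s$horizon_years) && is.numeric(s$treatment_duration_years)) {
    f <- .check(f, s$horizon_years >= s$treatment_duration_years,
                paste0(path, ".horizon_years"),
                "horizon must cover the treatment duration")
  }
  for (fld in c("discount_rate_costs", "discount_rate_effects")) {
    f <- .check(f, is.numeric(s[[fld]]) && s[[fld]] >= 0,
                paste0(path, ".", fld), "must be a non-negative rate")
  }
  for (fld in c("induction_surgery_prob", "annual_surgery_prob")) {
    f <- .check(f, .is_prob(s[[fld]]), paste0(path, ".", fld),
                "must be a probability in [0, 1]")
  }
  f <- .check(f, s$response_criterion %in% c("CDAI100", "CDAI70"),
              paste0(path, ".response_criterion"),
              "must be one of CDAI100, CDAI70")
  for (fld in c("include_indirect_costs", "include_ae_effects",
                "allow_dose_escalation")) {
    f <- .check(f, is.logical(s[[fld]]) && length(s[[fld]]) == 1,
                paste0(path, ".", fld), "must be a single logical flag")
  }
  f <- .check(f, .is_nonneg(s$wtp_reference), paste0(path, ".wtp_reference"),
              "must be a non-negative money amount")
  f
}

.validate_costs <- function(f, cst, path = "costs") {
  n0 <- length(f)
  f <- .require_fields(f, cst, c("iv_admin", "sc_inhospital_admin",
                                 "state_direct_2wk", "state_indirect_2wk",
                                 "concomitant_soc_fraction", "soc_drug_cost_2wk",
                                 "surgery_complication_cost", "ae_unit_costs"),
                       path)
  if (length(f) > n0) return(f)
  state_cost_names <- c("remission", "mild", "moderate_severe", "surgery")
  for (fld in c("state_direct_2wk", "state_indirect_2wk")) {
    v <- cst[[fld]]
    f <- .check(f, is.list(v) && all(state_cost_names %in% names(v)),
                paste0(path, ".", fld),
                "must name remission, mild, moderate_severe and surgery")
    if (is.list(v)) {
      f <- .check(f, .is_nonneg(unlist(v)), paste0(path, ".", fld),
                  "all state costs must be non-negative")
    }
  }
  for (fld in c("iv_admin", "sc_inhospital_admin", "soc_drug_cost_2wk",
                "surgery_complication_cost")) {
    f <- .check(f, .is_nonneg(cst[[fld]]), paste0(path, ".", fld),
                "must be non-negative")
  }
  f <- .check(f, .is_prob(cst$concomitant_soc_fraction),
              paste0(path, ".concomitant_soc_fraction"),
              "must be a fraction in [0, 1]")
  f <- .check(f, is.list(cst$ae_unit_costs) &&
                .is_nonneg(unlist(cst$ae_unit_costs)),
              paste0(path, ".ae_unit_costs"),
              "must be a named list of non-negative event costs")
  f
}

.validate_utilities <- function(f, u, path = "utilities") {
  n0 <- length(f)
  f <- .require_fields(f, u, c("state", "ae_disutility"), path)
  if (length(f) > n0) return(f)
  need <- c("remission", "mild", "moderate_severe", "surgery")
  f <- .check(f, is.list(u$state) && all(need %in% names(u$state)),
              paste0(path, ".state"),
              "must name remission, mild, moderate_severe and surgery")
  if (is.list(u$state)) {
    f <- .check(f, .is_prob(unlist(u$state)), paste0(path, ".state"),
                "state utilities must lie in [0, 1]")
  }
  d <- unlist(u$ae_disutility)
  f <- .check(f, is.numeric(d) && all(d <= 0) && all(d >= -1),
              paste0(path, ".ae_disutility"),
              "event disutilities must lie in [-1, 0]")
  f
}

.validate_efficacy_stage <- function(f, e, path, gamma = 0) {
  n0 <- length(f)
  f <- .require_fields(f, e, c("response", "remission"), path)
  if (length(f) > n0) return(f)
  f <- .check(f, .is_prob(e$response), paste0(path, ".response"),
              "must be a probability in [0, 1]")
  f <- .check(f, .is_prob(e$remission), paste0(path, ".remission"),
              "must be a probability in [0, 1]")
  if (.is_prob(e$response) && .is_prob(e$remission)) {
    f <- .check(f, e$remission <= e$response, path,
                "remission rate cannot exceed response rate (remitters are responders)")
    # the response split requires a non-negative mild share:
    # remission <= response * (1 - gamma)
    if (.is_prob(gamma)) {
      f <- .check(f, e$remission <= e$response * (1 - gamma) + 1e-12, path,
                  paste0("remission rate cannot exceed the response rate net ",
                         "of the moderate-to-severe responder fraction"))
    }
  }
  f
}

.validate_treatments <- function(f, trts, structural, gamma = 0,
                                 path = "treatments") {
  n0 <- length(f)
  f <- .check(f, is.list(trts) && length(trts) == 2 &&
                all(c("intervention", "comparator") %in% names(trts)),
              path, "exactly two strategies required: intervention and comparator")
  if (length(f) > n0) return(f)
  for (arm in c("intervention", "comparator")) {
    t <- trts[[arm]]
    p <- paste0(path, ".", arm)
    n_arm <- length(f)
    f <- .require_fields(f, t, c("name", "drug", "induction", "maintenance",
                                 "efficacy", "discontinuation_cycle_prob_standard",
                                 "discontinuation_cycle_prob_escalated",
                                 "escalation_cycle_prob",
                                 "escalation_cost_multiplier",
                                 "convergence_cycles"), p)
    if (length(f) > n_arm) next
    f <- .check(f, .is_nonneg(t$drug$pack_cost), paste0(p, ".drug.pack_cost"),
                "must be non-negative")
    f <- .check(f, is.numeric(t$drug$pack_mg) && t$drug$pack_mg > 0,
                paste0(p, ".drug.pack_mg"), "must be positive")
    for (stage in c("first", "second")) {
      ind <- t$induction[[stage]]
      ps <- paste0(p, ".induction.", stage)
      f <- .require_fields(f, ind, c("route", "weeks"), ps)
      if (!is.null(ind$route)) {
        f <- .check(f, ind$route %in% c("IV", "SC"), paste0(ps, ".route"),
                    "must be IV or SC")
      }
      f <- .check(f, !is.null(ind$doses_mg) || !is.null(ind$weight_band_mg), ps,
                  "needs doses_mg or weight_band_mg")
    }
    f <- .check(f, is.numeric(t$induction$first_assessment_week) &&
                  t$induction$first_assessment_week > 0,
                paste0(p, ".induction.first_assessment_week"), "must be positive")
    f <- .check(f, is.numeric(t$induction$second_assessment_week) &&
                  t$induction$second_assessment_week >=
                    t$induction$first_assessment_week,
                paste0(p, ".induction.second_assessment_week"),
                "must be at or after the first assessment")
    f <- .check(f, is.numeric(t$maintenance$interval_weeks) &&
                  t$maintenance$interval_weeks > 0,
                paste0(p, ".maintenance.interval_weeks"), "must be positive")
    f <- .check(f, t$maintenance$route %in% c("IV", "SC"),
                paste0(p, ".maintenance.route"), "must be IV or SC")
    crit <- if (!is.null(structural$response_criterion))
      structural$response_criterion else "CDAI100"
    f <- .check(f, !is.null(t$efficacy[[crit]]), paste0(p, ".efficacy"),
                sprintf("missing efficacy set for response criterion %s", crit))
    for (set_name in names(t$efficacy)) {
      for (stage in c("first", "second")) {
        f <- .validate_efficacy_stage(
          f, t$efficacy[[set_name]][[stage]],
          paste0(p, ".efficacy.", set_name, ".", stage), gamma)
      }
    }
    for (fld in c("discontinuation_cycle_prob_standard",
                  "discontinuation_cycle_prob_escalated",
                  "escalation_cycle_prob")) {
      f <- .check(f, .is_prob(t[[fld]]), paste0(p, ".", fld),
                  "must be a probability in [0, 1]")
    }
    f <- .check(f, is.numeric(t$escalation_cost_multiplier) &&
                  t$escalation_cost_multiplier >= 1,
                paste0(p, ".escalation_cost_multiplier"), "must be >= 1")
    f <- .check(f, is.numeric(t$convergence_cycles) && t$convergence_cycles >= 0,
                paste0(p, ".convergence_cycles"), "must be >= 0")
    if (!is.null(t$ae_cycle_rates)) {
      f <- .check(f, .is_prob(unlist(t$ae_cycle_rates)),
                  paste0(p, ".ae_cycle_rates"),
                  "cycle rates must be probabilities in [0, 1]")
    }
  }
  f
}

.validate_unpublished <- function(f, u, trts, path = "unpublished") {
  n0 <- length(f)
  f <- .require_fields(f, u, c("soc_transition_matrix", "post_surgery_distribution",
                               "mortality_table", "maintenance_targets",
                               "surgery_complication_prob"), path)
  if (length(f) > n0) return(f)
  m <- .as_matrix3(u$soc_transition_matrix)
  f <- .check(f, !is.null(m) && all(m >= 0) && all(m <= 1) &&
                all(abs(rowSums(m) - 1) <= 1e-9),
              paste0(path, ".soc_transition_matrix"),
              "must be a row-stochastic 3x3 matrix over the CDAI states")
  ps <- unlist(u$post_surgery_distribution)
  f <- .check(f, .is_prob(ps) && length(ps) == 3 && abs(sum(ps) - 1) <= 1e-9,
              paste0(path, ".post_surgery_distribution"),
              "must be three fractions over the CDAI states summing to 1")
  mt <- u$mortality_table
  f <- .check(f, is.list(mt) && !is.null(mt$age) && !is.null(mt$cycle_prob) &&
                length(mt$age) == length(mt$cycle_prob),
              paste0(path, ".mortality_table"),
              "must pair an age vector with per-cycle death probabilities")
  if (is.list(mt) && !is.null(mt$cycle_prob)) {
    f <- .check(f, .is_prob(mt$cycle_prob) && !is.unsorted(mt$cycle_prob),
                paste0(path, ".mortality_table"),
                "per-cycle death probabilities must be in [0,1], non-decreasing in age")
  }
  f <- .check(f, .is_prob(u$surgery_complication_prob),
              paste0(path, ".surgery_complication_prob"),
              "must be a probability in [0, 1]")
  for (trt in names(u$maintenance_targets)) {
    tg <- u$maintenance_targets[[trt]]
    pth <- paste0(path, ".maintenance_targets.", trt)
    f <- .check(f, .is_prob(tg$remission) && .is_prob(tg$mild) &&
                  tg$remission + tg$mild <= 1,
                pth, "target remission and mild must be fractions with sum <= 1")
  }
  if (is.list(trts)) {
    for (arm in intersect(c("intervention", "comparator"), names(trts))) {
      nm <- trts[[arm]]$name
      f <- .check(f, !is.null(u$maintenance_targets[[nm]]),
                  paste0(path, ".maintenance_targets"),
                  sprintf("missing end-of-maintenance target for treatment '%s'", nm))
    }
  }
  f
}

.as_matrix3 <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(3, 3))) {
    m <- x
  } else if (is.list(x) && length(x) == 3) {
    rows <- lapply(x, unlist)
    if (!all(lengths(rows) == 3)) return(NULL)
    m <- do.call(rbind, rows)
  } else if (is.numeric(x) && length(x) == 9) {
    m <- matrix(x, 3, 3, byrow = TRUE)
  } else {
    return(NULL)
  }
  dimnames(m) <- list(health_states("cdai"), health_states("cdai"))
  m
}

# ---- file IO ----------------------------------------------------------------

#' Load model inputs from a configuration document
#'
#' Reads a YAML configuration describing one population/comparison, validates
#' every field and fills missing unpublished inputs from the synthetic
#' defaults.
#'
#' @param path Path to a YAML document (see `inst/extdata/` for the schema).
#' @return A validated [as_model_inputs()] object.
#' @export
load_model_inputs <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  as_model_inputs(yaml::read_yaml(path))
}

#' Write model inputs back to a configuration document
#'
#' Inverse of [load_model_inputs()]: a written document reloads to an input
#' set with identical parameter values.
#'
#' @param inputs A `cdcem_inputs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "cdcem_inputs"))
  x <- unclass(inputs)
  x$unpublished$soc_transition_matrix <-
    .matrix_to_rows(.as_matrix3(x$unpublished$soc_transition_matrix))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

.matrix_to_rows <- function(m) {
  setNames(lapply(seq_len(nrow(m)), function(i) as.list(setNames(m[i, ], colnames(m)))),
           rownames(m))
}

#' Published base-case inputs for one study population
#'
#' Returns the packaged input set for either the conventional-care-failure
#' population (ustekinumab versus adalimumab) or the TNF-alpha-inhibitor
#' failure population (ustekinumab versus vedolizumab), with every published
#' value carried verbatim from its printed source. Inputs the publication
#' does not report -- the standard-of-care transition matrix, post-surgery
#' destinations, background mortality, end-of-maintenance targets, adverse
#' event unit costs, standard-of-care drug cost and the surgical complication
#' probability -- are deterministic synthetic stand-ins; the object's
#' `provenance` field lists them so no run can be mistaken for an exact
#' reproduction of the published base case.
#'
#' @param population `"conventional_care_failure"` or `"tnf_failure"`.
#' @return A validated `cdcem_inputs` object.
#' @export
#' @examples
#' inp <- published_baseline_inputs("conventional_care_failure")
#' inp$treatments$intervention$drug$pack_cost  # 3546 EUR per 90 mg
published_baseline_inputs <- function(population = c("conventional_care_failure",
                                                 "tnf_failure")) {
  population <- match.arg(population)
  fname <- switch(population,
                  conventional_care_failure = "conventional_care.yaml",
                  tnf_failure = "tnf_failure.yaml")
  path <- system.file("extdata", fname, package = "cdcem", mustWork = TRUE)
  load_model_inputs(path)
}

#' Published disaggregated base-case results
#'
#' The per-arm discounted totals and cost components reported for the two
#' base-case comparisons (2016 EUR; QALYs over a 60-year horizon). These are
#' inputs for worked examples of the incremental-analysis arithmetic; the
#' package does not claim to regenerate them (they depend on inputs the
#' publication does not report).
#'
#' @return Data frame with one row per treatment arm.
#' @export
published_base_case <- function() {
  path <- system.file("extdata", "published_base_case.csv",
                      package = "cdcem", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.cdcem_inputs <- function(x, ...) {
  trt <- vapply(x$treatments, function(t) t$name, character(1))
  cat("<cdcem_inputs>\n")
  cat("  population:", x$population$name, "\n")
  cat("  comparison:", trt[["intervention"]], "vs", trt[["comparator"]], "\n")
  cat("  horizon:", x$structural$horizon_years, "years;",
      "treatment duration:", x$structural$treatment_duration_years, "years\n")
  if (!is.null(x$provenance)) {
    cat("  synthetic stand-in fields:", paste(x$provenance, collapse = ", "), "\n")
  }
  invisible(x)
}
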