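#' Construct a CDAI transition matrix
#'
#' Row-stochastic 3x3 matrix over the disease-activity states (remission,
#' mild, moderate-severe), applied once per 2-week maintenance cycle.
#'
#' @param x 3x3 numeric matrix, a list of three rows, or a length-9 vector
#'   (row-major).
#' @param tol Row-sum tolerance.
#' @return Matrix with CDAI state dimnames, class `cdcem_matrix`.
#' @export
#' @examples
#' transition_matrix(diag(3))
transition_matrix <- function(x, tol = 1e-9) {
  m <- .as_matrix3(x)
  if (is.null(m)) stop("transition matrix must be 3x3 over the CDAI states",
                       call. = FALSE)
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) {
    stop("transition matrix rows must sum to 1; offending row(s): ",
         paste(rownames(m)[bad], collapse = ", "), call. = FALSE)
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  class(m) <- c("cdcem_matrix", class(m))
  m
}

#' Specify a calibration target
#'
#' The calibration problem: starting from the cohort's CDAI distribution at
#' the beginning of maintenance, find a transition matrix that, applied for
#' `n_cycles` cycles, reproduces the remission and mild fractions predicted
#' externally (in the source study, by network meta-analysis and treatment
#' sequence analysis) at the end of maintenance.
#'
#' @param start_distribution Length-3 fractions over (remission, mild,
#'   moderate-severe), summing to 1.
#' @param target_remission,target_mild Target end-of-maintenance fractions,
#'   with `target_remission + target_mild <= 1`.
#' @param n_cycles Number of 2-week cycles between start and target.
#' @return List of class `cdcem_cal_target`.
#' @export
calibration_target <- function(start_distribution, target_remission,
                               target_mild, n_cycles) {
  start_distribution <- unlist(start_distribution)
  stopifnot(length(start_distribution) == 3, all(start_distribution >= 0),
            abs(sum(start_distribution) - 1) <= 1e-9,
            target_remission >= 0, target_remission <= 1,
            target_mild >= 0, target_mild <= 1,
            target_remission + target_mild <= 1,
            n_cycles >= 1, n_cycles == round(n_cycles))
  structure(list(start_distribution = setNames(start_distribution,
                                               health_states("cdai")),
                 target_remission = target_remission,
                 target_mild = target_mild,
                 n_cycles = as.integer(n_cycles)),
            class = "cdcem_cal_target")
}

# propagate a CDAI distribution through a matrix for n cycles
.propagate <- function(dist, matrix, n_cycles) {
  v <- matrix(dist, nrow = 1)
  for (i in seq_len(n_cycles)) v <- v %*% matrix
  drop(v)
}

#' Calibration objective: squared deviation from the target distribution
#'
#' Propagates the start distribution through the candidate matrix for the
#' target's cycle count and returns the sum of squared deviations of the
#' resulting remission and mild fractions from their targets.
#'
#' @param matrix A [transition_matrix()] (or coercible input).
#' @param target A [calibration_target()].
#' @return Non-negative scalar.
#' @export
calibration_objective <- function(matrix, target) {
  m <- transition_matrix(matrix)
  stopifnot(inherits(target, "cdcem_cal_target"))
  end <- .propagate(target$start_distribution, m, target$n_cycles)
  unname((end[1] - target$target_remission)^2 +
           (end[2] - target$target_mild)^2)
}

# softmax row parameterisation keeps every candidate on the simplex,
# so any optimizer path yields a valid row-stochastic matrix
.theta_to_matrix <- function(theta) {
  m <- matrix(0, 3, 3)
  for (i in 1:3) {
    z <- c(theta[(i - 1) * 2 + 1], theta[(i - 1) * 2 + 2], 0)
    z <- exp(z - max(z))
    m[i, ] <- z / sum(z)
  }
  dimnames(m) <- list(health_states("cdai"), health_states("cdai"))
  m
}

.matrix_to_theta <- function(m, eps = 1e-9) {
  m <- pmin(pmax(m, eps), 1)
  th <- numeric(6)
  for (i in 1:3) {
    l <- log(m[i, ]) - log(m[i, 3])
    th[(i - 1) * 2 + 1:2] <- l[1:2]
  }
  th
}

#' Calibrate a maintenance transition matrix against a target distribution
#'
#' Minimises [calibration_objective()] over row-stochastic matrices. Rows are
#' parameterised on the probability simplex (softmax), so every iterate is a
#' valid matrix, and the bounded local search is repeated from multiple
#' random starts; spreadsheet-solver calibrations of this kind are sensitive
#' to starting values, which the restarts and the attached convergence report
#' make explicit. With two targets and six free parameters the solution is
#' generically non-unique; ties between restarts are broken by lower
#' objective, then by lower matrix entropy, for reproducibility.
#'
#' @param target A [calibration_target()].
#' @param start_values Optional starting matrix (also entered as one of the
#'   starts).
#' @param monotone_rows If `TRUE`, adds a penalty keeping each diagonal entry
#'   at least as large as each off-diagonal leaving probability in its row.
#' @param n_restarts Number of random restarts.
#' @param tol Objective value at or below which the target counts as reached.
#' @param seed Integer seed for the random restarts.
#' @return A [transition_matrix()] with attribute `convergence`: a list with
#'   `objective`, `converged`, `n_restarts` and `start_objective`. A solution
#'   that does not reach `tol` is returned flagged (`converged = FALSE`),
#'   never silently.
#' @export
calibrate_transition_matrix <- function(target, start_values = NULL,
                                        monotone_rows = FALSE,
                                        n_restarts = 10, tol = 1e-8,
                                        seed = 1L) {
  stopifnot(inherits(target, "cdcem_cal_target"), n_restarts >= 1)
  if (is.null(start_values)) {
    start_values <- transition_matrix(matrix(
      c(0.85, 0.10, 0.05,
        0.10, 0.80, 0.10,
        0.05, 0.15, 0.80), 3, 3, byrow = TRUE))
  } else {
    start_values <- transition_matrix(start_values)
  }
  penalty <- function(m) {
    if (!monotone_rows) return(0)
    v <- 0
    for (i in 1:3) v <- v + sum(pmax(m[i, -i] - m[i, i], 0)^2)
    1e4 * v
  }
  obj_theta <- function(theta) {
    m <- .theta_to_matrix(theta)
    calibration_objective(m, target) + penalty(m)
  }
  start_objective <- calibration_objective(start_values, target) +
    penalty(start_values)

  starts <- vector("list", n_restarts)
  starts[[1]] <- .matrix_to_theta(start_values)
  if (n_restarts > 1) {
    rand <- .with_seed(seed, stats::runif(6 * (n_restarts - 1), -2, 2))
    for (k in 2:n_restarts) starts[[k]] <- rand[(k - 2) * 6 + 1:6]
  }

  best <- NULL
  for (th0 in starts) {
    fit <- stats::optim(th0, obj_theta, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    # polish with a second pass from the candidate optimum
    fit <- stats::optim(fit$par, obj_theta, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    cand <- list(theta = fit$par, value = fit$value,
                 entropy = .matrix_entropy(.theta_to_matrix(fit$par)))
    if (is.null(best) || cand$value < best$value - 1e-15 ||
        (abs(cand$value - best$value) <= 1e-15 && cand$entropy < best$entropy)) {
      best <- cand
    }
  }

  m <- transition_matrix(.theta_to_matrix(best$theta))
  objective <- calibration_objective(m, target)
  if (objective > start_objective && !monotone_rows) {
    # never worsen relative to the supplied start values
    m <- start_values
    objective <- calibration_objective(m, target)
  }
  attr(m, "convergence") <- list(objective = objective,
                                 converged = objective <= tol,
                                 n_restarts = n_restarts,
                                 start_objective = start_objective)
  m
}

.matrix_entropy <- function(m) {
  p <- m[m > 0]
  -sum(p * log(p))
}

#' Blend an active-treatment matrix toward the standard-of-care matrix
#'
#' After treatment stops, efficacy declines gradually: the applied matrix
#' converges entrywise from the biologic matrix to the standard-of-care
#' matrix over a treatment-specific number of cycles.
#'
#' @param active,soc [transition_matrix()] objects (or coercible).
#' @param progress Fraction of the convergence period elapsed, in \[0, 1\].
#' @return The entrywise mixture `(1 - progress) * active + progress * soc`,
#'   itself row-stochastic.
#' @export
blend_matrices <- function(active, soc, progress) {
  stopifnot(is.numeric(progress), length(progress) == 1,
            progress >= 0, progress <= 1)
  a <- transition_matrix(active)
  s <- transition_matrix(soc)
  transition_matrix((1 - progress) * unclass(a) + progress * unclass(s))
}

# run a block of code under a temporary RNG state, restoring the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
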