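#' Run a closed cohort through the transition matrix
#'
#' Propagates the initial state occupancy through `cycles` monthly
#' transitions: `occupancy[t + 1, ] = occupancy[t, ] %*% P`. Row 1 of the
#' returned trace is cycle 0 (the initial distribution).
#'
#' @param matrix a row-stochastic [transition_matrix()].
#' @param initial a [cohort_spec()] (or numeric length-5 vector of counts).
#' @param cycles number of cycles to simulate.
#' @return A `cohort_trace`: numeric matrix of dimension `(cycles + 1) x 5`,
#'   rows labelled by cycle index starting at 0.
#' @export
run_cohort <- function(matrix, initial, cycles) {
  if (inherits(initial, "cohort_spec")) initial <- initial$initial_counts
  stopifnot(length(initial) == N_STATES, cycles >= 1)
  P <- unclass(matrix)
  rs <- rowSums(P)
  if (any(P < 0 | P > 1) || any(abs(rs - 1) > 1e-9))
    stop("transition matrix is not row-stochastic; normalize it first")
  trace <- base::matrix(0, nrow = cycles + 1L, ncol = N_STATES,
                        dimnames = list(0:cycles, hf_states()))
  trace[1L, ] <- initial
  occ <- as.numeric(initial)
  for (t in seq_len(cycles)) {
    occ <- as.numeric(occ %*% P)
    trace[t + 1L, ] <- occ
  }
  structure(trace, class = c("cohort_trace", "matrix", "array"))
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x) - 1L
  cat(sprintf("cohort trace: %d cycles, %g persons\n", n, sum(x[1L, ])))
  show <- unique(c(1L, min(2L, n + 1L), floor(n / 2) + 1L, n + 1L))
  print(round(unclass(x)[show, , drop = FALSE], 2))
  invisible(x)
}

#' Per-cycle discount factor
#'
#' The annual rate is compounded per cycle as
#' `(1 + rate)^(-(cycle_index - 1) / cycles_per_year)`; the first cycle is
#' undiscounted.
#'
#' @param cycle_index cycle number, 1-based (vectorized).
#' @param annual_rate annual discount rate (e.g. 0.03).
#' @param cycles_per_year cycles per year (12 for monthly cycles).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, annual_rate, cycles_per_year = 12L) {
  if (annual_rate < 0) stop("discount rate must be >= 0")
  stopifnot(all(cycle_index >= 1))
  (1 + annual_rate)^(-(cycle_index - 1) / cycles_per_year)
}

#' Cost accrued by one cycle's occupancy
#'
#' Each alive state contributes its prorated annual costs plus the expected
#' hospitalization cost:
#' `(direct_nonmedical + indirect + dtx) / 12 + monthly_prob * per_admission`.
#' Death contributes nothing.
#'
#' @param occupancy numeric length 5 of persons per state.
#' @param costs a [cost_profile()].
#' @param hosp a [hosp_profile()].
#' @return Total cost (CNY) for one monthly cycle.
#' @export
accrue_cycle_cost <- function(occupancy, costs, hosp) {
  if (any(occupancy < 0)) stop("negative occupancy")
  monthly <- (costs$direct_nonmedical_annual + costs$indirect_annual +
                costs$dtx_annual) / 12 +
             hosp$monthly_prob * costs$direct_medical_per_admission
  sum(occupancy[ALIVE] * monthly)
}

#' QALYs accrued by one cycle's occupancy
#'
#' Each alive state contributes one month of quality-adjusted time,
#' `occupancy * mean_utility / 12`; death contributes nothing.
#'
#' @param occupancy numeric length 5 of persons per state.
#' @param utilities a [utility_profile()].
#' @return QALYs for one monthly cycle.
#' @export
accrue_cycle_qaly <- function(occupancy, utilities) {
  if (any(occupancy < 0)) stop("negative occupancy")
  if (any(utilities$mean < 0 | utilities$mean > 1))
    stop("utility outside [0, 1]")
  sum(occupancy[ALIVE] * utilities$mean) / 12
}

#' Evaluate one strategy arm
#'
#' Runs the cohort for the configured number of cycles, accrues discounted
#' cost and QALYs per cycle on the cycle-start occupancy (optionally averaged
#' with the cycle-end occupancy when `half_cycle` is set in the settings),
#' divides totals by the initial cohort size, and annualizes. Matrices whose
#' rows do not sum to one (printed rounding defects) are repaired first
#' according to `normalize`.
#'
#' @param instance an `hf_model`.
#' @param normalize row-repair mode passed to [normalize_rows()], or `"none"`
#'   to use the matrix exactly as stored.
#' @return A `strategy_result` with per-capita discounted totals
#'   (`total_cost`, `total_qaly`, `life_years`), per-cycle vectors, the
#'   annualized values, the trace, and the settings used.
#' @export
evaluate_strategy <- function(instance,
                              normalize = c("adjust_diagonal",
                                            "proportional", "none")) {
  normalize <- match.arg(normalize)
  s <- instance$settings
  P <- instance$transition
  if (normalize != "none") P <- normalize_rows(P, normalize)

  trace <- run_cohort(P, instance$cohort, s$cycles)
  t_idx <- seq_len(s$cycles)
  disc <- discount_factor(t_idx, s$annual_discount_rate, s$cycles_per_year)

  start <- unclass(trace)[t_idx, , drop = FALSE]
  occ <- if (s$half_cycle)
    (start + unclass(trace)[t_idx + 1L, , drop = FALSE]) / 2 else start

  monthly_cost <- (instance$costs$direct_nonmedical_annual +
                     instance$costs$indirect_annual +
                     instance$costs$dtx_annual) / 12 +
                  instance$hosp$monthly_prob *
                    instance$costs$direct_medical_per_admission
  cycle_cost <- as.numeric(occ[, ALIVE, drop = FALSE] %*% monthly_cost)
  cycle_qaly <- as.numeric(occ[, ALIVE, drop = FALSE] %*%
                             instance$utilities$mean) / 12
  cycle_ly <- rowSums(occ[, ALIVE, drop = FALSE]) / 12

  n0 <- instance$cohort$size
  per_cycle_cost <- disc * cycle_cost / n0
  per_cycle_qaly <- disc * cycle_qaly / n0
  total_cost <- sum(per_cycle_cost)
  total_qaly <- sum(per_cycle_qaly)
  life_years <- sum(disc * cycle_ly) / n0

  denom <- switch(s$annualization,
                  per_horizon_year = s$horizon_years,
                  per_life_year = life_years)
  structure(list(arm = instance$arm,
                 total_cost = total_cost,
                 total_qaly = total_qaly,
                 life_years = life_years,
                 per_cycle_cost = per_cycle_cost,
                 per_cycle_qaly = per_cycle_qaly,
                 annualized_cost = total_cost / denom,
                 annualized_qaly = total_qaly / denom,
                 trace = trace,
                 normalize = normalize,
                 settings = s),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("strategy %s (%s, %s):\n", x$arm, x$settings$annualization,
              x$normalize))
  cat(sprintf("  per-capita discounted total: %.2f CNY, %.5f QALY, %.4f LY\n",
              x$total_cost, x$total_qaly, x$life_years))
  cat(sprintf("  annualized: %.2f CNY/yr, %.5f QALY/yr\n",
              x$annualized_cost, x$annualized_qaly))
  invisible(x)
}

#' Export a cohort trace with its accrual vectors
#'
#' @param result a `strategy_result`.
#' @return Data frame with cycle index, state occupancies, discount factor
#'   and discounted per-capita cycle cost and QALYs (cycle 0 rows carry the
#'   initial occupancy and no accrual).
#' @export
trace_table <- function(result) {
  tr <- as.data.frame(unclass(result$trace))
  s <- result$settings
  data.frame(cycle = 0:s$cycles, tr,
             discount = c(NA, discount_factor(seq_len(s$cycles),
                                              s$annual_discount_rate,
                                              s$cycles_per_year)),
             cycle_cost = c(NA, result$per_cycle_cost),
             cycle_qaly = c(NA, result$per_cycle_qaly),
             row.names = NULL)
}
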