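#' Health-state labels of the heart-failure Markov model
#'
#' The model tracks five mutually exclusive health states: the four New York
#' Heart Association (NYHA) functional classes plus death. Death is the unique
#' absorbing state and always occupies the last position.
#'
#' @return Character vector of the five state labels, in ordinal order.
#' @export
hf_states <- function() {
  c("NYHA_I", "NYHA_II", "NYHA_III", "NYHA_IV", "DEATH")
}

N_STATES <- 5L
ALIVE <- 1:4
DEATH <- 5L

#' Construct a monthly transition matrix
#'
#' @param entries numeric 5x5 matrix of per-cycle transition probabilities,
#'   rows and columns ordered as [hf_states()]. Rows are origin states.
#' @return A `transition_matrix`: the matrix with state dimnames.
#' @export
transition_matrix <- function(entries) {
  entries <- as.matrix(entries)
  if (!identical(dim(entries), c(N_STATES, N_STATES)))
    stop("transition matrix must be 5x5 (NYHA I-IV + death)")
  dimnames(entries) <- list(hf_states(), hf_states())
  structure(entries, class = c("transition_matrix", class(entries)))
}

#' Construct a hospitalization profile
#'
#' Hospitalization is modelled as an expected per-cycle event, not a separate
#' state: each alive state has a monthly probability of admission, and the
#' intervention arm's probabilities relate to the comparator's through
#' per-state risk ratios.
#'
#' @param monthly_prob numeric length 4, monthly admission probability per
#'   alive state.
#' @param risk_ratio numeric length 4, intervention-vs-comparator risk ratio
#'   per alive state (1 for the comparator arm).
#' @return A `hosp_profile` list.
#' @export
hosp_profile <- function(monthly_prob, risk_ratio = rep(1, 4)) {
  stopifnot(length(monthly_prob) == 4L, length(risk_ratio) == 4L)
  structure(list(monthly_prob = as.numeric(monthly_prob),
                 risk_ratio = as.numeric(risk_ratio)),
            class = "hosp_profile")
}

#' Construct a cost profile
#'
#' All amounts are in CNY. Direct medical cost is per hospital admission;
#' direct non-medical, indirect and digital-therapeutics (DTx) costs are
#' annual and prorated over monthly cycles by the engine.
#'
#' @param direct_medical_per_admission numeric length 4 (CNY per admission).
#' @param direct_nonmedical_annual numeric length 4 (CNY/year).
#' @param indirect_annual numeric length 4 (CNY/year).
#' @param dtx_annual scalar annual DTx fee (CNY/year; 0 for the comparator).
#' @return A `cost_profile` list.
#' @export
cost_profile <- function(direct_medical_per_admission,
                         direct_nonmedical_annual,
                         indirect_annual,
                         dtx_annual = 0) {
  stopifnot(length(direct_medical_per_admission) == 4L,
            length(direct_nonmedical_annual) == 4L,
            length(indirect_annual) == 4L,
            length(dtx_annual) == 1L)
  structure(list(
    direct_medical_per_admission = as.numeric(direct_medical_per_admission),
    direct_nonmedical_annual = as.numeric(direct_nonmedical_annual),
    indirect_annual = as.numeric(indirect_annual),
    dtx_annual = as.numeric(dtx_annual)), class = "cost_profile")
}

#' Construct a utility profile
#'
#' Mean health-state utilities (0-1 scale) with their variances for the four
#' alive states; death carries utility 0 by construction.
#'
#' @param mean numeric length 4 of state utilities.
#' @param variance numeric length 4 of utility variances (used by the
#'   probabilistic sensitivity analysis to fit beta distributions).
#' @return A `utility_profile` list.
#' @export
utility_profile <- function(mean, variance) {
  stopifnot(length(mean) == 4L, length(variance) == 4L)
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "utility_profile")
}

#' Construct economic settings
#'
#' @param annual_discount_rate annual discount rate applied to both costs and
#'   QALYs (default 3%/year).
#' @param cycles number of cycles (default 120 monthly cycles).
#' @param cycles_per_year cycles per year (default 12).
#' @param horizon_years model horizon in years (default 10); must satisfy
#'   `cycles == cycles_per_year * horizon_years`.
#' @param wtp willingness-to-pay threshold, CNY per QALY (default 85,698,
#'   China's 2022 GDP per capita).
#' @param annualization how per-capita totals are expressed per year:
#'   `"per_horizon_year"` divides the total discounted value by
#'   `horizon_years`; `"per_life_year"` divides by discounted life-years.
#' @param half_cycle logical; average start- and end-of-cycle occupancy when
#'   accruing (off by default).
#' @return An `economic_settings` list.
#' @export
economic_settings <- function(annual_discount_rate = 0.03,
                              cycles = 120L,
                              cycles_per_year = 12L,
                              horizon_years = 10,
                              wtp = 85698,
                              annualization = c("per_horizon_year",
                                                "per_life_year"),
                              half_cycle = FALSE) {
  annualization <- match.arg(annualization)
  if (annual_discount_rate < 0) stop("discount rate must be >= 0")
  if (cycles != cycles_per_year * horizon_years)
    stop("cycles must equal cycles_per_year * horizon_years")
  structure(list(annual_discount_rate = as.numeric(annual_discount_rate),
                 cycles = as.integer(cycles),
                 cycles_per_year = as.integer(cycles_per_year),
                 horizon_years = as.numeric(horizon_years),
                 wtp = as.numeric(wtp),
                 annualization = annualization,
                 half_cycle = isTRUE(half_cycle)),
            class = "economic_settings")
}

#' Construct an initial cohort specification
#'
#' @param initial_counts numeric length 5 of persons per state at cycle 0
#'   (death count must be 0).
#' @return A `cohort_spec` list with the counts and total size.
#' @export
cohort_spec <- function(initial_counts) {
  stopifnot(length(initial_counts) == N_STATES)
  initial_counts <- as.numeric(initial_counts)
  names(initial_counts) <- hf_states()
  structure(list(initial_counts = initial_counts,
                 size = sum(initial_counts)), class = "cohort_spec")
}

#' Assemble a complete model instance for one strategy arm
#'
#' @param arm arm label, `"CH"` (conventional home rehabilitation) or `"DT"`
#'   (digital therapeutics).
#' @param transition a [transition_matrix()].
#' @param hosp a [hosp_profile()].
#' @param costs a [cost_profile()].
#' @param utilities a [utility_profile()].
#' @param cohort a [cohort_spec()].
#' @param settings an [economic_settings()].
#' @return An `hf_model` list of the components.
#' @export
model_instance <- function(arm, transition, hosp, costs, utilities, cohort,
                           settings = economic_settings()) {
  structure(list(arm = as.character(arm), transition = transition,
                 hosp = hosp, costs = costs, utilities = utilities,
                 cohort = cohort, settings = settings),
            class = "hf_model")
}

#' @export
print.hf_model <- function(x, ...) {
  cat(sprintf("Markov model instance, arm %s\n", x$arm))
  cat(sprintf("  cohort: %g persons (%s)\n", x$cohort$size,
              paste(x$cohort$initial_counts[ALIVE], collapse = "/")))
  cat(sprintf("  cycles: %d monthly, discount %g%%/yr, annualization %s\n",
              x$settings$cycles, 100 * x$settings$annual_discount_rate,
              x$settings$annualization))
  rs <- rowSums(x$transition)
  cat(sprintf("  transition row sums: %s\n",
              paste(format(rs, digits = 4), collapse = " ")))
  invisible(x)
}

#' Validate a model instance
#'
#' Checks every structural invariant of the model and reports violations
#' instead of raising: transition entries in `[0,1]`, row sums within
#' `row_sum_tolerance` of 1, an absorbing death row, hospitalization
#' probabilities in `[0,1]`, positive risk ratios, non-negative costs,
#' utilities in `[0,1]` with positive variances, a non-negative cohort with
#' no deaths at baseline, and consistent cycle settings.
#'
#' @param instance an `hf_model`.
#' @param row_sum_tolerance allowed absolute deviation of each row sum from 1.
#' @return An `hf_validation` data frame with columns `field` and `message`;
#'   zero rows means the instance is valid.
#' @export
validate_model <- function(instance, row_sum_tolerance = 1e-6) {
  bad <- list()
  note <- function(field, message)
    bad[[length(bad) + 1L]] <<- data.frame(field = field, message = message)

  P <- unclass(instance$transition)
  if (any(P < 0 | P > 1))
    note("transition", "entries outside [0, 1]")
  rs <- rowSums(P)
  off <- which(abs(rs - 1) > row_sum_tolerance)
  for (i in off)
    note("transition", sprintf("row %s sums to %.6g", hf_states()[i], rs[i]))
  if (!isTRUE(all(P[DEATH, ] == c(0, 0, 0, 0, 1))))
    note("transition", "death row is not absorbing (0,0,0,0,1)")

  h <- instance$hosp
  if (any(h$monthly_prob < 0 | h$monthly_prob > 1))
    note("hosp", "monthly hospitalization probability outside [0, 1]")
  if (any(h$risk_ratio <= 0))
    note("hosp", "risk ratio must be > 0")

  co <- instance$costs
  if (any(unlist(co) < 0))
    note("costs", "negative cost")

  u <- instance$utilities
  if (any(u$mean < 0 | u$mean > 1))
    note("utilities", "mean utility outside [0, 1]")
  if (any(u$variance <= 0))
    note("utilities", "non-positive utility variance")

  ch <- instance$cohort
  if (any(ch$initial_counts < 0))
    note("cohort", "negative initial count")
  if (ch$initial_counts[DEATH] != 0)
    note("cohort", "baseline death count must be 0")

  s <- instance$settings
  if (s$cycles != s$cycles_per_year * s$horizon_years)
    note("settings", "cycles != cycles_per_year * horizon_years")
  if (s$annual_discount_rate < 0)
    note("settings", "negative discount rate")

  out <- if (length(bad)) do.call(rbind, bad)
         else data.frame(field = character(), message = character())
  structure(out, class = c("hf_validation", "data.frame"))
}

#' @export
print.hf_validation <- function(x, ...) {
  if (nrow(x) == 0L) cat("model instance valid: no invariant violations\n")
  else {
    cat(sprintf("%d invariant violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s\n", x$field[i], x$message[i]))
  }
  invisible(x)
}

#' Is a validation report clean?
#' @param report an `hf_validation` report.
#' @return `TRUE` if no violations were found.
#' @export
is_valid <- function(report) nrow(report) == 0L

#' Renormalize transition-matrix rows to sum to one
#'
#' Printed transition matrices sometimes carry rounding defects so that rows
#' sum to 0.999 or 1.001. Two repairs are offered: `"proportional"` divides
#' each row by its sum (preserving within-row ratios), `"adjust_diagonal"`
#' moves the whole residual onto the stay-probability (preserving the printed
#' off-diagonal transition and death probabilities, which are usually the
#' clinically sourced quantities).
#'
#' @param matrix a [transition_matrix()] with non-negative entries.
#' @param mode `"adjust_diagonal"` (default) or `"proportional"`.
#' @return A row-stochastic `transition_matrix` (rows sum to 1 within 1e-12).
#' @export
normalize_rows <- function(matrix,
                           mode = c("adjust_diagonal", "proportional")) {
  mode <- match.arg(mode)
  P <- unclass(matrix)
  if (any(P < 0)) stop("normalize_rows requires non-negative entries")
  rs <- rowSums(P)
  if (any(rs <= 0)) stop("zero-sum transition row: malformed matrix")
  if (mode == "proportional") {
    P <- P / rs
  } else {
    d <- diag(P) + (1 - rs)
    if (any(d < 0 | d > 1))
      stop("adjust_diagonal would push a stay-probability outside [0, 1]")
    diag(P) <- d
  }
  transition_matrix(P)
}
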