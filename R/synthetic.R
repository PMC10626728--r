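#' Configuration for the synthetic instance generator
#'
#' Controls the statistical shape of randomly generated two-arm model
#' instances: a severity gradient in monthly mortality, severity-ordered
#' utilities, positive cost scales, and an effect-size knob (the
#' intervention's hospitalization risk ratio and its mortality/stay
#' improvement). Defaults mirror the scale of the published heart-failure
#' parameterization: a 1,000-person cohort, monthly mortality rising from
#' about 1% (mildest class) to about 12% (most severe), and a moderately
#' protective intervention.
#'
#' @param cohort_size total persons at baseline.
#' @param mortality_range monthly death-probability bounds for the mildest
#'   and most severe alive state (interpolated in between, then jittered).
#' @param utility_bounds bounds for the (decreasing) state utilities.
#' @param cost_scale multiplicative scale applied to the cost magnitudes.
#' @param rr_range range of the intervention's hospitalization risk ratio;
#'   set both ends to 1 for a neutral intervention.
#' @param effect effect size in (0, 1]: the intervention multiplies each
#'   state's death and worsening probabilities by `effect` (1 = neutral).
#' @param settings shared [economic_settings()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(cohort_size = 1000,
                             mortality_range = c(0.01, 0.12),
                             utility_bounds = c(0.35, 0.95),
                             cost_scale = 1,
                             rr_range = c(0.6, 0.9),
                             effect = 0.8,
                             settings = economic_settings()) {
  stopifnot(cohort_size > 0, mortality_range[1] < mortality_range[2],
            utility_bounds[1] < utility_bounds[2],
            cost_scale > 0, all(rr_range > 0), effect > 0, effect <= 1)
  structure(list(cohort_size = cohort_size,
                 mortality_range = mortality_range,
                 utility_bounds = utility_bounds,
                 cost_scale = cost_scale, rr_range = rr_range,
                 effect = effect, settings = settings),
            class = "synthetic_config")
}

#' Generate a random, structurally valid two-arm model instance
#'
#' Transition rows are drawn from a Dirichlet-style simplex sampler with the
#' death probability pinned to a severity-increasing gradient; the death row
#' is absorbing; utilities decrease with severity; costs are positive. The
#' intervention arm is derived from the comparator by multiplying death and
#' worsening probabilities by the `effect` knob (residual moved to the
#' stay-probability) and scaling hospitalization probabilities by a risk
#' ratio drawn from `rr_range`. Every generated instance passes
#' [validate_model()] at tolerance 1e-12 by construction.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (same seed, same instances).
#' @return List with `hf_model` elements `ch` and `dt`, plus `ranges` (a
#'   modest sensitivity-range table for the sampled parameters, built the
#'   same way as the published one).
#' @export
random_model_instance <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }

  mort <- seq(config$mortality_range[1], config$mortality_range[2],
              length.out = 4)
  mort <- pmin(mort * stats::runif(4, 0.8, 1.2), 0.5)

  P <- matrix(0, 5, 5)
  for (i in ALIVE) {
    # Dirichlet weights over the alive destinations, concentrated on staying
    a <- rep(0.4, 4); a[i] <- 12
    g <- stats::rgamma(4, shape = a)
    P[i, ALIVE] <- (g / sum(g)) * (1 - mort[i])
    P[i, DEATH] <- mort[i]
    P[i, DEATH] <- 1 - sum(P[i, ALIVE])   # exact row sum
  }
  P[DEATH, DEATH] <- 1

  # intervention: scale death and worsening transitions down by `effect`,
  # absorb the freed mass into the stay-probability
  Q <- P
  if (config$effect < 1) {
    for (i in ALIVE) {
      worse <- c(if (i < 4) (i + 1):4 else integer(0), DEATH)
      Q[i, worse] <- P[i, worse] * config$effect
      Q[i, i] <- 1 - sum(Q[i, -i])
    }
  }

  u <- sort(stats::runif(4, config$utility_bounds[1],
                         config$utility_bounds[2]), decreasing = TRUE)
  uvar <- pmin(stats::runif(4, 0.002, 0.02), 0.9 * u * (1 - u))
  util <- utility_profile(u, uvar)

  sc <- config$cost_scale
  dm <- stats::runif(4, 20000, 70000) * sc
  nm <- stats::runif(4, 800, 6000) * sc
  ind <- stats::runif(4, 15000, 50000) * sc
  neutral <- config$effect == 1 && diff(config$rr_range) == 0 &&
    config$rr_range[1] == 1
  dtx <- if (neutral) 0 else stats::runif(1, 100, 300) * sc
  hosp_p <- sort(stats::runif(4, 0.002, 0.1))
  rr <- if (diff(config$rr_range) == 0) rep(config$rr_range[1], 4) else
    stats::runif(4, config$rr_range[1], config$rr_range[2])

  w <- stats::runif(4, 0.6, 0.9)   # initial mass decreasing with severity
  init <- config$cohort_size * c(cumprod(w) / sum(cumprod(w)), 0)

  cohort <- cohort_spec(init)
  s <- config$settings
  ch <- model_instance("CH", transition_matrix(P), hosp_profile(hosp_p),
                       cost_profile(dm, nm, ind, 0), util, cohort, s)
  dt <- model_instance("DT", transition_matrix(Q),
                       hosp_profile(pmin(hosp_p * rr, 1), rr),
                       cost_profile(dm, nm, ind, dtx), util, cohort, s)

  alive <- hf_states()[1:4]
  spread <- function(x, f = 0.2) data.frame(low = x * (1 - f),
                                            high = x * (1 + f))
  ranges <- rbind(
    cbind(data.frame(group = "direct_medical", state = alive, base = dm),
          spread(dm), family = "gamma"),
    cbind(data.frame(group = "direct_nonmedical", state = alive, base = nm),
          spread(nm), family = "gamma"),
    cbind(data.frame(group = "indirect", state = alive, base = ind),
          spread(ind), family = "gamma"),
    cbind(data.frame(group = "dtx_cost", state = "ALL", base = dtx),
          spread(dtx), family = "gamma"),
    data.frame(group = "utility", state = "ALL", base = NA_real_,
               low = max(0.01, min(u) - 0.05), high = min(0.99, max(u) + 0.05),
               family = "beta"),
    data.frame(group = "hospitalization_rr", state = "ALL", base = NA_real_,
               low = mean(rr) * 0.7, high = mean(rr) * 1.3,
               family = "lognormal"))
  rownames(ranges) <- NULL

  list(ch = ch, dt = dt, ranges = ranges)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` independent patients through the same model:
#' monthly state paths by categorical sampling from the transition-matrix
#' rows, hospitalization as per-cycle Bernoulli events, and the identical
#' per-cycle cost/QALY accrual and discounting as the cohort engine. Its
#' per-capita means converge to the cohort model's expectation, making it an
#' independent check of the transition dynamics.
#'
#' @param instance an `hf_model`.
#' @param n_patients number of simulated individuals.
#' @param seed integer seed.
#' @param normalize transition-row repair mode (match the cohort run).
#' @return An `hf_microsim` list: `cost` and `qaly` (per-capita discounted
#'   means), `cost_se`/`qaly_se` (standard errors), `annualized_cost`,
#'   `annualized_qaly`, `n_patients`.
#' @export
microsimulate <- function(instance, n_patients, seed = NULL,
                          normalize = "adjust_diagonal") {
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }
  s <- instance$settings
  P <- instance$transition
  if (normalize != "none") P <- normalize_rows(P, normalize)
  P <- unclass(P)
  cum <- t(apply(P, 1L, cumsum))

  init_p <- instance$cohort$initial_counts / instance$cohort$size
  n <- as.integer(n_patients)
  state <- sample.int(N_STATES, n, replace = TRUE, prob = init_p)

  monthly_fixed <- (instance$costs$direct_nonmedical_annual +
                      instance$costs$indirect_annual +
                      instance$costs$dtx_annual) / 12
  adm_cost <- instance$costs$direct_medical_per_admission
  hosp_p <- instance$hosp$monthly_prob
  u <- instance$utilities$mean

  cost <- numeric(n); qaly <- numeric(n)
  half <- s$half_cycle
  for (t in seq_len(s$cycles)) {
    d <- discount_factor(t, s$annual_discount_rate, s$cycles_per_year)
    alive <- state != DEATH
    # accrual on the cycle-start state
    cyc_cost <- numeric(n); cyc_qaly <- numeric(n)
    if (any(alive)) {
      st <- state[alive]
      ev <- stats::rbinom(sum(alive), 1L, hosp_p[st])
      cyc_cost[alive] <- monthly_fixed[st] + ev * adm_cost[st]
      cyc_qaly[alive] <- u[st] / 12
    }
    # transition
    r <- stats::runif(n)
    nxt <- state
    for (i in ALIVE) {
      sel <- state == i
      if (any(sel))
        nxt[sel] <- 1L + rowSums(outer(r[sel], cum[i, ], ">"))
    }
    if (half) {
      alive2 <- nxt != DEATH
      cyc2_cost <- numeric(n); cyc2_qaly <- numeric(n)
      if (any(alive2)) {
        st2 <- nxt[alive2]
        ev2 <- stats::rbinom(sum(alive2), 1L, hosp_p[st2])
        cyc2_cost[alive2] <- monthly_fixed[st2] + ev2 * adm_cost[st2]
        cyc2_qaly[alive2] <- u[st2] / 12
      }
      cyc_cost <- (cyc_cost + cyc2_cost) / 2
      cyc_qaly <- (cyc_qaly + cyc2_qaly) / 2
    }
    cost <- cost + d * cyc_cost
    qaly <- qaly + d * cyc_qaly
    state <- nxt
  }

  denom <- switch(s$annualization, per_horizon_year = s$horizon_years,
                  per_life_year = NA_real_)
  out <- list(cost = mean(cost), qaly = mean(qaly),
              cost_se = stats::sd(cost) / sqrt(n),
              qaly_se = stats::sd(qaly) / sqrt(n),
              annualized_cost = if (is.na(denom)) NA_real_ else
                mean(cost) / denom,
              annualized_qaly = if (is.na(denom)) NA_real_ else
                mean(qaly) / denom,
              n_patients = n)
  structure(out, class = "hf_microsim")
}

#' @export
print.hf_microsim <- function(x, ...) {
  cat(sprintf(
    "microsimulation (n = %d): cost %.2f (SE %.2f), QALY %.5f (SE %.5f)\n",
    x$n_patients, x$cost, x$cost_se, x$qaly, x$qaly_se))
  invisible(x)
}

#' Parameter-recovery experiment on synthetic instances
#'
#' For each replicate, generates a synthetic instance pair with known true
#' incremental cost and QALYs, runs a PSA around it, and checks that (a) the
#' mean of the cost-effectiveness point cloud recovers the deltas of the
#' model evaluated at the sampling-distribution means within 3 standard
#' errors, and (b) when the intervention is effective, the acceptability
#' curve crosses 0.5 near the true ICER.
#'
#' @param config a [synthetic_config()].
#' @param n_replicates number of synthetic instance pairs.
#' @param seed integer seed.
#' @param n_draws PSA draws per replicate.
#' @return An `hf_recovery` data frame, one row per replicate, with true and
#'   recovered deltas, their standard errors, the CEAC 0.5 crossing, and
#'   pass flags.
#' @export
parameter_recovery_experiment <- function(config = synthetic_config(),
                                          n_replicates = 5, seed = 1,
                                          n_draws = 400) {
  rows <- lapply(seq_len(n_replicates), function(k) {
    inst <- random_model_instance(config, seed = seed + k)
    truth <- markov_cea(inst$ch, inst$dt, normalize = "none")

    psa <- run_psa(inst$ch, inst$dt, inst$ranges, n_iterations = n_draws,
                   seed = seed + 1000L + k, normalize = "none",
                   utility_envelope = NULL)
    # reference point: model evaluated at the sampling-distribution means
    at_means <- psa_mean_reference(inst$ch, inst$dt, inst$ranges)

    md_c <- mean(psa$delta_cost); se_c <- stats::sd(psa$delta_cost) / sqrt(n_draws)
    md_e <- mean(psa$delta_qaly); se_e <- stats::sd(psa$delta_qaly) / sqrt(n_draws)
    wtp_max <- if (is.finite(truth$icer)) 5 * abs(truth$icer) + 1e5 else 1e6
    cc <- ceac(psa, wtp_grid = seq(0, wtp_max, length.out = 400))
    cross <- if (all(cc$probability > 0.5)) 0 else
      cc$wtp[which(cc$probability > 0.5)[1]]
    neutral <- truth$delta_qaly == 0 && truth$delta_cost == 0
    data.frame(replicate = k,
               true_delta_cost = truth$delta_cost,
               true_delta_qaly = truth$delta_qaly,
               true_icer = truth$icer,
               ref_delta_cost = at_means["cost"],
               ref_delta_qaly = at_means["qaly"],
               mean_delta_cost = md_c, se_delta_cost = se_c,
               mean_delta_qaly = md_e, se_delta_qaly = se_e,
               ceac_half_crossing = if (length(cross)) cross else NA_real_,
               no_effect = neutral,
               cost_recovered = abs(md_c - at_means["cost"]) <= 3 * se_c,
               qaly_recovered = abs(md_e - at_means["qaly"]) <= 3 * se_e)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("hf_recovery", "data.frame"))
}

# Deltas of the model evaluated at the PSA sampling-distribution means
# (gamma means = base costs, beta means = base utilities, lognormal mean =
# median * exp(sigma^2 / 2) for the risk ratio).
psa_mean_reference <- function(ch, dt, ranges, normalize = "none") {
  rrr <- ranges[ranges$group == "hospitalization_rr", ]
  sigma <- (log(rrr$high) - log(rrr$low)) / (2 * 1.96)
  rr_mean <- dt$hosp$risk_ratio * exp(sigma^2 / 2)
  dt$hosp$monthly_prob <- pmin(ch$hosp$monthly_prob * rr_mean, 1)
  fit <- markov_cea(ch, dt, normalize = normalize)
  c(cost = fit$delta_cost, qaly = fit$delta_qaly)
}
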