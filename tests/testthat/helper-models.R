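# Shared fixtures and independent oracles for the test suite.

# Two-state toy embedded in the five-state frame: one alive state with
# stay-probability `s`, the rest of the mass going to death. Unit utility,
# zero costs unless given.
toy_instance <- function(stay = 0.9, cycles = 12L, rate = 0,
                         utility = 1, monthly_cost = 0) {
  P <- diag(5)
  P[1, 1] <- stay; P[1, 5] <- 1 - stay
  settings <- economic_settings(annual_discount_rate = rate,
                                cycles = cycles, cycles_per_year = 12L,
                                horizon_years = cycles / 12)
  model_instance(
    "TOY", transition_matrix(P),
    hosp_profile(rep(0, 4)),
    cost_profile(rep(0, 4), rep(monthly_cost * 12, 4), rep(0, 4), 0),
    utility_profile(c(utility, 0.5, 0.5, 0.5), rep(0.01, 4)),
    cohort_spec(c(1, 0, 0, 0, 0)), settings)
}

# Deliberately independent accrual implementation: naive per-cycle loops over
# states, no shared code with the engine. Guards against a bug common to the
# cohort engine and the microsimulation (which share the accrual formulas).
independent_accrual <- function(instance, normalize = "adjust_diagonal") {
  s <- instance$settings
  P <- unclass(instance$transition)
  if (normalize == "adjust_diagonal") {
    for (i in 1:4) P[i, i] <- P[i, i] + (1 - sum(P[i, ]))
  } else if (normalize == "proportional") {
    P <- P / rowSums(P)
  }
  occ <- as.numeric(instance$cohort$initial_counts)
  cost <- 0; qaly <- 0
  for (t in seq_len(s$cycles)) {
    d <- (1 + s$annual_discount_rate)^(-(t - 1) / s$cycles_per_year)
    start <- occ
    occ <- as.numeric(occ %*% P)
    w <- if (s$half_cycle) (start + occ) / 2 else start
    for (i in 1:4) {
      monthly <- (instance$costs$direct_nonmedical_annual[i] +
                    instance$costs$indirect_annual[i] +
                    instance$costs$dtx_annual) / 12 +
        instance$hosp$monthly_prob[i] *
          instance$costs$direct_medical_per_admission[i]
      cost <- cost + d * w[i] * monthly
      qaly <- qaly + d * w[i] * instance$utilities$mean[i] / 12
    }
  }
  n0 <- sum(instance$cohort$initial_counts)
  c(cost = cost / n0, qaly = qaly / n0)
}

paper_fixture <- hf_paper_model()
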