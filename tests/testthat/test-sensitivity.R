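test_that("gamma moment fit reproduces its source mean and range-derived SD", {
  fit <- fit_gamma_from_mean_range(180, 144, 216)
  expect_equal(fit$sd, 72 / (2 * 1.96), tolerance = 1e-12)
  expect_equal(fit$shape, 180^2 / fit$sd^2, tolerance = 1e-12)
  expect_equal(fit$shape, 96.04, tolerance = 1e-4)
  expect_equal(fit$scale, fit$sd^2 / 180, tolerance = 1e-12)
  expect_equal(fit$scale, 1.8742, tolerance = 1e-4)
  # fitted moments round-trip to 1e-9
  expect_equal(fit$shape * fit$scale, 180, tolerance = 1e-9)
  expect_equal(sqrt(fit$shape) * fit$scale, fit$sd, tolerance = 1e-9)

  expect_error(fit_gamma_from_mean_range(-1, 0, 1), "positive")
  expect_error(fit_gamma_from_mean_range(180, 216, 144), "low")

  near <- fit_gamma_from_mean_range(180, 180 - 1e-13, 180 + 1e-13)
  expect_true(near$near_deterministic)
  expect_identical(sample_fit(near, 3L), rep(180, 3))

  set.seed(5)
  draws <- sample_fit(fit, 1e5)
  se <- fit$sd / sqrt(1e5)
  expect_lt(abs(mean(draws) - 180), 3 * se)
})

test_that("beta moment fit matches the stated formulas and round-trips", {
  fit <- fit_beta_from_mean_variance(0.87976, 0.00827)
  k <- 0.87976 * (1 - 0.87976) / 0.00827 - 1
  expect_equal(fit$alpha, 0.87976 * k, tolerance = 1e-12)
  expect_equal(fit$beta, (1 - 0.87976) * k, tolerance = 1e-12)
  m <- fit$alpha / (fit$alpha + fit$beta)
  v <- fit$alpha * fit$beta /
    ((fit$alpha + fit$beta)^2 * (fit$alpha + fit$beta + 1))
  expect_equal(m, 0.87976, tolerance = 1e-9)
  expect_equal(v, 0.00827, tolerance = 1e-9)

  sym <- fit_beta_from_mean_variance(0.5, 0.05)
  expect_equal(sym$alpha, 2, tolerance = 1e-12)
  expect_equal(sym$beta, 2, tolerance = 1e-12)

  expect_error(fit_beta_from_mean_variance(0.5, 0.3), "infeasible")
  expect_error(fit_beta_from_mean_variance(1.2, 0.01), "mean in")
})

test_that("lognormal fit preserves the median exactly", {
  fit <- fit_lognormal_from_median_range(0.75, 0.36, 0.85)
  expect_equal(fit$meanlog, log(0.75), tolerance = 1e-15)
  expect_equal(fit$sdlog, log(0.85 / 0.36) / (2 * 1.96), tolerance = 1e-15)
  expect_equal(exp(fit$meanlog), 0.75, tolerance = 1e-12)

  set.seed(7)
  draws <- sample_fit(fit, 1e5)
  # median SE ~ 1.2533 * sd / sqrt(n) for the lognormal near its center
  expect_lt(abs(stats::median(draws) - 0.75), 0.01)
  expect_error(fit_lognormal_from_median_range(0.75, -1, 2), "positive")
})

test_that("group substitution touches the right fields in the right arms", {
  pm <- paper_fixture
  m <- set_group_value(pm$ch, pm$dt, "dtx_cost", 216)
  expect_identical(m$dt$costs$dtx_annual, 216)
  expect_identical(m$ch$costs$dtx_annual, 0)

  m2 <- set_group_value(pm$ch, pm$dt, "indirect", c(1, 2, 3, 4))
  expect_equal(m2$ch$costs$indirect_annual, c(1, 2, 3, 4))
  expect_equal(m2$dt$costs$indirect_annual, c(1, 2, 3, 4))

  m3 <- set_group_value(pm$ch, pm$dt, "hospitalization_rr", 0.36)
  expect_equal(m3$dt$hosp$monthly_prob, pm$ch$hosp$monthly_prob * 0.36)
  expect_identical(m3$ch$hosp$monthly_prob, pm$ch$hosp$monthly_prob)

  m4 <- set_group_value(pm$ch, pm$dt, "utility", 0.66)
  expect_equal(m4$dt$utilities$mean, rep(0.66, 4))

  expect_error(set_group_value(pm$ch, pm$dt, "nonsense", 1), "unknown")
})

test_that("one-way sensitivity brackets the base case and collapses at base values", {
  pm <- paper_fixture
  base <- markov_cea(pm$ch, pm$dt)

  # base-value bounds give zero swing
  e0 <- one_way_sensitivity(pm$ch, pm$dt, "dtx_cost", 180, 180)
  expect_equal(e0$swing, 0, tolerance = 1e-12)
  expect_equal(e0$icer_at_low, base$icer, tolerance = 1e-9)

  # DTx fee only shifts the intervention's cost: ICER monotone, bracketing
  e <- one_way_sensitivity(pm$ch, pm$dt, "dtx_cost", 144, 216)
  expect_true(e$icer_at_low < base$icer && base$icer < e$icer_at_high)
  # effectiveness fixed: swing equals the fee span times the discounted
  # per-capita alive-time weight over the incremental QALYs
  fee_weight <- (one_way_sensitivity(pm$ch, pm$dt, "dtx_cost", 180,
                                     192)$swing) / 12
  expect_equal(e$swing, fee_weight * 72, tolerance = 1e-6)
})

test_that("the tornado is swing-sorted with the DTx fee least influential", {
  pm <- paper_fixture
  tor <- tornado(pm$ch, pm$dt, pm$ranges)
  expect_setequal(tor$group,
                  c("direct_medical", "direct_nonmedical", "indirect",
                    "dtx_cost", "utility", "hospitalization_rr"))
  expect_true(all(diff(tor$swing) <= 1e-12))
  expect_true(all(tor$swing >= 0))
  expect_identical(tor$group[nrow(tor)], "dtx_cost")

  # over the five published tornado groups (the published figure carries no
  # utility bar), the cost groups rank indirect > direct medical >
  # direct non-medical > DTx fee, and the risk ratio is a top-two driver
  tor5 <- tornado(pm$ch, pm$dt,
                  pm$ranges[pm$ranges$group != "utility", ])
  pos <- match(c("indirect", "direct_medical", "direct_nonmedical",
                 "dtx_cost"), tor5$group)
  expect_true(all(diff(pos) > 0))
  expect_true(match("hospitalization_rr", tor5$group) <= 2L)
})

test_that("two-way grids are consistent with sequential one-parameter substitution", {
  pm <- paper_fixture
  base <- markov_cea(pm$ch, pm$dt)

  # 1x1 grid at base values reproduces the base ICER
  g0 <- two_way_sensitivity(pm$ch, pm$dt, "dtx_cost", 180, "utility",
                            list(pm$ch$utilities$mean))
  expect_equal(as.numeric(g0), base$icer, tolerance = 1e-12)

  r_ind <- pm$ranges[pm$ranges$group == "indirect", ]
  g <- two_way_sensitivity(pm$ch, pm$dt, "dtx_cost", c(144, 216),
                           "indirect", list(r_ind$low, r_ind$high))
  for (i in 1:2) for (j in 1:2) {
    m1 <- set_group_value(pm$ch, pm$dt, "dtx_cost", c(144, 216)[i])
    m2 <- set_group_value(m1$ch, m1$dt, "indirect",
                          list(r_ind$low, r_ind$high)[[j]])
    expect_equal(g[i, j], markov_cea(m2$ch, m2$dt)$icer, tolerance = 1e-12)
  }
  # ICER increases with the DTx fee at fixed everything else
  expect_true(all(g[2, ] > g[1, ]))
})

test_that("PSA draws are reproducible, in-support, and collapse to the base case", {
  pm <- paper_fixture
  p1 <- run_psa(pm$ch, pm$dt, pm$ranges, n_iterations = 200, seed = 42)
  p2 <- run_psa(pm$ch, pm$dt, pm$ranges, n_iterations = 200, seed = 42)
  expect_identical(p1$delta_cost, p2$delta_cost)
  expect_identical(p1$delta_qaly, p2$delta_qaly)

  s <- attr(p1, "samples")
  expect_true(all(s[paste0("u", 1:4)] >= 0 & s[paste0("u", 1:4)] <= 1))
  expect_true(all(s[c(paste0("dm", 1:4), "dtx")] >= 0))
  expect_true(all(s$rr > 0))
  # envelope truncation applies to the states whose means lie inside it
  expect_true(all(s$u1 >= 0.66 & s$u1 <= 0.96))
  expect_true(all(s$u2 >= 0.66 & s$u2 <= 0.96))

  base <- markov_cea(pm$ch, pm$dt)
  pc <- run_psa(pm$ch, pm$dt, pm$ranges, n_iterations = 3, seed = 1,
                collapse = TRUE)
  expect_equal(pc$delta_cost, rep(base$delta_cost, 3), tolerance = 1e-12)
  expect_equal(pc$delta_qaly, rep(base$delta_qaly, 3), tolerance = 1e-12)

  # a PSA draw evaluated through the weight shortcut equals a full
  # re-evaluation of modified instances through the engine
  set.seed(9)
  dtx <- 200; u <- c(0.8, 0.7, 0.6, 0.5); rr <- 0.6
  m <- set_group_value(pm$ch, pm$dt, "hospitalization_rr", rr)
  m <- set_group_value(m$ch, m$dt, "utility", u)
  m$dt$costs$dtx_annual <- dtx
  full <- markov_cea(m$ch, m$dt)
  w_ch <- hfcea:::strategy_weights(pm$ch, "adjust_diagonal")
  w_dt <- hfcea:::strategy_weights(pm$dt, "adjust_diagonal")
  a_ch <- hfcea:::accrue_from_weights(w_ch, m$ch$costs,
                                      m$ch$hosp$monthly_prob, u)
  a_dt <- hfcea:::accrue_from_weights(w_dt, m$dt$costs,
                                      m$dt$hosp$monthly_prob, u)
  expect_equal(a_dt[["cost"]] - a_ch[["cost"]], full$delta_cost,
               tolerance = 1e-9)
  expect_equal(a_dt[["qaly"]] - a_ch[["qaly"]], full$delta_qaly,
               tolerance = 1e-12)
})

test_that("simulate() on a fitted comparison runs the PSA", {
  pm <- paper_fixture
  fit <- markov_cea(pm$ch, pm$dt)
  sim <- simulate(fit, nsim = 50, seed = 3, ranges = pm$ranges)
  expect_s3_class(sim, "hf_psa")
  expect_equal(nrow(sim), 50L)
  direct <- run_psa(pm$ch, pm$dt, pm$ranges, n_iterations = 50, seed = 3)
  expect_identical(sim$delta_cost, direct$delta_cost)
})

test_that("the CE-plane cloud mean matches the model at the distribution means", {
  pm <- paper_fixture
  n <- 4000
  psa <- run_psa(pm$ch, pm$dt, pm$ranges, n_iterations = n, seed = 13,
                 utility_envelope = NULL)
  ref <- hfcea:::psa_mean_reference(pm$ch, pm$dt, pm$ranges,
                                    normalize = "adjust_diagonal")
  se_c <- stats::sd(psa$delta_cost) / sqrt(n)
  se_e <- stats::sd(psa$delta_qaly) / sqrt(n)
  expect_lt(abs(mean(psa$delta_cost) - ref["cost"]), 3 * se_c)
  expect_lt(abs(mean(psa$delta_qaly) - ref["qaly"]), 3 * se_e)
})

test_that("CEAC endpoints follow their definitional identities", {
  pm <- paper_fixture
  psa <- run_psa(pm$ch, pm$dt, pm$ranges, n_iterations = 500, seed = 8,
                 arm_draws = "independent")
  cc <- ceac(psa, wtp_grid = c(0, 85698, 1e9))
  expect_equal(cc$probability[1], mean(psa$delta_cost < 0))
  expect_equal(cc$probability[3], mean(psa$delta_qaly > 0))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_error(ceac(data.frame()), "empty")

  # default grid covers both decision thresholds
  cc_def <- ceac(psa)
  expect_true(all(c(85698, 257094) >= min(cc_def$wtp) &
                    c(85698, 257094) <= max(cc_def$wtp)))
})
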