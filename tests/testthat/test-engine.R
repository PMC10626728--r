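test_that("cohort propagation matches hand arithmetic and closed forms", {
  pm <- paper_fixture

  # identity matrix: occupancy is constant
  tr_id <- run_cohort(transition_matrix(diag(5)), pm$ch$cohort, 120)
  expect_true(all(apply(unclass(tr_id), 2, function(col)
    all(col == col[1]))))

  # two-state toy: survival after 12 cycles is 0.9^12
  toy <- toy_instance(stay = 0.9, cycles = 12L)
  tr <- run_cohort(toy$transition, toy$cohort, 12)
  expect_equal(unclass(tr)[13, 1], 0.9^12, tolerance = 1e-14)
  expect_equal(0.9^12, 0.282429536481, tolerance = 1e-12)

  # one-step arithmetic from the published matrix: NYHA I at cycle 1 gathers
  # stayers plus improvers from NYHA II and III
  expected <- 1795 * 0.981 + 172 * 0.068 + 280 * 0.004
  tr_ch <- run_cohort(pm$ch$transition, pm$ch$cohort, 2)
  expect_equal(unclass(tr_ch)[2, 1], expected, tolerance = 1e-12)
})

test_that("cohort traces conserve mass and death is monotone", {
  pm <- paper_fixture
  for (seed in 1:5) {
    inst <- random_model_instance(seed = seed)
    tr <- run_cohort(inst$ch$transition, inst$ch$cohort, 120)
    sums <- rowSums(unclass(tr))
    expect_true(all(abs(sums - inst$ch$cohort$size) < 1e-9))
    expect_true(all(diff(unclass(tr)[, 5]) >= -1e-12))
    expect_true(all(unclass(tr) >= -1e-12))
  }
  tr <- run_cohort(normalize_rows(pm$dt$transition), pm$dt$cohort, 120)
  expect_true(all(abs(rowSums(unclass(tr)) - 2315) < 1e-9))
})

test_that("non-stochastic matrices are rejected by the cohort engine", {
  pm <- paper_fixture
  expect_error(run_cohort(pm$dt$transition, pm$dt$cohort, 12),
               "row-stochastic")
})

test_that("discount factors follow the first-cycle-undiscounted convention", {
  expect_identical(discount_factor(1, 0.03, 12), 1)
  expect_equal(discount_factor(13, 0.03, 12), 1 / 1.03, tolerance = 1e-15)
  expect_identical(discount_factor(c(1, 7, 50), 0, 12), c(1, 1, 1))
  expect_equal(discount_factor(121, 0.03, 12), 1.03^-10, tolerance = 1e-15)
  expect_error(discount_factor(5, -0.01), ">= 0")
})

test_that("cycle accrual reproduces hand-computed costs and QALYs", {
  pm <- paper_fixture
  one_in_I <- c(1, 0, 0, 0, 0)

  ch_cost <- accrue_cycle_cost(one_in_I, pm$ch$costs, pm$ch$hosp)
  expect_equal(ch_cost, (1012.25 + 45720) / 12 + 0.004 * 35587.73,
               tolerance = 1e-12)
  expect_equal(ch_cost, 4036.705087, tolerance = 1e-9)

  dt_cost <- accrue_cycle_cost(one_in_I, pm$dt$costs, pm$dt$hosp)
  expect_equal(dt_cost, (1012.25 + 45720 + 180) / 12 + 0.003 * 35587.73,
               tolerance = 1e-12)

  # everyone dead: nothing accrues
  expect_identical(accrue_cycle_cost(c(0, 0, 0, 0, 2315), pm$ch$costs,
                                     pm$ch$hosp), 0)
  expect_identical(accrue_cycle_qaly(c(0, 0, 0, 0, 10), pm$ch$utilities), 0)

  expect_equal(accrue_cycle_qaly(one_in_I, pm$ch$utilities), 0.87976 / 12,
               tolerance = 1e-15)
  expect_identical(accrue_cycle_qaly(rep(0, 5), pm$ch$utilities), 0)

  expect_error(accrue_cycle_cost(c(-1, 0, 0, 0, 0), pm$ch$costs,
                                 pm$ch$hosp), "negative")
})

test_that("a year spent in one state accrues that state's utility", {
  # 12 undiscounted cycles fully in NYHA II with no mortality
  P <- diag(5)
  inst <- toy_instance(stay = 1, cycles = 12L, rate = 0)
  inst$transition <- transition_matrix(P)
  inst$cohort <- cohort_spec(c(0, 1, 0, 0, 0))
  inst$utilities <- paper_fixture$ch$utilities
  res <- evaluate_strategy(inst, normalize = "none")
  expect_equal(res$total_qaly, 0.71178, tolerance = 1e-12)
})

test_that("strategy evaluation matches the geometric-series closed form", {
  # survival s per cycle, unit utility, zero discounting, 12 cycles:
  # QALY = sum_t s^(t-1)/12 = (1 - s^12) / (0.1 * 12)
  toy <- toy_instance(stay = 0.9, cycles = 12L, rate = 0)
  res <- evaluate_strategy(toy, normalize = "none")
  expect_equal(res$total_qaly, (1 - 0.9^12) / (0.1 * 12), tolerance = 1e-12)
  expect_equal(res$annualized_qaly, 0.597975386, tolerance = 1e-9)

  # with discounting: geometric series in s * d, checked to 1e-12
  toy3 <- toy_instance(stay = 0.9, cycles = 120L, rate = 0.03)
  res3 <- evaluate_strategy(toy3, normalize = "none")
  x <- 0.9 / 1.03^(1 / 12)
  expect_equal(res3$total_qaly, (1 - x^120) / (1 - x) / 12,
               tolerance = 1e-12)
  expect_equal(res3$life_years, res3$total_qaly, tolerance = 1e-12)

  # zero-utility, zero-cost instance accrues nothing
  toy0 <- toy_instance(stay = 0.9, cycles = 12L, utility = 0)
  res0 <- evaluate_strategy(toy0, normalize = "none")
  expect_identical(res0$total_cost, 0)
  expect_identical(res0$total_qaly, 0)
})

test_that("strategy totals equal their per-cycle sums and respect discounting", {
  pm <- paper_fixture
  res <- evaluate_strategy(pm$ch)
  expect_equal(res$total_cost, sum(res$per_cycle_cost), tolerance = 1e-9)
  expect_equal(res$total_qaly, sum(res$per_cycle_qaly), tolerance = 1e-9)

  undisc <- pm$ch
  undisc$settings <- economic_settings(annual_discount_rate = 0)
  res0 <- evaluate_strategy(undisc)
  expect_true(res$total_cost < res0$total_cost)
  expect_true(res$total_qaly < res0$total_qaly)

  # agreement with the independent accrual implementation
  for (inst in list(pm$ch, pm$dt)) {
    ref <- independent_accrual(inst, "adjust_diagonal")
    got <- evaluate_strategy(inst, "adjust_diagonal")
    expect_equal(got$total_cost, unname(ref["cost"]), tolerance = 1e-10)
    expect_equal(got$total_qaly, unname(ref["qaly"]), tolerance = 1e-10)
  }
  hc <- pm$dt
  hc$settings$half_cycle <- TRUE
  ref <- independent_accrual(hc, "proportional")
  got <- evaluate_strategy(hc, "proportional")
  expect_equal(got$total_cost, unname(ref["cost"]), tolerance = 1e-10)
  expect_equal(got$total_qaly, unname(ref["qaly"]), tolerance = 1e-10)
})

test_that("total QALYs respond monotonically to utilities, mortality and discounting", {
  base <- random_model_instance(seed = 11)$ch

  # raising one utility never decreases total QALYs
  up <- base
  up$utilities$mean[2] <- min(1, up$utilities$mean[2] + 0.1)
  expect_gte(evaluate_strategy(up, "none")$total_qaly,
             evaluate_strategy(base, "none")$total_qaly)

  # raising a state's death probability (renormalized) never increases QALYs
  worse <- base
  P <- unclass(worse$transition)
  P[1, 5] <- P[1, 5] + 0.05
  P[1, ] <- P[1, ] / sum(P[1, ])
  worse$transition <- transition_matrix(P)
  expect_lte(evaluate_strategy(worse, "none")$total_qaly,
             evaluate_strategy(base, "none")$total_qaly)

  # discounted totals are non-increasing in the discount rate
  rates <- c(0, 0.01, 0.03, 0.08)
  vals <- sapply(rates, function(r) {
    m <- base
    m$settings <- economic_settings(annual_discount_rate = r)
    res <- evaluate_strategy(m, "none")
    c(res$total_cost, res$total_qaly)
  })
  expect_true(all(diff(vals[1, ]) <= 1e-12))
  expect_true(all(diff(vals[2, ]) <= 1e-12))
})

test_that("trace export carries occupancies, discount factors and accruals", {
  res <- evaluate_strategy(paper_fixture$ch)
  tab <- trace_table(res)
  expect_equal(nrow(tab), 121L)
  expect_equal(tab$cycle[1], 0)
  expect_true(is.na(tab$cycle_cost[1]))
  expect_equal(sum(tab$cycle_cost, na.rm = TRUE), res$total_cost,
               tolerance = 1e-9)
  expect_equal(tab$discount[2], 1)
})
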