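#' Fit a gamma distribution from a mean and a 95% range
#'
#' Cost parameters are given as a base value with a published variation
#' range. The range is read as a 95% interval, so `SD = (high - low) / (2 *
#' 1.96)`, and the gamma is fitted by moments: `shape = mean^2 / SD^2`,
#' `scale = SD^2 / mean`. The fitted mean equals the input mean exactly.
#'
#' @param mean base (mean) value, > 0.
#' @param low,high range bounds, `low < high`.
#' @return A `distribution_fit` (family `"gamma"`).
#' @export
fit_gamma_from_mean_range <- function(mean, low, high) {
  if (mean <= 0) stop("gamma fit requires a positive mean")
  if (low >= high) stop("low must be < high")
  sd <- (high - low) / (2 * 1.96)
  structure(list(family = "gamma",
                 shape = mean^2 / sd^2, scale = sd^2 / mean,
                 mean = mean, sd = sd,
                 near_deterministic = sd < 1e-12 * mean,
                 source = list(mean = mean, low = low, high = high)),
            class = "distribution_fit")
}

#' Fit a beta distribution from a mean and variance
#'
#' Method of moments for utilities: with
#' `k = mean * (1 - mean) / variance - 1`, `alpha = mean * k` and
#' `beta = (1 - mean) * k`. The fitted mean and variance equal the inputs
#' exactly; the variance must be below `mean * (1 - mean)` for the fit to be
#' feasible.
#'
#' @param mean utility mean in (0, 1).
#' @param variance utility variance in (0, mean * (1 - mean)).
#' @return A `distribution_fit` (family `"beta"`).
#' @export
fit_beta_from_mean_variance <- function(mean, variance) {
  if (mean <= 0 || mean >= 1) stop("beta fit requires mean in (0, 1)")
  if (variance <= 0 || variance >= mean * (1 - mean))
    stop("infeasible beta: variance must be in (0, mean * (1 - mean))")
  k <- mean * (1 - mean) / variance - 1
  structure(list(family = "beta",
                 alpha = mean * k, beta = (1 - mean) * k,
                 mean = mean, variance = variance,
                 source = list(mean = mean, variance = variance)),
            class = "distribution_fit")
}

#' Fit a lognormal distribution from a median and a 95% range
#'
#' Used for hospitalization risk ratios: `mu = log(median)` (the lognormal
#' median is preserved exactly) and
#' `sigma = (log(high) - log(low)) / (2 * 1.96)`.
#'
#' @param median base (median) value, > 0.
#' @param low,high positive range bounds, `low < high`.
#' @return A `distribution_fit` (family `"lognormal"`).
#' @export
fit_lognormal_from_median_range <- function(median, low, high) {
  if (median <= 0 || low <= 0) stop("lognormal fit requires positive values")
  if (low >= high) stop("low must be < high")
  structure(list(family = "lognormal",
                 meanlog = log(median),
                 sdlog = (log(high) - log(low)) / (2 * 1.96),
                 median = median,
                 source = list(median = median, low = low, high = high)),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  p <- switch(x$family,
              gamma = sprintf("shape %.4f, scale %.4f (mean %.4f, sd %.4f)",
                              x$shape, x$scale, x$mean, x$sd),
              beta = sprintf("alpha %.4f, beta %.4f (mean %.5f, var %.5f)",
                             x$alpha, x$beta, x$mean, x$variance),
              lognormal = sprintf("meanlog %.5f, sdlog %.5f (median %.4f)",
                                  x$meanlog, x$sdlog, x$median))
  cat(sprintf("%s fit: %s\n", x$family, p))
  invisible(x)
}

#' Draw random variates from a distribution fit
#'
#' @param fit a `distribution_fit`.
#' @param n number of draws.
#' @return Numeric vector of length `n` (degenerate gamma fits return the
#'   mean).
#' @export
sample_fit <- function(fit, n) {
  switch(fit$family,
         gamma = if (isTRUE(fit$near_deterministic)) rep(fit$mean, n)
                 else stats::rgamma(n, shape = fit$shape, scale = fit$scale),
         beta = stats::rbeta(n, fit$alpha, fit$beta),
         lognormal = stats::rlnorm(n, fit$meanlog, fit$sdlog),
         stop("unknown distribution family"))
}

PARAM_GROUPS <- c("direct_medical", "direct_nonmedical", "indirect",
                  "dtx_cost", "hospitalization_rr", "utility")

#' Substitute one parameter group's value into both arms
#'
#' Cost and utility groups are shared across arms; the DTx fee applies to the
#' intervention arm only; the hospitalization risk ratio regenerates the
#' intervention arm's admission probabilities as
#' `pmin(CH probability * RR, 1)`.
#'
#' @param ch,dt the two `hf_model` arms.
#' @param group one of `"direct_medical"`, `"direct_nonmedical"`,
#'   `"indirect"`, `"dtx_cost"`, `"hospitalization_rr"`, `"utility"`.
#' @param value scalar (recycled over the four alive states where the group
#'   is per-state) or length-4 vector.
#' @return List with modified `ch` and `dt`.
#' @export
set_group_value <- function(ch, dt, group, value) {
  if (!group %in% PARAM_GROUPS)
    stop(sprintf("unknown parameter group '%s'", group))
  as4 <- function(v) if (length(v) == 1L) rep(v, 4L) else {
    stopifnot(length(v) == 4L); as.numeric(v)
  }
  field <- switch(group,
                  direct_medical = "direct_medical_per_admission",
                  direct_nonmedical = "direct_nonmedical_annual",
                  indirect = "indirect_annual", NULL)
  if (!is.null(field)) {
    ch$costs[[field]] <- as4(value)
    dt$costs[[field]] <- as4(value)
  } else if (group == "dtx_cost") {
    dt$costs$dtx_annual <- as.numeric(value)[1L]
  } else if (group == "utility") {
    ch$utilities$mean <- as4(value)
    dt$utilities$mean <- as4(value)
  } else { # hospitalization_rr
    rr <- as4(value)
    dt$hosp$risk_ratio <- rr
    dt$hosp$monthly_prob <- pmin(ch$hosp$monthly_prob * rr, 1)
  }
  list(ch = ch, dt = dt)
}

#' One-way sensitivity of the ICER to a parameter group
#'
#' Sets every state's value in the group to its low (resp. high) bound
#' simultaneously, re-evaluates both arms, and records the two ICERs and
#' their absolute swing.
#'
#' @param ch,dt the two `hf_model` arms.
#' @param group parameter group (see [set_group_value()]).
#' @param low,high bound values (scalar or per-state length 4).
#' @param normalize transition-row repair mode.
#' @return A `tornado_entry` list: `group`, `icer_at_low`, `icer_at_high`,
#'   `swing`.
#' @export
one_way_sensitivity <- function(ch, dt, group, low, high,
                                normalize = "adjust_diagonal") {
  icer_at <- function(v) {
    m <- set_group_value(ch, dt, group, v)
    markov_cea(m$ch, m$dt, normalize)$icer
  }
  il <- icer_at(low); ih <- icer_at(high)
  structure(list(group = group, icer_at_low = il, icer_at_high = ih,
                 swing = abs(ih - il)), class = "tornado_entry")
}

#' Tornado analysis over every parameter group
#'
#' Runs [one_way_sensitivity()] for each group in a ranges table (as produced
#' by [hf_paper_model()]) and sorts by decreasing swing. Groups without
#' per-state bounds (utility, hospitalization risk ratio) use their single
#' global range.
#'
#' @param ch,dt the two `hf_model` arms.
#' @param ranges data frame with columns `group`, `state`, `low`, `high`.
#' @param normalize transition-row repair mode.
#' @return An `hf_tornado` data frame (`group`, `icer_at_low`,
#'   `icer_at_high`, `swing`), sorted descending by swing, with the base-case
#'   ICER as attribute `base_icer`.
#' @export
tornado <- function(ch, dt, ranges, normalize = "adjust_diagonal") {
  rows <- lapply(unique(ranges$group), function(g) {
    r <- ranges[ranges$group == g, ]
    e <- one_way_sensitivity(ch, dt, g, r$low, r$high, normalize)
    data.frame(group = g, icer_at_low = e$icer_at_low,
               icer_at_high = e$icer_at_high, swing = e$swing)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  structure(out, class = c("hf_tornado", "data.frame"),
            base_icer = markov_cea(ch, dt, normalize)$icer)
}

#' @export
plot.hf_tornado <- function(x, ...) {
  y <- x[rev(seq_len(nrow(x))), ]
  base <- attr(x, "base_icer")
  rng <- range(c(y$icer_at_low, y$icer_at_high, base))
  graphics::plot(NA, xlim = rng, ylim = c(0.5, nrow(y) + 0.5), yaxt = "n",
                 xlab = "ICER (CNY/QALY)", ylab = "", main = "Tornado", ...)
  graphics::axis(2, at = seq_len(nrow(y)), labels = y$group, las = 1,
                 cex.axis = 0.8)
  for (i in seq_len(nrow(y)))
    graphics::rect(min(y$icer_at_low[i], y$icer_at_high[i]), i - 0.35,
                   max(y$icer_at_low[i], y$icer_at_high[i]), i + 0.35,
                   col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Two-way sensitivity of the ICER to two parameter groups
#'
#' Evaluates the ICER on the full cartesian grid of two groups' values.
#'
#' @param ch,dt the two `hf_model` arms.
#' @param group1,group2 parameter groups.
#' @param values1,values2 list (or vector) of values for each group; each
#'   element is a scalar or per-state length-4 vector.
#' @param normalize transition-row repair mode.
#' @return Numeric matrix of ICERs, rows indexed by `values1`, columns by
#'   `values2`.
#' @export
two_way_sensitivity <- function(ch, dt, group1, values1, group2, values2,
                                normalize = "adjust_diagonal") {
  if (!is.list(values1)) values1 <- as.list(values1)
  if (!is.list(values2)) values2 <- as.list(values2)
  out <- matrix(NA_real_, length(values1), length(values2),
                dimnames = list(vapply(values1, function(v)
                  paste(v, collapse = "/"), ""), vapply(values2, function(v)
                    paste(v, collapse = "/"), "")))
  for (i in seq_along(values1)) {
    m1 <- set_group_value(ch, dt, group1, values1[[i]])
    for (j in seq_along(values2)) {
      m2 <- set_group_value(m1$ch, m1$dt, group2, values2[[j]])
      out[i, j] <- markov_cea(m2$ch, m2$dt, normalize)$icer
    }
  }
  out
}

# Precompute the discounted per-capita state-time weights of one arm.
# Transitions are not varied in the PSA, so each arm's trace is fixed and the
# draw evaluation reduces to linear accrual over these weights.
strategy_weights <- function(instance, normalize = "adjust_diagonal") {
  s <- instance$settings
  P <- instance$transition
  if (normalize != "none") P <- normalize_rows(P, normalize)
  trace <- run_cohort(P, instance$cohort, s$cycles)
  t_idx <- seq_len(s$cycles)
  disc <- discount_factor(t_idx, s$annual_discount_rate, s$cycles_per_year)
  start <- unclass(trace)[t_idx, , drop = FALSE]
  occ <- if (s$half_cycle)
    (start + unclass(trace)[t_idx + 1L, , drop = FALSE]) / 2 else start
  A <- as.numeric(disc %*% occ[, ALIVE, drop = FALSE]) / instance$cohort$size
  ly <- sum(A) / 12
  denom <- switch(s$annualization, per_horizon_year = s$horizon_years,
                  per_life_year = ly)
  list(A = A, life_years = ly, denom = denom, settings = s)
}

accrue_from_weights <- function(w, costs, hosp_prob, utility_mean) {
  monthly <- (costs$direct_nonmedical_annual + costs$indirect_annual +
                costs$dtx_annual) / 12 +
             hosp_prob * costs$direct_medical_per_admission
  c(cost = sum(w$A * monthly) / w$denom,
    qaly = sum(w$A * utility_mean) / 12 / w$denom)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo re-evaluation of the incremental comparison under parameter
#' uncertainty. Per draw: each cost group is sampled per state from its gamma
#' fit (mean = base value, SD = range/3.92) and shared across arms; the DTx
#' fee is sampled from its gamma fit (intervention arm only); state utilities
#' are sampled from per-state beta fits of the published mean/variance and
#' shared across arms; the hospitalization risk ratio is sampled via a single
#' lognormal deviate scaling all four state risk ratios, and the intervention
#' arm's admission probabilities are regenerated as
#' `pmin(CH probability * RR, 1)`. Transition probabilities are not varied
#' (no published uncertainty). Utility draws for states whose base mean lies
#' inside the global utility envelope are rejection-resampled into it (at
#' most 100 attempts per draw).
#'
#' @param ch,dt the two `hf_model` arms.
#' @param ranges ranges table (see [hf_paper_model()]).
#' @param n_iterations number of Monte Carlo draws.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param normalize transition-row repair mode.
#' @param utility_mode `"per_state"` (independent beta draws per state) or
#'   `"global_quantile"` (one uniform quantile mapped through every state's
#'   beta, i.e. comonotone utilities).
#' @param arm_draws `"shared"` (default): each draw's cost and utility values
#'   are common to both arms, so only the risk ratio and DTx fee
#'   differentiate the arms; `"independent"`: each arm receives its own cost
#'   and utility draws, inflating the spread of the incremental cloud.
#' @param utility_envelope length-2 global plausibility envelope applied to
#'   states whose base mean lies inside it, or `NULL` to disable truncation.
#' @param collapse logical; collapse all distributions to their base values
#'   (every draw then reproduces the base case — a degeneracy check).
#' @return An `hf_psa` data frame with columns `draw`, `delta_cost`,
#'   `delta_qaly`; attributes: `samples` (sampled parameters per draw),
#'   `base` (base-case `markov_cea`), `resamples` (envelope rejection
#'   counts), `seed`, `wtp`.
#' @export
run_psa <- function(ch, dt, ranges, n_iterations = 10000L, seed = NULL,
                    normalize = "adjust_diagonal",
                    utility_mode = c("per_state", "global_quantile"),
                    arm_draws = c("shared", "independent"),
                    utility_envelope = c(0.66, 0.96),
                    collapse = FALSE) {
  utility_mode <- match.arg(utility_mode)
  arm_draws <- match.arg(arm_draws)
  stopifnot(n_iterations >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }

  w_ch <- strategy_weights(ch, normalize)
  w_dt <- strategy_weights(dt, normalize)

  cost_groups <- c("direct_medical", "direct_nonmedical", "indirect")
  cost_fits <- lapply(cost_groups, function(g) {
    r <- ranges[ranges$group == g, ]
    lapply(seq_len(nrow(r)), function(i)
      fit_gamma_from_mean_range(r$base[i], r$low[i], r$high[i]))
  })
  names(cost_fits) <- cost_groups
  rdtx <- ranges[ranges$group == "dtx_cost", ]
  dtx_fit <- if (nrow(rdtx) == 1L && rdtx$base > 0)
    fit_gamma_from_mean_range(rdtx$base, rdtx$low, rdtx$high) else
    list(family = "gamma", mean = dt$costs$dtx_annual,
         near_deterministic = TRUE)
  util_fits <- lapply(ALIVE, function(s)
    fit_beta_from_mean_variance(dt$utilities$mean[s], dt$utilities$variance[s]))
  rrr <- ranges[ranges$group == "hospitalization_rr", ]
  rr_sigma <- (log(rrr$high) - log(rrr$low)) / (2 * 1.96)
  rr_base <- dt$hosp$risk_ratio

  env_states <- if (is.null(utility_envelope)) integer(0) else
    which(dt$utilities$mean >= utility_envelope[1] &
            dt$utilities$mean <= utility_envelope[2])

  n <- as.integer(n_iterations)
  draw_cost <- function(fits) vapply(fits, function(f)
    if (collapse) f$mean else sample_fit(f, 1L), 0)
  resamples <- 0L
  samples <- matrix(NA_real_, n, 18L)
  colnames(samples) <- c(paste0("dm", 1:4), paste0("nm", 1:4),
                         paste0("ind", 1:4), "dtx", paste0("u", 1:4), "rr")
  out_dc <- numeric(n); out_de <- numeric(n)

  draw_utilities <- function() {
    u <- if (collapse) dt$utilities$mean
    else if (utility_mode == "global_quantile") {
      q <- stats::runif(1L)
      vapply(util_fits, function(f) stats::qbeta(q, f$alpha, f$beta), 0)
    } else vapply(util_fits, function(f) sample_fit(f, 1L), 0)
    for (s in env_states) {
      k <- 0L
      while ((u[s] < utility_envelope[1] || u[s] > utility_envelope[2]) &&
               k < 100L) {
        u[s] <- sample_fit(util_fits[[s]], 1L)
        k <- k + 1L
        resamples <<- resamples + 1L
      }
    }
    u
  }
  draw_cost_set <- function(dtx) list(
    direct_medical_per_admission = draw_cost(cost_fits$direct_medical),
    direct_nonmedical_annual = draw_cost(cost_fits$direct_nonmedical),
    indirect_annual = draw_cost(cost_fits$indirect),
    dtx_annual = dtx)

  for (i in seq_len(n)) {
    costs_ch <- draw_cost_set(0)
    dtx <- if (collapse) dtx_fit$mean else sample_fit(dtx_fit, 1L)
    costs_dt <- if (arm_draws == "shared") costs_ch else draw_cost_set(0)
    costs_dt$dtx_annual <- dtx
    u_ch <- draw_utilities()
    u_dt <- if (arm_draws == "shared") u_ch else draw_utilities()

    # collapsed draws keep the arm's stored admission probabilities so that
    # a degenerate PSA reproduces the base case exactly; real draws
    # regenerate them from the sampled risk ratio
    z <- if (collapse) 0 else stats::rnorm(1L)
    rr <- rr_base * exp(rr_sigma * z)
    hosp_dt <- if (collapse) dt$hosp$monthly_prob
               else pmin(ch$hosp$monthly_prob * rr, 1)

    a_ch <- accrue_from_weights(w_ch, costs_ch, ch$hosp$monthly_prob, u_ch)
    a_dt <- accrue_from_weights(w_dt, costs_dt, hosp_dt, u_dt)
    out_dc[i] <- a_dt[["cost"]] - a_ch[["cost"]]
    out_de[i] <- a_dt[["qaly"]] - a_ch[["qaly"]]
    samples[i, ] <- c(costs_dt$direct_medical_per_admission,
                      costs_dt$direct_nonmedical_annual,
                      costs_dt$indirect_annual, dtx, u_dt, rr[1L])
  }

  base <- markov_cea(ch, dt, normalize)
  structure(data.frame(draw = seq_len(n), delta_cost = out_dc,
                       delta_qaly = out_de),
            class = c("hf_psa", "data.frame"),
            samples = as.data.frame(samples), base = base,
            resamples = resamples, seed = seed,
            wtp = ch$settings$wtp)
}

#' @export
print.hf_psa <- function(x, ...) {
  wtp <- attr(x, "wtp")
  acc <- mean(wtp * x$delta_qaly - x$delta_cost > 0)
  cat(sprintf("PSA: %d draws; mean dCost %.2f, mean dQALY %.5f\n",
              nrow(x), mean(x$delta_cost), mean(x$delta_qaly)))
  cat(sprintf("P(cost-effective at WTP %s) = %.1f%%\n",
              format(wtp, big.mark = ","), 100 * acc))
  invisible(x)
}

#' @export
plot.hf_psa <- function(x, wtp = attr(x, "wtp"), ...) {
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = expression(Delta ~ "QALY/yr"),
                 ylab = expression(Delta ~ "cost (CNY/yr)"),
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::abline(0, wtp, lty = 2)
  invisible(x)
}

#' Probabilistic draws from a fitted comparison
#'
#' `simulate()` on a [markov_cea()] object runs the probabilistic
#' sensitivity analysis (see [run_psa()]).
#'
#' @param object a `markov_cea` created by [markov_cea()].
#' @param nsim number of Monte Carlo draws.
#' @param seed integer seed.
#' @param ranges ranges table (see [hf_paper_model()]).
#' @param ... further arguments passed to [run_psa()].
#' @return An `hf_psa` object.
#' @export
simulate.markov_cea <- function(object, nsim = 10000L, seed = NULL,
                                ranges, ...) {
  if (is.null(object$instances))
    stop("simulate() needs a comparison created by markov_cea()")
  run_psa(object$instances$ch, object$instances$dt, ranges,
          n_iterations = nsim, seed = seed,
          normalize = object$normalize, ...)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' incremental net monetary benefit `wtp * dQALY - dCost > 0`.
#'
#' @param points an `hf_psa` (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid willingness-to-pay grid (CNY/QALY); the default spans 0 to
#'   300,000 in 1,000-CNY steps.
#' @return An `hf_ceac` data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(points, wtp_grid = seq(0, 300000, by = 1000)) {
  if (NROW(points) == 0L) stop("empty PSA point set")
  prob <- vapply(wtp_grid, function(w)
    mean(w * points$delta_qaly - points$delta_cost > 0), 0)
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("hf_ceac", "data.frame"))
}

#' @export
plot.hf_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "willingness-to-pay (CNY/QALY)",
                 ylab = "P(intervention cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey")
  invisible(x)
}
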