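#' Incremental cost-effectiveness comparison of two strategy arms
#'
#' The central fitting function of the package: evaluates the comparator
#' ("CH", conventional home-based cardiac rehabilitation) and intervention
#' ("DT", digital therapeutics) Markov models and returns their incremental
#' comparison — per-arm annualized cost and QALYs, incremental cost and
#' QALYs, the incremental cost-effectiveness ratio
#' `ICER = (cost_DT - cost_CH) / (QALY_DT - QALY_CH)`, and a dominance
#' classification. Use [summary()] for net monetary benefit at the
#' willingness-to-pay threshold and [simulate()] for probabilistic
#' sensitivity draws.
#'
#' @param ch comparator `hf_model`.
#' @param dt intervention `hf_model`.
#' @param normalize transition-row repair mode (see [evaluate_strategy()]).
#' @return A `markov_cea` object.
#' @examples
#' pm <- hf_paper_model()
#' fit <- markov_cea(pm$ch, pm$dt)
#' fit
#' summary(fit)
#' @export
markov_cea <- function(ch, dt,
                       normalize = c("adjust_diagonal", "proportional",
                                     "none")) {
  normalize <- match.arg(normalize)
  if (!identical(ch$settings, dt$settings))
    stop("both arms must share identical economic settings")
  if (!identical(ch$cohort, dt$cohort))
    stop("both arms must share the same initial cohort")
  res_ch <- evaluate_strategy(ch, normalize)
  res_dt <- evaluate_strategy(dt, normalize)
  out <- compare_strategies(res_ch, res_dt)
  out$instances <- list(ch = ch, dt = dt)
  out$normalize <- normalize
  out
}

#' Compare two evaluated strategies
#'
#' Lower-level constructor of the incremental comparison from two
#' [evaluate_strategy()] results (annualized per-capita scale).
#'
#' @param ch comparator `strategy_result`.
#' @param dt intervention `strategy_result`.
#' @return A `markov_cea` object with fields `cost_ch`, `cost_dt`, `qaly_ch`,
#'   `qaly_dt`, `delta_cost`, `delta_qaly`, `icer` (`NA` when
#'   `delta_qaly == 0`), and `dominance` (one of `"tradeoff"`,
#'   `"intervention_dominates"`, `"comparator_dominates"`, `"equivalent"`).
#' @export
compare_strategies <- function(ch, dt) {
  if (!identical(ch$settings, dt$settings))
    stop("strategy results were computed under different economic settings")
  delta_cost <- dt$annualized_cost - ch$annualized_cost
  delta_qaly <- dt$annualized_qaly - ch$annualized_qaly
  icer <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly
  dominance <-
    if (delta_cost == 0 && delta_qaly == 0) "equivalent"
    else if (delta_cost <= 0 && delta_qaly >= 0) "intervention_dominates"
    else if (delta_cost >= 0 && delta_qaly <= 0) "comparator_dominates"
    else "tradeoff"
  structure(list(cost_ch = ch$annualized_cost, cost_dt = dt$annualized_cost,
                 qaly_ch = ch$annualized_qaly, qaly_dt = dt$annualized_qaly,
                 delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = icer, dominance = dominance,
                 strategies = list(ch = ch, dt = dt),
                 settings = ch$settings),
            class = "markov_cea")
}

#' @export
print.markov_cea <- function(x, ...) {
  cat("Markov cohort cost-effectiveness comparison (per capita, per year)\n")
  print(cea_table(x), row.names = FALSE)
  if (x$dominance != "tradeoff")
    cat(sprintf("dominance: %s (ICER not meaningful on its own)\n",
                x$dominance))
  invisible(x)
}

#' @export
summary.markov_cea <- function(object, wtp = object$settings$wtp, ...) {
  nmb <- net_monetary_benefit(object, wtp)
  structure(list(cea = object, nmb = nmb), class = "summary.markov_cea")
}

#' @export
print.summary.markov_cea <- function(x, ...) {
  print(x$cea)
  n <- x$nmb
  cat(sprintf("at WTP %s CNY/QALY: incremental NMB %.2f CNY => %s\n",
              format(n$wtp, big.mark = ","), n$incremental_nmb,
              if (n$cost_effective) "intervention cost-effective"
              else "intervention not cost-effective"))
  invisible(x)
}

#' Summary table of the comparison
#'
#' @param x a `markov_cea`.
#' @return Data frame with one row per arm and columns cost, incremental
#'   cost, QALYs, incremental QALYs and ICER (comparator row carries `NA`
#'   increments).
#' @export
cea_table <- function(x) {
  data.frame(
    group = c("CH", "DT"),
    cost = round(c(x$cost_ch, x$cost_dt), 2),
    incremental_cost = c(NA, round(x$delta_cost, 2)),
    qalys = round(c(x$qaly_ch, x$qaly_dt), 5),
    incremental_qaly = c(NA, round(x$delta_qaly, 5)),
    icer = c(NA, round(x$icer, 2)))
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB(arm) = wtp * QALY - cost`; the incremental NMB
#' `wtp * delta_QALY - delta_cost` is positive exactly when the intervention
#' is cost-effective at that threshold. This is the decision rule used for
#' probabilistic acceptance (it remains well-defined when `delta_qaly <= 0`,
#' where an ICER comparison is not).
#'
#' @param result a `markov_cea`.
#' @param wtp willingness-to-pay, CNY per QALY (>= 0).
#' @return An `nmb_result` list: `wtp`, per-arm `nmb`, `incremental_nmb`,
#'   `cost_effective`.
#' @export
net_monetary_benefit <- function(result, wtp = result$settings$wtp) {
  stopifnot(wtp >= 0)
  nmb <- c(CH = wtp * result$qaly_ch - result$cost_ch,
           DT = wtp * result$qaly_dt - result$cost_dt)
  inc <- wtp * result$delta_qaly - result$delta_cost
  structure(list(wtp = wtp, nmb_per_arm = nmb, incremental_nmb = inc,
                 cost_effective = inc > 0), class = "nmb_result")
}

#' @export
print.nmb_result <- function(x, ...) {
  cat(sprintf("NMB at WTP %s: CH %.2f, DT %.2f; incremental %.2f (%s)\n",
              format(x$wtp, big.mark = ","), x$nmb_per_arm[["CH"]],
              x$nmb_per_arm[["DT"]], x$incremental_nmb,
              if (x$cost_effective) "cost-effective" else "not cost-effective"))
  invisible(x)
}

#' @export
plot.markov_cea <- function(x, which = c("trace", "ce"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- unclass(x$strategies$dt$trace)
    tr0 <- unclass(x$strategies$ch$trace)
    cyc <- 0:(nrow(tr) - 1L)
    graphics::matplot(cyc, tr0, type = "l", lty = 1, col = 1:5,
                      xlab = "cycle (months)", ylab = "persons",
                      main = "State occupancy (solid CH, dashed DT)", ...)
    graphics::matlines(cyc, tr, lty = 2, col = 1:5)
    graphics::legend("right", legend = hf_states(), col = 1:5, lty = 1,
                     bty = "n")
  } else {
    graphics::plot(x$delta_qaly, x$delta_cost, pch = 19,
                   xlab = expression(Delta ~ "QALY/yr"),
                   ylab = expression(Delta ~ "cost (CNY/yr)"),
                   main = "Incremental cost-effectiveness", ...)
    graphics::abline(0, x$settings$wtp, lty = 2)
    graphics::abline(h = 0, v = 0, col = "grey")
  }
  invisible(x)
}
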