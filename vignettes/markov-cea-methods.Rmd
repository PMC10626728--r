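---
title: "Methods: the Markov cohort model behind hfcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Markov cohort model behind hfcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcea)
```

## The decision problem

`hfcea` evaluates whether app-guided (digital-therapeutics, DTx) home-based
cardiac rehabilitation is cost-effective relative to conventional home-based
rehabilitation for chronic heart failure, from a healthcare decision-maker's
perspective. Disease severity is tracked with the NYHA functional
classification: patients occupy one of five states — NYHA I to IV or death —
and move between them once per monthly cycle according to a 5×5 transition
probability matrix. Death is absorbing and accrues neither cost nor utility.
A closed cohort (no entrants) is propagated for 120 cycles, a ten-year
horizon.

Hospitalization is not a separate state. Each alive state has a monthly
admission probability, and an admission costs that state's per-visit direct
medical cost; the expected hospitalization cost
(probability × cost per admission) is added to the cycle's accrual. The
intervention arm's admission probabilities relate to the comparator's
through per-state risk ratios below one, reflecting the protective effect of
continuous remote monitoring and guided exercise.

Per cycle, a person in alive state $s$ accrues

$$c_s = \frac{\text{nonmedical}_s + \text{indirect}_s + \text{dtx}}{12}
  + p_s \cdot \text{admission}_s, \qquad
  q_s = \frac{u_s}{12},$$

where the non-medical, indirect and DTx fees are annual amounts prorated to
the month, and $u_s$ is the state utility on the 0–1 scale. Both costs and
QALYs are discounted at 3% per year, compounded per cycle as
$(1.03)^{-(t-1)/12}$ with the first cycle undiscounted. Accrual uses the
cycle-*start* occupancy by default; a half-cycle option averages start and
end occupancy. The source analysis never mentions half-cycle correction, so
it is off by default but exposed (`economic_settings(half_cycle = TRUE)`)
because it shifts totals by roughly half a cycle's accrual and readers may
want the sensitivity.

Totals are per-capita (divided by the initial cohort size) and annualized.
Two annualization conventions are exposed because "per person per year" is
genuinely ambiguous for a cohort with substantial mortality:

* `per_horizon_year` (default): total discounted value ÷ 10 model years.
  This treats the horizon as the denominator regardless of survival.
* `per_life_year`: total discounted value ÷ discounted life-years, i.e. an
  amount per year actually lived.

The built-in parameter set's printed per-year results lie *between* these
two conventions and are reproduced exactly by neither; the package does not
guess a third, undocumented convention. The acceptance test evaluates every
documented mode, reports the per-target relative errors, and verifies that
the decision-relevant conclusion — the digital arm gains QALYs at an ICER
well below the willingness-to-pay threshold — holds in every mode.

## The built-in parameter set

`hf_paper_model()` returns both arms fully parameterized from a published
real-world data source: a 2,315-patient baseline cohort (1795/172/280/68
across NYHA I–IV), monthly transition matrices, monthly hospitalization
probabilities, per-state costs in CNY, utilities with variances, and
sensitivity ranges with distribution families. Two quirks of the printed
tables are handled explicitly:

* **Defective row sums.** Three rows of the intervention arm's transition
  matrix sum to 0.999 or 1.001. The engine repairs rows at evaluation time;
  the default `adjust_diagonal` mode moves the residual onto the
  stay-probability, because the off-diagonal transitions and death
  probabilities are the clinically sourced quantities. `proportional`
  (divide the row by its sum) and `none` are selectable so the sensitivity
  of results to this repair is checkable — the choice moves the ICER by
  under 0.01%.
* **Swapped column labels.** The printed cost table and the printed
  sensitivity-range table disagree on which column is "direct non-medical"
  and which is "indirect": each range interval brackets the *other* label's
  base values. Ranges are therefore attached to the cost component whose
  base values they bracket, the only internally consistent assignment.

## Incremental comparison

`markov_cea()` evaluates both arms and reports incremental cost, incremental
QALYs and their ratio $\mathrm{ICER} = \Delta C / \Delta E$, with a
dominance label when the signs make a bare ICER misleading. The
willingness-to-pay threshold defaults to 85,698 CNY/QALY (China's 2022 GDP
per capita; 3× that value, 257,094, is the secondary threshold). The
cost-effectiveness decision rule everywhere is incremental net monetary
benefit, $\mathrm{NMB} = \lambda\,\Delta E - \Delta C$, which stays
well-defined for draws where $\Delta E \le 0$.

Comparisons are made on annualized per-capita values; because both numerator
and denominator scale by the same horizon, total ten-year comparison yields
the identical ICER (asserted as a test).

## Deterministic sensitivity

`one_way_sensitivity()` sets *every state's* value in a parameter group to
its low (resp. high) bound simultaneously, in both arms (DTx fee only in the
intervention arm; the risk ratio regenerates the intervention's admission
probabilities as $\min(p^{CH}_s \cdot RR, 1)$), and records the two ICERs.
`tornado()` does this for all groups and sorts by swing. Note that the
published utility range (0.66–0.96) is a single global envelope, so the
utility bar means "all states share one utility value at the bound" — a much
larger perturbation than the per-state cost ranges, which is why it
dominates the tornado when included. The published tornado figure carries no
utility bar; run the tornado on the five remaining groups to compare with
it. `two_way_sensitivity()` evaluates the ICER on a cartesian grid of two
groups; edges agree with the one-way evaluations by construction.

## Probabilistic sensitivity analysis

Distribution fits follow the published families with method-of-moments
parameterizations, reading ranges as 95% intervals
($SD = \text{span}/3.92$):

* costs: gamma with mean at the base value, $k = m^2/SD^2$,
  $\theta = SD^2/m$;
* utilities: per-state beta from the published mean/variance,
  $\alpha = m\,k$, $\beta = (1-m)k$ with $k = m(1-m)/v - 1$;
* hospitalization risk ratio: lognormal with $\mu = \ln(\text{median})$
  (median preserved exactly) and $\sigma = \ln(\text{high}/\text{low})/3.92$.
  One standard-normal deviate per draw scales all four state risk ratios by
  $e^{\sigma z}$, preserving each state's published median while honouring
  the single published spread.

By default one cost/utility draw is shared by both arms, so only the risk
ratio and DTx fee differentiate the arms within a draw — the published
range table lists no arm-specific cost or utility variation. Under this
structure the QALY gain is nearly deterministic and the acceptance
probability at the primary threshold saturates near 100%, above the
published ~83%; fully arm-independent draws (`arm_draws = "independent"`)
overshoot in the other direction (~70%). Neither correlation structure —
nor any intermediate one, given the base-case deltas derivable from the
printed inputs — reproduces both published probabilities, so the package
keeps the structurally defensible shared-draw default and exposes the
alternative rather than fitting a correlation to the published curve.

Utility draws for states whose base mean lies inside the global 0.66–0.96
envelope (NYHA I and II here) are rejection-resampled into it, at most 100
attempts, with counts logged; the envelope is a config switch
(`utility_envelope = NULL` disables it) because a single global utility row
is ambiguous across states. Transition probabilities are not varied — no
published uncertainty exists for them. Draws are sequential from one seeded
RNG stream, so a fixed seed gives bit-identical scatter.

Because transitions are fixed across draws, each arm's discounted
state-occupancy weights are precomputed once and each draw reduces to linear
accrual over them — an exact shortcut, not an approximation (asserted
against full re-evaluation in the tests). 10,000 draws complete in a few
seconds. `ceac()` converts the scatter to an acceptability curve over a WTP
grid (default 0–300,000 CNY in 1,000-CNY steps, covering both thresholds).

## Synthetic instances and the microsimulation oracle

`random_model_instance()` generates structurally valid two-arm instances:
Dirichlet-style transition rows concentrated on staying, monthly mortality
increasing with severity (defaults about 1%→12% per month, the scale of the
built-in set), severity-decreasing utilities, positive costs at realistic
CNY magnitudes, and an intervention derived from the comparator by an
effect knob (death/worsening probabilities scaled down, freed mass moved to
staying) plus a hospitalization risk ratio. Neutral knobs produce two
identical arms — a degeneracy check. Synthetic cohorts default to 1,000
persons. Generated instances emulate the *structure* of real parameter
tables, not their empirical correlations (costs, utilities and transitions
are drawn independently), so passing tests demonstrate engine correctness,
not calibration to any real population.

`microsimulate()` is the validation oracle: individual-level simulation of
monthly state paths (categorical draws from matrix rows) and Bernoulli
admission events, with the identical accrual and discounting. Its per-capita
mean converges to the cohort model's expectation; the test suite checks
agreement within 3 standard errors at n = 50,000 on the built-in set and on
20 random instances. Because oracle and engine share the accrual formulas to
isolate the transition dynamics, the tests additionally compare both against
a deliberately independent naive accrual implementation. A deterministic
matrix makes the oracle exact (zero variance), which is asserted bit-wise.

`parameter_recovery_experiment()` closes the loop: on synthetic instances
with known truth, the PSA cloud mean must recover the deltas of the model at
the sampling-distribution means (cost and QALYs are linear in the sampled
parameters at fixed risk ratio; the lognormal's mean exceeds its median by
$e^{\sigma^2/2}$, which the reference point accounts for), and the CEAC must
cross 0.5 near the true ICER.

## Numerical choices and degenerate inputs

* Row repairs require non-negative entries and positive row sums; a zero
  row is an error, as is a repair that would push a stay-probability outside
  [0, 1].
* The cohort engine refuses matrices whose rows deviate from 1 by more than
  1e-9 — repair must be explicit, never silent.
* Occupancy conservation is maintained to 1e-9 over 120 cycles; the
  two-state toy matches its geometric-series closed form to 1e-12.
* Gamma fits with a vanishing range are flagged near-deterministic and
  sample as constants.
* `validate_model()` reports violations instead of raising, so defective
  printed inputs can be inspected; loading a config rejects hard content
  violations (negative costs, out-of-range probabilities) but tolerates
  defective row sums, which the engine repairs visibly.

## Problem sizes

The shipped tests run the full 120-cycle model everywhere, 10,000-draw PSAs
for the headline probabilities, 50,000-patient microsimulations for oracle
agreement, and 20 random instances for the property checks — a few tens of
seconds in total, chosen so the whole suite is routinely runnable at a desk.

## Known limitations

* No tunnel states, time-varying transitions, or patient covariates; the
  monthly matrix is memoryless.
* No correlation structure between sampled parameters beyond the
  shared-vs-independent arm switch; no EVPI.
* Only two strategies; no multi-way efficiency frontier.
* Costs are in CNY as printed, with no inflation indexing or currency
  conversion.
* The built-in set's printed per-year summary values are not exactly
  recoverable from its printed inputs under any documented accounting
  convention (see above); the package reports what the model arithmetic
  actually yields.
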