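---
title: "Methods: a three-state cost-effectiveness model for ACI in mCRC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state cost-effectiveness model for ACI in mCRC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acicea)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## The decision problem

Adoptive cellular immunotherapy (ACI: PD1-blockade-activated DC-CIK cells)
added to first-line XELOX plus bevacizumab improved progression-free and
overall survival in metastatic colorectal cancer in a phase III trial
(median PFS 14.8 vs 9.9 months, HR 0.60; control median OS 25.6 months,
HR 0.57, ACI median OS not reached; grade ≥3 adverse events 20.0% vs
23.5%; subsequent therapy 56.0% vs 64.7%). The economic question is whether
the added cost of ACI — a per-cycle price of $6,819.45 in the base case —
buys quality-adjusted survival at an acceptable rate, judged against
willingness-to-pay (WTP) thresholds indexed to China's per-capita GDP
($12,240.62 in 2024): 1.5× ($18,360.93/QALY), 1.94× ($23,746.80) and 3×
($36,721.86).

## The synthetic trial emulator

Individual patient data for the trial are not public, so the package ships
a generator that reproduces the *printed* statistical structure and serves
as the test bed for every downstream stage.

**Survival law.** Both endpoints use Weibull proportional hazards. An
exponential law cannot jointly satisfy two medians and a hazard ratio
unless the median ratio equals 1/HR (14.8/9.9 ≈ 1.49 ≠ 1/0.60), so the
Weibull shape is identified in closed form from the pair of medians and
the HR:

$$k = \frac{\log(1/\mathrm{HR})}{\log(m_t/m_c)}, \qquad
  \lambda = \frac{m_c}{(\log 2)^{1/k}},$$

giving $k = 1.2704$, $\lambda = 13.21$ months for PFS. The treatment arm is
$S_c(t)^{\mathrm{HR}}$, again Weibull with the same shape.

**The OS shape choice.** The ACI OS median was not reached, so the
two-median identity cannot pin down an OS shape. The package sets the OS
shape equal to the PFS-calibrated shape — the same mildly increasing
hazard dynamics — and solves the scale from the 25.6-month control median
($\lambda_{OS} = 34.16$ months). The ACI OS law is then defined purely
through HR 0.57. A useful consistency check falls out: the implied ACI OS
median is 39.8 months, beyond the default 36-month follow-up, so emulated
ACI OS medians are indeed typically "not reached".

**Censoring.** The trial's censoring pattern is not reported. The default
is uniform-accrual administrative censoring: accrual over 18 months,
database lock at 36 months, so censoring times are
$36 - U(0, 18)$ months. These values were chosen once so that the control
OS median (25.6 mo) is observable while the ACI OS median (39.8 mo) is
not; they are flagged as an assumption in the config and can be replaced.
Arm sizes default to 100 (ACI) and 102 (control), mirroring the trial;
calibration tests use 200,000.

**What the generator does not emulate:** patient covariates, non-administrative
(dropout) censoring, non-proportional hazards, and any correlation between
PFS and OS within patients (each endpoint is simulated marginally). Tests
passing on this generator therefore certify the pipeline's arithmetic and
algorithms, not the clinical fidelity of any particular extrapolation.

## Digitization and pseudo-IPD reconstruction

`emit_digitized_km()` emulates what a plot digitizer produces: exact KM
step-function values at a set of coordinate times plus exact at-risk
counts. `digitization_grid()` places the coordinates where a human would
click — on the visible step corners, roughly 25 of them, always anchoring
the last step at or before each number-at-risk axis tick. The anchor rule
matters: without it, events falling between the last click of a risk-table
interval and the interval boundary are mistaken for censorings and the
whole reconstructed curve drifts.

`guyot_reconstruct()` rebuilds pseudo-IPD per risk-table interval: a
censoring count is proposed, censoring times are spread uniformly over the
interval, events at each coordinate are inferred from the drop of the
digitized curve against the running product-limit estimate
($d_k = \mathrm{round}(n_k (1 - S_k / \hat{S}))$), and the count is chosen
so the implied number at risk matches the published one. Where several
censoring counts satisfy the at-risk constraint, the implementation scans
them all and keeps the one whose product-limit values deviate least from
the digitized coordinates — on small instances this provably coincides
with an exhaustive integer search (tested against one). In the final
interval, with no further at-risk anchor and no reported total event
count, no within-interval censoring is assumed and subjects still at risk
after the last coordinate are censored there; a reported total event count,
when available, is matched instead. Coordinates are isotonically clipped
(running minimum) against digitization noise; inversions larger than 0.05
survival units are rejected as inconsistent input rather than noise.
Reconstructed times are reported at 4-decimal precision; diagnostics (the
maximum deviation between the reconstructed KM curve and the input
coordinates) are computed before rounding.

Under the study conditions (n = 102, 25 coordinates, risk table every 3
months) the round trip recovers the source arm's KM median and 30-month
restricted mean within 5%, with maximum curve deviation below 0.02.

## Parametric extrapolation

Seven families are fitted by right-censored maximum likelihood through
`flexsurv`: exponential, Weibull, Gompertz, gamma, log-logistic,
log-normal, generalized gamma (the (μ, σ, Q) parameterization, whose Q → 0
boundary is the log-normal). Spline and fractional-polynomial families are
deliberately out of scope: their knot configurations are analysis-specific
and cannot be standardized here. Ranking is AIC-ascending with a ΔAIC < 2
cluster treated as a statistical tie broken by BIC — fully deterministic;
the visual-inspection step of practice is left to the analyst via overlay
plots. Every curve pair entering the cohort model must pass
`screen_pair()`: OS ≥ PFS (within 1e-9) at every cycle time, equality
allowed.

## The cohort model

Three mutually exclusive states — progression-free (PFS), progressed (PD),
death — on 21-day cycles matching the regimen. The horizon is 20 years,
i.e. `ceiling(20 × 365.25 / 21)` = 348 cycles; a cycle-count override
exists for sensitivity use (e.g. 374 cycles ≈ 21.5 years). No background
general-population mortality floor and no tunnel states.

Two engines are implemented and tested against each other:

* **Partitioned survival** (base case): occupancy read directly off the
  curves, $pfs_k = S_{PFS}(t_k)$, $pd_k = S_{OS}(t_k) - S_{PFS}(t_k)$
  (clamped at 0), $death_k = 1 - S_{OS}(t_k)$. This reproduces the fitted
  curves exactly.
* **Transition matrices** (used by the cross-validation scenario): per
  cycle, the PFS exit probability is $1 - S_{PFS}(t_{k+1})/S_{PFS}(t_k)$
  and the overall conditional death probability is
  $1 - S_{OS}(t_{k+1})/S_{OS}(t_k)$. Curves alone do not dictate how PFS
  exits split between PD and death; the package assigns the overall death
  probability to PFS→death and the remainder of the exits to PFS→PD, then
  solves PD→death each cycle so cohort deaths track $1 - S_{OS}$ exactly.
  Probabilities pushed outside [0, 1] are clamped and flagged. When no
  clamp activates, the chain reproduces the partitioned trace to 1e-6 per
  state per cycle.

Discounting is 5%/year (accepted range 0–8%) applied to costs and
outcomes as $(1+r)^{-c/365.25}$ per cycle of $c$ days, which compounds
exactly to $1/(1+r)$ over a year. No half-cycle correction is applied by
default — the simplest reading, reproducible by anyone — but
`model_settings(half_cycle = TRUE)` switches to mid-cycle (averaged)
occupancy weights.

## Costs and utilities

Per cycle in PFS: bevacizumab 7.5 mg/kg (65 kg default) and capecitabine
1,000 mg/m² twice daily on days 1–14 (BSA 1.79 m², a direct config input —
no standard formula reproduces 1.79 from 165 cm / 65 kg, so it is not
recomputed); plus oxaliplatin 130 mg/m² and, in the ACI arm, the ACI
per-cycle price during the six induction cycles. Later PFS cycles are
maintenance (no oxaliplatin, no ACI). The first cycle adds the expected
grade ≥3 adverse-event management cost ($\sum_i p_i c_i$) and subtracts the
duration-adjusted expected disutility
($\sum_i p_i u_i \min(d_i, 21)/365.25$ QALYs). PD cycles accrue best
supportive care plus follow-up; the expected subsequent-therapy cost is a
lump sum charged on the flow into PD weighted by the arm's uptake (56.0% /
64.7%) — regimen durations are unreported, so a duration-based variant is
left to configuration. Terminal care is charged once per incremental death
in the cycle of death. Utilities are arm-specific in PFS (the published
tornado names "utility of PFS in the ACI group", implying arm-specific
values) and shared in PD, scaled to the 21/365.25-year cycle.

The default parameter values (`inst/extdata/default_econ.yaml`) are a
**synthetic plausible set** for the Chinese setting — the trial-anchored
entries are only the ACI price and the subsequent-therapy uptakes. Every
model-level test that depends on them is a property test (orderings,
affinity, conservation), not a value match. Two consequences worth
stating: the package's base-case ICER (about $62,000/QALY) is an artifact
of these placeholders plus the deliberately tail-light Weibull emulator,
and analysts must supply real micro-costing inputs before drawing any
decision from the numbers.

## Sensitivity analysis

**One-way (tornado).** Each parameter in turn at its bounds, two full model
evaluations per row. Defaults: ±25%, except the higher-uncertainty
adverse-event, BSC and terminal-care costs at ±30%, and the discount rate
over its full 0–8% range; utility highs cap at 1. Under the defaults the
leading drivers include the PD utility, the discount rate and the ACI
price, consistent with the published tornado.

**Probabilistic.** 1,000 Monte Carlo iterations by default; gamma for
costs (shape $m^2/s^2$, scale $s^2/m$), beta for utilities and
probabilities (moment-matched, feasibility $s^2 < m(1-m)$ enforced).
Dispersions are unreported in the source setting, so the default ties each
standard deviation to the one-way bounds, $s = (\mathrm{high} -
\mathrm{low})/(2 \times 1.96)$ — one coherent uncertainty description for
both analyses. Survival-curve parameters are *not* sampled: the published
analysis describes only cost/probability/utility distributions, and curve
uncertainty is covered by the cross-validation grid instead. Acceptability
curves are counting fractions of $\Delta C \le \lambda \Delta E$, never
smoothed.

## Price inversion

Incremental QALY does not depend on the ACI price, and incremental cost is
exactly affine in it, $\Delta C(p) = \Delta C_0 + \beta p$ with slope
$\beta$ = discounted PFS occupancy summed over the six ACI-dosed cycles.
Two model runs therefore determine the map (a third run verifies
affinity), and the price ceiling at WTP $\lambda$ is
$p^\star = (\lambda \Delta E - \Delta C_0)/\beta$, floored at zero and
flagged when unreachable. The iterative re-running described in practice
is retained as a bisection cross-check and agrees to $0.01. GDP is stored
once and thresholds derived from it, so the three thresholds cannot drift
apart by rounding.

## Scenarios

**Horizons.** Full re-evaluation at 10, 15 and 20 years. Because the
incremental cost concentrates in the first six cycles while incremental
survival accrues for years, the ICER falls as the horizon extends.

**Distribution cross-validation.** All screened PFS/OS family combinations
of each arm are paired across arms (screening happens *before* pairing, so
the pair count is an exact Cartesian product — a 72 × 34 grid yields
2,448). Each pairing runs through the transition-matrix engine. Since each
arm's totals depend only on its own curve set, the implementation
evaluates each set once and crosses the totals, which is why the full grid
completes in seconds. The exact 72/34 combination counts of the published
grid depend on unreported screening details; the package reproduces the
shape, not the provenance, of that grid.

## Numerical and testing choices

Problem sizes: calibration checks use 200,000 subjects per arm (KM-median
Monte Carlo error ≈ 0.03 months) and 50,000 per arm for the
proportional-hazards recovery; reconstruction round trips use the
trial-sized n = 102; family-recovery tests use 10,000 draws; the
probabilistic analysis is exercised at 60–200 iterations in tests and
1,000 by default in use. All stochastic tests fix seeds. Degenerate inputs
are rejected loudly: negative times, horizons shorter than one cycle,
hazard-ratio/median combinations that contradict proportional hazards,
beta moments outside the feasible region, at-risk counts that increase in
time.

## Limitations

* The generator's marginal, proportional-hazards Weibull world is exactly
  that — a world. Real extrapolation disagreements between families (the
  reason for the cross-validation grid) are larger than anything the
  emulator produces.
* Default economics are synthetic; all headline economic outputs shift
  with real inputs.
* No vial-sharing/wastage optimization, no indirect costs, no
  population-mortality floor on extrapolated OS, no interval-censored
  reconstruction.
* The PFS-exit allocation rule in the transition-matrix engine is one
  defensible convention among several; alternatives redistribute deaths
  between states within a cycle but cannot change the OS-driven death
  trace.
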