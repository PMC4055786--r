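---
title: "PK/PD and clinical trial simulation with pkpdtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PK/PD and clinical trial simulation with pkpdtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkpdtrial)
library(dplyr)
```

## What this package models

pkpdtrial is a scriptable toolkit for compartmental
pharmacokinetic/pharmacodynamic (PK/PD) simulation and for simulating the
clinical trials that such models are built to inform. Interactive
simulation tools are excellent for exploring a model with a clinical team,
but a slider session is not reproducible. This package provides the same
building blocks — ODE models with dosing events, interindividual
variability, trial-level readouts — as plain functions returning tidy
tables, so that every simulation is a script that can be re-run, tested,
and diffed.

The pieces, bottom-up:

* an ODE **engine** (`pk_integrate()`) with fixed-step Euler/RK2/RK4 and an
  adaptive stiff method, plus exact handling of bolus and infusion regimens
  (`dose_regimen()`);
* a **model library** (`pk_model()`): one/two/three-compartment PK with
  first-order or capped absorption, transit-compartment chains, a
  full-binding target-mediated drug disposition (TMDD) system, and the PD
  algebra (Emax, logistic, indirect response, circadian and placebo
  factors, a Hill flare-probability curve);
* a **population** layer: lognormal interindividual variability, correlated
  effects through Cholesky factorization, covariate (body-weight) models;
* two complete **trial simulators**: a blood-pressure dose-success design
  and a flare/randomized-withdrawal design with binomial visit events;
* **evaluation and fitting**: parameter sweeps, statistic-at-time
  extraction, summary intervals, and a deliberately simple least-squares
  curve fit.

## The ODE engine and its dosing conventions

A simulation is defined by a `solver_config()` (method, window
`[start_time, stop_time]`, step `dt` or the adaptive controls
`dt_min`/`dt_max`/`tolerance`, output interval `dt_out`) and one or more
`dose_regimen()`s. Several numerical choices deserve an explicit record:

* **Bolus doses are discrete state increments** of
  `amount * bioavailability` applied at the first grid point at or after
  the scheduled time. Simulation languages that smear a pulse over two
  integration steps can deliver half a dose when a pulse abuts the window
  edge; adding the amount directly to the state delivers the exact mass
  regardless of `dt`. Off-grid dose times are snapped forward to the next
  grid point with a logged warning.
* **Trajectory rows at a dose time hold the pre-dose state** (the trough
  convention) for the fixed-step methods. A concentration read "at 72 h"
  when a dose is also scheduled at 72 h is therefore the value just before
  that dose — the clinically intended "prior to dosing on day 3" reading.
  The adaptive method reports the post-event state at dose times instead
  (a property of the underlying event handling); the difference only
  matters for the dosed compartment itself at the exact dose instant.
* **The fixed grid is anchored at `start_time`**, which defaults to −1 time
  unit. Starting slightly before the first dose keeps the first dose away
  from the window edge and gives every regimen at least one pre-dose
  output row.
* **Infusions are rate terms**, active while
  `(t - first_time) mod interval < infusion_duration`, so a 2 h infusion
  at 7 mg/h every 24 h contributes 14 mg per cycle through the quadrature
  of the solver itself.
* **`adaptive_stiff`** delegates to the `lsoda` implicit solver (deSolve)
  with the configured relative tolerance and step bounds; bolus events
  force an internal restart at the dose time. With `dt_out = 0` the
  fixed-step methods return every accepted step; the adaptive method
  returns a `dt_max`-spaced grid (its internal accepted steps are not
  exposed), and any positive `dt_out` is produced by linear interpolation.
* Linear invariants (total mass with eliminations zeroed) are preserved by
  Runge–Kutta methods up to floating-point roundoff; the test suite holds
  this to 1e-9 relative at every output time.

Solver accuracy is validated against closed forms: the one-compartment
bolus `A(t) = D e^{-k_e t}` and the Bateman solution

$$A(t) = D\,\frac{k_a}{k_a - k_e}\left(e^{-k_e t} - e^{-k_a t}\right),$$

with the degenerate limit `D k_a t e^{-k_a t}` substituted when
`|ka - ke| < 1e-10 * ka` so the oracle itself cannot blow up near
`ka = ke`. RK4 at `dt = 0.02` matches both within 1e-6 relative over
0–100 h.

## The TMDD system

The full-binding model tracks molar amounts of the depot `S`, free drug
`D`, free target `T` and complex `TD`; binding is second order in
concentration (hence the `kon/V` term), the target turns over with
production `RateT` and elimination `keT`, and drug, target and complex are
eliminated at distinct rates:

$$\begin{aligned}
S' &= \mathrm{input} - k_a S \\
D' &= -\tfrac{k_{on}}{V} D T + k_{off} TD - k_{eD} D + k_a S\\
T' &= -\tfrac{k_{on}}{V} D T + k_{off} TD - k_{eT} T + Rate_T\\
TD' &= +\tfrac{k_{on}}{V} D T - k_{off} TD - k_{eTD} TD
\end{aligned}$$

`koff` is reparameterized as `Kd * kon` (so affinity and kinetics can be
set independently), and the free target starts at its turnover steady
state `RateT / keT`. Doses in mg are converted to nmol through the drug
mass-concentration factor (0.15 by default); the drug and target factors
(0.15 and 190 per nmol/L) are stored as named parameters; treat the
absolute concentration scales as nominal reporting conventions rather
than strict unit conversions. The defaults describe a theoretical
monoclonal antibody with time in days. The system is stiff (binding is
fast relative to turnover), hence the adaptive implicit solver with
`tolerance = 1e-3`, `dt_min = 1e-3`, `dt_max = 0.1` d.

Two structural facts double as tests: undosed, the system must stay at its
steady state indefinitely; and because complexes cannot outnumber the
available target, total target concentration rises with dose but
saturates — the simulated 75/150/300 mg regimens must give pointwise
ordered total-target curves.

## Interindividual variability

Individual parameters are lognormal around the population value:
`p_i = p_pop * exp(eta_i * MC)`, with `eta ~ N(0, sd^2)` univariate or
`eta ~ MVN(0, COV)` correlated. Correlated draws are `r %*% CH` with `CH`
the upper Cholesky factor (`t(CH) %*% CH = COV`) and `r` standard normal.
The factor is always computed at run time by `cholesky_upper()`; factors
transcribed by hand go stale when the covariance changes, so known
reference factors serve as regression tests instead of inputs.

Conventions worth noting:

* The `MC` (Monte-Carlo) switch draws the etas either way but multiplies
  them by 0 or 1, so `mc_switch = 0` gives a population-typical cohort of
  identical subjects without changing the random-number stream.
* Draws are made in **subject-major order under one master seed**:
  subject *i* consumes a contiguous block of draws, so enlarging the
  cohort appends subjects without reshuffling earlier ones.
* `empirical_covariance()` uses the **uncentered** estimator
  `mean(eta_j * eta_k)` (the means are structurally zero); a centered
  variant exists but is not the default. With 1e5 subjects a reference
  3×3 covariance is recovered within 5% relative on the diagonal and
  ±0.05 absolute off-diagonal.
* Normal body weights are resampled at or below zero. Simulation tools
  typically do not truncate, but negative weights are physically
  meaningless and at 70 ± 10 kg the resampling probability is about
  1e-12, far below Monte-Carlo resolution.
* A residual error written as `exp(normal(0, 0.01))` is read as a
  **standard deviation** of 0.01 on the log scale (the convention of
  common simulation tools); reading it as a variance would change
  magnitudes.

## The blood-pressure success trial

`simulate_bp_trial()` implements a dose-finding question: *what fraction
of patients achieves at least a 20 mmHg blood-pressure reduction at 72 h?*
Each of `n_subjects` (default 100) patients gets individual
`ka, ke, V1` and baseline (lognormal sds 1.0, 0.01, 0.2, 0.1), daily oral
doses (default 4), one-compartment PK on a 0.1 h RK4 grid over
−1 to 144 h, concentration `central / V1 * exp(N(0, 0.01))`, and an
inhibitory Emax effect `PD_change = Emax * C / (C + EC50)` with
`E0 = 125` mmHg, `Emax = −40` mmHg, `EC50 = 20` ng/mL. Success is
`PD_change < −20` at the evaluation time, read **pre-dose** (the 72 h
evaluation coincides with the fourth dose). The trial statistic is
`100 * mean(success)`.

Two design points were genuinely open and are resolved as follows. A
variability term on `ke` is drawn and applied as the individual `ke_i`
(at sd 0.01 the distinction from using the population value is well below
Monte-Carlo noise). And the residual error, which an interactive tool
would re-draw at every integration step, is applied once at the
evaluation time, since only that reading enters the statistic.

`bp_dose_response()` maps replicate trials over a dose grid (the classic
0–200 mg in 10 mg steps gives 21 levels), one independent sub-seed per
(replicate, dose) cell. At 150 mg, 10 replicate 100-patient studies
consistently all reach the 80% target; around 120 mg roughly half do,
which is what makes 150 mg the robust choice.

## The flare / randomized-withdrawal trial

`simulate_flare_trial()` implements a two-arm randomized withdrawal for a
subcutaneous antibody (time in days): 18 patients per arm, body weight
uniform on 10–80 kg, dose 150 mg (2 mg/kg below 40 kg), two-compartment
clearance-form PK with allometric scaling (`CL`, `V2`, `V3` scale with
`WT/70`; `PS` with `(WT/70)^0.667`), correlated lognormal effects on
(CL, V2) and (PS, V3) from their reported covariance matrices, and
independent lognormal effects on `ka`, bioavailability and the flare IC50
`KIEF` (sds √0.185, √0.0881, √0.0158). The probability of a disease flare
declines with concentration as a Hill curve,
`Pflare = 1 / (1 + (C/KIEF)^HILL)` with `HILL = 4.22` and
`KIEF = 1.13` µg/mL at the 50:50 point.

Both arms are dosed at day 0; at day 56 arm 1 receives three further doses
every 56 days while arm 2 is withdrawn. Weekly visits run from day −28;
at each visit **strictly after** day 56 a flare event is drawn
`Bernoulli(Pflare(C_visit))`, and a patient's first flare transfers them
out of the randomized phase — the transfer indicator is absorbing, so the
per-arm flare-free fraction `1 − transfers/N` is non-increasing by
construction. Visits that coincide with a dose read the pre-dose
concentration.

Two conventions are deliberate. Doses are placed at their exact scheduled
times through the event list; simulation tools that smear pulses over
integration steps need to offset the first dose by one step and gate
maintenance doses with step-dependent windows, workarounds that discrete
state increments make unnecessary. And only the two active arms exist —
interactive implementations of this design often carry extra all-zero
dummy arms purely to cycle plot colors. Whether the withdrawn arm should
receive any additional loading before withdrawal is a genuine design
choice; here it receives exactly the single initial dose.

`replicate_trials()` runs the design repeatedly under derived sub-seeds.
No reference numeric values exist for these curves, so the tests assert
structure instead: curves start at 1 and never rise, transfers absorb,
and — averaged over 200 replicates — the withdrawn arm's flare-free
fraction never sits meaningfully above the continued arm's from day 84
onward (99% binomial band).

## Evaluation utilities

`statistic_at_time()` returns the series value at the **first** grid time
within `dt` of the evaluation time, and an explicit `NA` when nothing
matches. (Interactive tools often emulate this with ±Inf sentinels and a
min/max over time; the direct window extraction has the same semantics
without sentinel values leaking into exports. When two adjacent grid
points both fall in the window, the earlier one wins — ties are not
otherwise meaningful on a fixed grid.) `parameter_sweep()` runs one full
simulation per grid point `from + k (to − from)/(steps − 1)` and records
min/max/mean/at-time statistics per output. `array_summary()` reports
`m ± z·sd` with the population-denominator SD and
`z = qnorm(0.975)` — the familiar 1.96 is a two-decimal rounding of a
computed quantile, not a hard-coded constant.

## Least-squares fitting

`least_squares_fit()` is a curve fit, on purpose no more: it minimizes the
unweighted residual sum of squares treating every observation as
independent, ignoring any subject structure. That mirrors its intended
role — recovering plausible parameter ranges to seed mixed-effects
estimation elsewhere — and its known blind spot is documented rather than
patched: with repeated-measures data the subject correlation is simply
ignored. The optimizer is Nelder-Mead on log-transformed parameters
(positivity for free, better conditioning across decades), run from each
provided start; the convention of supplying two guesses per parameter maps
naturally onto a two-start multistart, and the best run wins.
Single-parameter fits use Brent's method on a wide log bracket.
Predictions at observation times come from linear interpolation of the
simulated trajectory; non-convergence is flagged on the result, never
thrown. On noise-free synthetic Bateman data the fit recovers `ka` and
`ke` within 1e-3 relative from perturbed starts; the `ka`/`ke` flip-flop
ambiguity is real and is handled by documentation, not by automatic
reparameterization.

## What the synthetic data do and do not show

Every dataset used in the tests is generated by the package itself
(`generate_pk_dataset()`: model prediction times `exp(N(0, noise_sd))`
noise, reproducible under a seed). This validates internal consistency —
the solver against closed forms, the samplers against their target
distributions, the estimators against the parameters that generated the
data. It does not validate the models against any real patient data:
model misspecification, dropout, dosing-history errors, assay floors and
censoring are all absent. Passing tests therefore demonstrate that the
machinery is correct, not that any particular parameterization describes a
real drug.

## Problem sizes and runtime

The defaults used in the tests and the acceptance script are the study
conditions themselves: 100-patient blood-pressure trials on a 0.1 h grid
(10 replicates per master seed), 2 × 18-patient flare trials on a 1 d
grid (200 replicates when averaging arms), 1e5-subject draws for the
Monte-Carlo recovery checks, and RK4 at `dt = 0.02` h over 100 h for the
solver oracles. The whole suite runs in about a minute on one CPU.

## Known limitations

* No event-time root finding: dosing cannot be conditioned on the state,
  and delay differential equations are out of scope.
* No quasi-steady-state or Michaelis–Menten TMDD approximations — only the
  full binding model.
* The fitting module has no weighting, no variance model, and no
  mixed-effects machinery, by design.
* Statistical evaluation is limited to means, SDs and normal-quantile
  intervals; hypothesis testing belongs in downstream analysis of the
  exported tables.
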