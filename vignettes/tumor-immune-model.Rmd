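---
title: "Modeling CD8+ T cell control of tumor growth under pulse vaccination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CD8+ T cell control of tumor growth under pulse vaccination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellvax)
```

## The model

`tcellvax` simulates the primary cytotoxic CD8+ T cell response elicited
by a replication-deficient adenovirus vaccine against a defined tumor
antigen, and the response's effect on the growth of a transplanted
B16F10 melanoma in the mouse. The biology is compressed into three
compartments — lymph node, blood, and tumor microenvironment — and nine
state variables:

| state | meaning | units |
|---|---|---|
| `t_n` | naive antigen-specific CD8+ T cells | cells mm^-3 |
| `t_e1` | effector CTL in the lymph node | cells mm^-3 |
| `lv` | adenovirus-derived antigen expression | RLU mm^-3 |
| `t_e2` | effector CTL in blood | cells mm^-3 |
| `c_pos` | MHC class I positive tumor cells | count |
| `c_neg` | MHC class I negative tumor cells | count |
| `t_e3` | effector CTL in the tumor | cells mm^-3 |
| `ifng` | interferon gamma in the tumor | moles mm^-3 |
| `tnfa` | tumor necrosis factor alpha in the tumor | moles mm^-3 |

Naive cells are produced at a constant rate `c1` and die at `kd1`, so
their homeostatic level is `c1/kd1` (0.0714 cells mm^-3 with the
calibrated constants — 100 antigen-specific naive cells distributed over
the 1.4e3 mm^3 mouse blood volume). Vaccination drives activation
through the saturable antigen term `lv/(lv + gamma)`; lymph-node
effectors proliferate under the same drive, braked by the checkpoint
term `alpha/(alpha + t_e1^2)`. Effectors traffic between compartments
with first-order rate constants `a12`, `a21`, `a23`, `a32`, with
volume ratios converting between compartment concentrations. The
vaccine antigen itself decays exponentially (`kd2`, half-life about 1.9
days) and is replenished only by vaccination impulses: at each
scheduled day the antigen state jumps by the administered dose,
`LV(t+) - LV(t-) = dose`, which is what makes the system an impulsive
ODE rather than a plain one.

In the tumor, MHC class I negative cells (the inoculated phenotype,
invisible to CTL) grow logistically and convert to the MHC class I
positive phenotype under IFN-gamma (saturable in `k1`). Positive cells
are killed by tumor-infiltrating effectors at rate
`c4 * t_e3 * c_pos / (epsilon + C)` where `C = c_pos + c_neg`, and
"dilute" back into the negative pool through proliferation. Effectors
in the tumor die (`kd5`), proliferate locally on antigen recognition
(`kp3`), and secrete both cytokines; TNF-alpha production has an
autocrine saturable term plus a constitutive term.

The 27 calibrated constants ship in
`inst/extdata/calibrated_parameters.yaml` and load with
`default_parameters()`. Two derived quantities anchor the biology: the
logistic carrying capacity `K = (kp2 - kd4)/r2` is about 1.497e9 cells,
equivalently `s_t * K` is about 898.2 mm^3 of tumor.

### The role of `epsilon`

A small positive constant `epsilon` appears in two roles: as a volume
offset in the tumor compartment volume
`Vol_t = epsilon + s_t*C + v_i*t_e3` and as a count offset in the
fractions `c_pos/(epsilon + C)`. The equations use one symbol for both,
and we keep that convention exactly (default `1e-3`, configurable)
despite the dimensional tension, because the Jacobian entries and the
stability analysis are written in terms of it. The closed-form
high-tumor spectrum additionally uses the `epsilon -> 0` limit; the
numeric spectrum uses the configured value, and
`classify_equilibria()` reports both.

## Simulation

`simulate_trajectory()` integrates the system with the classical
fourth-order Runge-Kutta method on a segment-wise uniform grid that
lands exactly on every vaccination day; the impulse is applied after
the step reaching the vaccination time, and both the pre-jump and
post-jump states are recorded. The default step of 0.01 day resolves
the fastest calibrated rate (`kp1` around 12 day^-1) with
`rate * dt` about 0.12; order-4 convergence is verified in the test
suite against the antigen exponential closed form, and the full
calibrated run agrees with an adaptive reference solution
(`simulate_reference()`, `deSolve::lsoda` segment-by-segment between
impulses) to better than 1e-4 relative per state.

Two numerical guards depart from a bare textbook RK4, and both are
reported rather than silent:

* **Negativity projection** (`clip_negative = TRUE`). The kill term
  makes `c_pos` locally fast whenever `c4 * t_e3 / (epsilon + C)` is
  large; explicit steps can then overshoot below zero. Overshoots are
  projected back to zero and the worst per-state excursion is kept in
  the `negative_excursions` attribute, so a trajectory that needed
  projection is identifiable. `clip_negative = FALSE` gives the strict
  unclipped method.
* **Extinction floor** (`extinction_threshold`, off by default, 1 cell
  in scenario runs). Tumor cell states are counts; once the total
  falls below a single cell the population it describes no longer
  exists. The continuum equations, however, happily regrow a remnant
  of 1e-10 "cells" at `kp2 - kd4 = 0.5` per day, which would make any
  eliminated tumor relapse after a few hundred days of simulated time.
  When the floor is enabled the two tumor states are absorbed at zero
  at the first crossing (exactly, via a terminal root in the adaptive
  solver; per-step in RK4). The absorbed state is an exact fixed point
  of the tumor sub-dynamics, so this is a clean model statement —
  discrete populations go extinct — not a numerical fudge.

### Stiffness in the enhanced-effector scenarios

The in-silico experiments that raise T cell cytotoxicity (`c4` from
2.49e-13 to 2.49e5) push the kill term into a genuinely stiff regime:
the local decay rate of `c_pos` reaches 1e3–1e4 day^-1 and beyond as
the tumor shrinks. A fixed-step explicit RK4 cannot cross this regime
at any affordable step: the discrete map is captured by a spurious
equilibrium that self-organizes where the step times the local rate
sits at the RK4 stability boundary (about 2.785, where the
amplification factor returns to +1 — the divergence is monotone and
never goes negative, so no projection can catch it). We verified this
capture empirically from `dt = 0.01` down to `1e-4`: the minimum tumor
burden stalls at 1e5–1e6 cells instead of crashing, while the adaptive
stiff solver shows the true collapse. Scenario runs
(`run_scenario()`, `sweep_scenarios()`) therefore default to
`method = "lsoda"`; `method = "rk4"` remains available and agrees with
the adaptive path everywhere outside the stiff regime. This is a
useful cautionary tale: the captured RK4 trajectory looks entirely
plausible — smooth, positive, slowly decaying — and only the
cross-solver comparison exposes it.

## Equilibria and stability

Setting the right-hand sides to zero yields two equilibria: the
tumor-free state (naive cells at `c1/kd1`, everything else zero) and
the high-tumor state (additionally `c_neg = K`). `model_jacobian()`
returns the exact 9x9 Jacobian at any state (validated against central
finite differences at random states to 1e-5 relative).

At the tumor-free state the spectrum is available in closed form: the
seven decay rates plus the roots of the trafficking quadratic
`lambda^2 + (a12 + a21 + a23 + kd3) lambda + a12(kd3 + a23) = 0`,
whose roots always have negative real part for positive constants. The
single sign that decides everything is `kp2 - kd4`: when tumor
proliferation outpaces tumor death the tumor-free state is unstable —
any inoculum grows — and the high-tumor state is stable, which is the
calibrated situation. At the high-tumor state the nontrivial part of
the spectrum reduces (in the `epsilon -> 0` limit) to a cubic whose
Routh-Hurwitz quantities `a0, a1, a2, a2*a1 - a0` are all positive for
any positive constants; `classify_equilibria()` reports the criterion
verdict and the numeric-eigenvalue verdict side by side, and reports
the marginal case `kp2 = kd4` without classifying it. Note the numeric
Jacobian at the high-tumor state contains entries spanning about 17
orders of magnitude (the cytokine production constants are large in
moles-based units); the LAPACK balancing used by `eigen()` handles
this, but it is the reason the closed-form route is the primary
verdict and the numeric spectrum the cross-check.

```{r stability}
fit <- classify_equilibria(default_parameters())
glance(fit)
```

## Calibration

The constants were originally estimated against seven observed time
series (lymph-node, blood and tumor CTL, antigen expression, tumor
volume, and IFN-gamma / TNF-alpha gene expression) digitized from
published figures; those measurements are not deposited anywhere
machine-readable, so the package ships a synthetic-data generator with
the same design instead of the data. `default_design()` samples the
seven observables on coarse day grids within the 49-day protocol (93
mean points in total, matching the design's points-versus-parameters
accounting), with multiplicative log-normal noise (default CV 0.2)
across 5 synthetic replicate animals per point, reporting mean and SEM.
The generator reproduces the study's sampling structure, not real
mouse-to-mouse variability (no tumor-take failures, no censoring, no
day-to-day batch effects), so calibration tests against it demonstrate
that the machinery recovers parameters under the assumed noise model —
not that the original biological estimates are reproducible.

`calibrate_ga()` is a generational real-coded genetic algorithm over
log10-encoded parameters (values span 1e-18 to 1e11, so log space is
the only sensible chromosome): tournament selection (size 3),
BLX-alpha blend crossover (probability 0.9, alpha 0.3), per-gene
Gaussian mutation (rate 0.1, sd 5% of the gene's log-range), elitism
(2), population 100 — all configurable in `ga_config()`. The fitness
is the sum over series of normalized squared errors plus normalized
squared differences of consecutive-day slopes, with per-series
normalizers (maximum observed value; maximum absolute observed slope)
making series of wildly different units commensurate; the two terms
carry configurable weights defaulting to 1 and 1. SEM values ride
along in the dataset but do not enter the default fitness; inverse-SEM
weighting is available behind a flag. Fitness evaluations integrate at
`dt = 0.05` for speed (the reported best fit should be re-simulated at
0.01; the two differ by less than the fitness resolution in practice).
Candidates whose simulation blows up receive infinite fitness and are
culled. With elitism the best-so-far fitness is non-increasing, and
the whole run is deterministic given the seed. A five-parameter
recovery experiment on noiseless synthetic data (population 100, 150
generations, bounds at the true values times/divided by 100, truth not
seeded into the population) recovers every parameter within a fraction
of a percent in the test suite.

## In-silico vaccination experiments

`scenario_preset()` ships the experiment families explored with the
calibrated model: a booster dose sweep (1e6 / 1e8 / 1e10 RLU mm^-3
every 5 days, 10 boosters), an inter-dose period sweep (5 / 10 / 15 /
20 days), 30-day booster count sweeps, and single vaccinations with
enhanced cytotoxicity (`c4 = 2.49e5`) or enhanced local proliferation
(`kp3 = 5.73`). `summarize_trajectory()` reduces each run to peaks,
peak times, response durations and tumor metrics. "Response duration"
has no canonical definition here; we use the time between the first
and last crossing of a threshold, defaulting to 1% of the state's own
peak. Within a sweep the thresholds are held fixed across scenarios
(taken from the first scenario's peaks) — with per-scenario relative
thresholds a 100-fold larger dose would raise its own threshold
100-fold and the duration comparison would be meaningless.

The qualitative findings these tools reproduce: escalating the booster
dose lengthens the antigen and CTL response (about 12–13 days per
100-fold dose increase) while barely moving its magnitude; longer
inter-dose periods lower the peak blood CTL concentration (about 19%
from 5-day to 20-day spacing) while stretching the response envelope;
and no multi-vaccination schedule eliminates the tumor — but a single
vaccination does, within about 100 days, if either effector
cytotoxicity or local effector proliferation is raised enough. Under
the calibrated constants the tumor instead settles above the logistic
carrying capacity in an IFN-gamma-sustained quasi-plateau (`c_neg`
about 2.75 K with a large MHCI+ pool) that persists for hundreds of
days, relaxing to K only once the effector and cytokine states have
fully decayed — by day 800 the burden is within 0.2% of K. The
elimination dichotomy is sharp: with the one-cell extinction floor,
eliminated tumors stay eliminated through day 800, while the baseline
run never drops below its inoculum.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 49-day calibration
runs at `dt = 0.01` (about 5,000 steps), 800-day scenario runs with
the adaptive solver, a 100 x 150 GA recovery with five free
parameters (about 15,000 forward solves at `dt = 0.05`), and 50–100
random draws for the spectral and Jacobian property checks. Every
stochastic component (synthetic data, GA) takes an explicit integer
seed and restores the caller's RNG state afterwards.

## Known limitations

* The lymph-node compartment is deliberately coarse; the model places
  the lymph-node CTL peak earlier than real data show, a known
  structural trade-off for keeping the stability analysis tractable.
* `C(t)` enters the density equations as a raw count, and `epsilon`
  serves two dimensional roles; both are kept verbatim from the model
  definition.
* `beta1` (a gene-expression proportionality constant) is stored with
  the calibrated values but enters no equation; cytokine
  gene-expression observables use free positive AU scales defaulting
  to 1 in `observation_model()`.
* No immunosuppression, no spatial structure, no stochastic tumor
  take; schedule optimization beyond grid sweeps is out of scope.
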