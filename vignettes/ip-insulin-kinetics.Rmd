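---
title: "Modelling intraperitoneal insulin absorption and kinetics with ipkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intraperitoneal insulin absorption and kinetics with ipkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipkin)
```

## The modelling problem

Implanted intraperitoneal (IP) insulin pumps deliver insulin into the
peritoneal cavity, from which it is absorbed toward the liver — unlike
subcutaneous delivery, which reaches the circulation peripherally. A
pharmacokinetic description of this route needs two coupled pieces: a model
of absorption from the IP space into the liver, and a model of whole-body
insulin kinetics including the first-pass hepatic extraction that IP
delivery makes so consequential. `ipkin` implements a battery of nine such
models (three absorption structures × three hepatic-extraction laws), the
Bayesian machinery to fit them to plasma-insulin time series from a
basal–bolus study day, and the protocol to select among them. Because
clinical datasets of this kind are small and access-restricted, the package
also ships a synthetic-data generator that reproduces the statistical
structure the identification assumes, so estimator behaviour can be
studied on virtual cohorts with known ground truth.

## Model structure and assumptions

All amounts are in mU, times in minutes, volumes in litres, concentrations
in mU/L (insulin) and mg/dL (glucose); doses given in units are converted
at 1 U = 1000 mU. The insulin formulation's concentration (U-400) affects
only the delivered volume, not the mass, and is ignored.

**IP absorption.** Model 1 is a single compartment emptying into the liver
at rate `ka1`. Model 2 has two compartments in series (transfer `kd`,
absorption `ka2` from the distal one); since swapping `kd` and `ka2` leaves
the data distribution unchanged, the convention `kd >= ka2` pins the
labelling, enforced in estimation by the reparameterisation
`kd = ka2 (1 + delta)`, `delta > 0`. Model 3 absorbs from both compartments
(`ka1` proximal, `ka2` distal); its inter-compartment transfer runs at the
same rate `ka2` as the distal exit — the structure is implemented exactly
as stated, although a separate transfer rate would have been a natural
alternative. Note the nesting this creates: Model 3 with `ka1 = 0` is
exactly Model 2 with `kd = ka2`, and Model 2 with very fast transfer
approaches Model 1 — both reductions are verified numerically in the test
suite, and the first is the basis of one of the post-fit simplification
rules.

**Whole-body kinetics.** A two-compartment (plasma/liver) model with
measurement `Ip = Qp / VI`. The liver degradation rate is tied to the
hepatic extraction `HE(t)` by `m3(t) = HE/(1-HE) * m1`, and the peripheral
degradation rate to the post-hepatic clearance by `CL = (HEb m2 + m4) VI`.
The fractional hepatic plasma flow `m2` is fixed (default 0.268 /min, a
literature value) — the battery is identifiable only with `m2` known. The
three extraction laws are: constant (A); affine in plasma glucose (B),
`HE = -aG (G - Gb) + HEb`, which makes glucose an exogenous input — there
is deliberately no glucose–insulin feedback; and affine in liver insulin
(C), `HE = -aI (Ql - Qlb) + HEb`, which makes the kinetics mildly
nonlinear and encodes saturation of extraction at high intrahepatic
insulin.

Because the affine HE laws can leave the physical range, and `m3` diverges
as `HE -> 1`, the simulator clamps `HE(t)` to a configurable interval,
default `[0, 0.95]`, and reports when clamping was active. The bound is a
numerical safeguard, not a claim about physiology; fits that ride the clamp
should be treated with suspicion.

## Simulation

Simulations start at the exact basal steady state for the profile's basal
rate (derived by setting all derivatives to zero; the plasma/liver pair
solves a 2×2 linear system), so no burn-in is needed and a basal-only run
is constant by construction. Boluses are impulses: instantaneous additions
to the proximal IP compartment, with the integration restarted at each
bolus and at each meal-period parameter switch. Pump boluses are short
compared with absorption time constants (tens of minutes), which justifies
the idealisation; a square-wave option with configurable duration exists
for sensitivity checks. Meal periods — the spans over which absorption
parameters may differ — run from one meal bolus to the next, with the first
period starting at t = 0.

The right-hand side is compiled C integrated by `deSolve::lsoda` (rtol
1e-8, atol 1e-10 mU; output grid distinct from the internal steps), the
standard arrangement for compartmental PK models where an estimation run
needs thousands of solves. An auxiliary state accumulates the absorption
flux so the IP mass balance (delivered dose = IP mass change + integrated
flux) can be audited at solver accuracy; the tests hold it to 1e-6
relative over 24 h, and additionally check the trajectories against a
matrix-exponential solution in the linear (constant-extraction) case and
against the closed-form bolus response of Model 1.

## The synthetic study day

The generator emulates a hospitalized open-loop protocol: 24 h, three
meals, an implanted pump programmed as basal–bolus therapy. Defaults, and
why: daily insulin requirement 0.60 U/kg/day (the average reported for the
study population this design mirrors) for a 75 kg subject; half the daily
dose as constant basal, half split equally across meal boluses at 08:00,
13:00 and 19:00 (the split fraction is a design choice — the protocol's
actual per-patient regimens are not public); plasma insulin sampled every
10 min (145 samples — "frequent" sampling made concrete); measurement
error zero-mean Gaussian, uncorrelated, with known SD
`max(cv * Ip, floor)`, defaults cv = 6% and floor = 1 mU/L, typical of
plasma-insulin immunoassays (the study's actual assay SDs are not public
either; both numbers are configurable and the recovery harness sets them
explicitly). Negative measurement draws are truncated at zero and flagged.
Glucose, needed only by HE law B, is a smooth parametric trace: basal
level plus one log-normal-shaped postprandial excursion per meal peaking
~60 min after the meal.

Population draws are log-normal around the package's population-median
parameter values with configurable dispersion, with optional meal-by-meal
multiplicative variation of the absorption rates to mimic intra-subject
variability. What the generator does *not* emulate: assay drift or
correlated errors, delays or nonlinearities in IP absorption, intra-day
variation of the kinetics parameters, or any glucose dynamics. Passing
recovery tests on these data therefore demonstrates correctness of the
estimator under the model's own assumptions, not robustness to the ways
real patients violate them.

## MAP estimation

The objective is the negative log-posterior
`0.5 * sum(((y - yhat)/SD)^2) + sum((log th - log med)^2 / (2 sdlog^2))`,
with log-normal priors (given as median and CV) on `VI`, `m1`, `CL`, `HEb`
and flat positivity-constrained priors on the absorption parameters and the
extraction gains `aG`/`aI`. Estimation runs in log-parameter space (logit
for `HEb`), which enforces positivity without constraints. The optimizer is
multi-start Nelder–Mead (first start at the prior centres, the rest
jittered in log space, seeded) followed by alternating BFGS/Nelder–Mead
polish cycles: the posterior has long, flat ridges along correlated
kinetics parameters on which either method alone terminates early, a
failure mode we observed directly and test against. Parameter excursions
far outside the physical range are penalised with a large finite value
before the solver is invoked, keeping derivative-free search alive without
stalling the integrator.

Two simplification rules are applied after convergence, and the reduced
model refitted when one triggers: in Model 2, `kd` is tied to `ka2` when
their absolute relative difference is below 1%; in Model 3, `ka1` is set
to zero when estimated below 1e-3 /min. Collapsed parameters leave the
free-parameter count `P` and receive no CV.

Precision comes from the posterior information matrix in log coordinates —
the Gauss–Newton term `S' Sigma^-1 S` with sensitivities by central finite
differences on the simulator (relative step 1e-4), plus the prior
precision. Its inverse gives `CV% = 100 * sd(log th)`, which by the delta
method is exactly the relative SD of the natural-scale estimate. Whether
the prior precision belongs in a "parameter estimated with precision"
statement is genuinely arguable, so it is a toggle
(`include_prior_in_cv`, default on, recorded in the fit's metadata); for
Model 2 the covariance is computed in `(ka2, kd)` coordinates rather than
`(ka2, delta)` so the reported CVs refer to the parameters users care
about.

## Assessment and selection

Three instruments, in lexicographic order: (1) a Wald–Wolfowitz runs test
on the signs of the weighted residuals (two-sided — clustered *and*
over-alternating residuals both reject; normal approximation at 20+
residuals, exact enumeration below; exact zeros excluded); (2) the
percentage of estimated parameters with CV below 100%, pooled across
subjects, collapsed parameters excluded; (3) BIC, which under the known-SD
Gaussian error model reduces to `WRSS + P log N` after dropping a
data-only constant common to all models on shared data — medians across
subjects are compared, and ties break toward fewer parameters (and are
reported as ties). The precision stage keeps models within 2 percentage
points of the best precision fraction, a tolerance chosen so that a
two-point difference is not treated as decisive while a five-point gap is;
runs-test results are aggregated across subjects (maximal pass count)
rather than used as a per-subject veto. The published battery summary on
the original eight-patient study is reproduced in the tests as a worked
example of the protocol, which selects model 3C.

## Parameter recovery and what it teaches

The package's headline validation (`recovery_experiment()`, rerun from
scratch by `scripts/acceptance.R` and by the acceptance tests) generates
20 replicate virtual subjects from model 3C at the population-median
parameters and refits each with priors deliberately de-centred at 1.5× the
truth with 100% CV — centred priors would make recovery trivial. The
absorption parameters (`ka2` especially) and `HEb`, `CL` come back close
to truth with modest spread.

`VI` — and to a lesser degree `m1` and `aI` — behaves differently, and the
reason is structural. With `m2` fixed, the linearised map from absorption
flux to measured concentration exposes only three quantities: the gain
`m1/VI` (jointly with the loss rates) and the two pole coefficients — for
four unknowns (`VI`, `m1`, `m4`, `m3`). Only the weak extraction
nonlinearity of law C breaks this one-dimensional ridge, so the data alone
barely constrain where along it the estimate sits, and the posterior mode
for `VI` follows the prior centre and the noise draw rather than the
truth: in the recovery experiment its median lands well above the
generating value, by more than its own interquartile spread suggests it
should. This is a faithful property of MAP estimation for this model class
under weak, de-centred priors — the cure in practice is informative
population priors on the kinetics parameters, which is exactly how the
original analysis of this model family was run. Users fitting real data
should treat `VI` and `m1` estimates as prior-dominated unless their
priors are genuinely informative.

## Numerical and design choices, collected

* ODE: `lsoda`, rtol 1e-8 / atol 1e-10, compiled RHS, segment restarts at
  boluses and parameter switches; impulse boluses by default.
* HE clamped to `[0, 0.95]`, configurable; clamping logged.
* Optimizer: Nelder–Mead (default 5 starts; reltol 1e-8) + BFGS/NM polish;
  all stochastic pieces seeded.
* Sensitivities: central differences, relative step 1e-4.
* Runs test: normal approximation at n ≥ 20, exact below; pass at
  p ≥ 0.05.
* Exercised problem sizes (chosen to make the suite informative yet quick):
  recovery with 20 replicates; battery smoke runs with 2 subjects and a
  single-start optimizer; runs-test calibration with 10,000 length-50
  draws; error-model calibration with 500 replicate draws.

## Limitations

No glucose dynamics or feedback; no subcutaneous absorption model; no CGM
error model or meal-absorption model. The generator's clean-error,
stationary-parameter world is easier than reality. Identifiability of the
kinetics block leans on the priors, as discussed above; and all defaults
describing the study day (sampling, noise, dosing) are stand-ins for a
restricted clinical protocol, kept configurable precisely because they are
stand-ins.
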