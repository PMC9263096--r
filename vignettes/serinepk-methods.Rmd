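---
title: "Modelling L-serine kinetics over an endogenous baseline: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling L-serine kinetics over an endogenous baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serinepk)
```

## The problem

AST-001 is the L-isomer of serine, an amino acid the body synthesizes
continuously. Unlike a xenobiotic, its plasma concentration never decays to
zero: before any dose a healthy adult sits at a steady baseline of roughly
12.5 µg/mL, and after an oral dose the measured concentration is the sum of
that baseline and the absorbed drug. Any population model, and any exposure
metric used for dose selection, must handle the two sources jointly.

`serinepk` implements a population pharmacokinetic analysis of this system:
structural model, stochastic population layer, FOCE-with-interaction
estimation, phase-I trial simulation, baseline-adjusted non-compartmental
analysis, and allometry-based pediatric fixed-dose selection.

## Structural model

Disposition is a standard two-compartment linear system. Oral input is a
zero-order process: each dose `A` enters the central compartment at constant
rate `A/D1` for `D1` hours (the estimated absorption duration, about 1.26 h
— serine is absorbed quickly and a zero-order window describes the plateau
better than first-order absorption in this data-rich design). Elimination is
linear, `k10 = CLF/V1F`.

Endogenous production is a second zero-order input at rate `R1` (g/h) into
the central compartment, assumed at steady state throughout: the central
concentration contribution is `R1/CLF` with the peripheral compartment at
its equilibrium amount `R1 * V2F / CLF`. Two assumptions are deliberate:

* **Production enters the central compartment.** The data cannot locate the
  production site; central input is the parsimonious choice and is what the
  steady-state algebra above assumes. It is stated here once rather than
  guessed silently elsewhere.
* **No circadian or meal term.** The 24 h baseline profiles are flat to
  within noise under the trial's protein-restricted diet, so production is
  a constant.

Because the system is linear, everything is superposition: the model
concentration is the endogenous constant plus the analytic
constant-rate-input biexponential response summed over dose events. The
analytic solution is exact and fast (the simulations below push through
10^4–10^5 subjects); a numerical integrator of the same mass-balance ODEs
(`ode_reference`, deSolve/lsoda at tolerance 1e-12) is kept strictly as an
independent cross-check, and the test suite holds the two routes to within
1e-6 relative over random parameter sets and regimens. `Q/F = 0` or
`V2F = 0` degrade gracefully to the one-compartment limit.

Units are g, L, h internally (so concentrations are g/L); the interfaces
report µg/mL (× 1000).

## Population layer

Inter-individual variability is log-normal (`individual = typical × e^η`)
on `V1F`, `CLF`, `D1` and `R1`, with a covariance between the `V1` and `CL`
effects; `V2F` and `QF` carry none — this is the structure the
phase-I data supports. The published variabilities are reported as CV%;
`omega_matrix()` interprets CV% as `ω = CV/100` (the common reporting
convention for exponential models). The exact log-normal transform
`ω² = log(1+CV²)` is a constructor option; at these magnitudes (≤ 38%) the
difference is second-order. Residual error is proportional,
`observed = predicted × (1 + ε)`, `ε ~ N(0, 0.183²)`; simulated negative
observations are floored at zero and counted (they essentially never occur
at these concentrations). No inter-occasion variability: baseline and
dosing days were consecutive confinement days.

Allometric scaling uses fixed empirical exponents — 0.75 on `CL/F` and
`Q/F`, 1 on `V1F` and `V2F`, referenced to 70 kg. `D1` is a duration and is
not scaled. `R1` is **not** scaled by default: the scaling rule is declared
for the disposition of externally administered drug, and the pediatric
exposure results below are only consistent with an unscaled production
rate; a `scale_r1` switch exists for sensitivity analyses.

## Trial simulation

`build_scenario()` ships the phase-I designs: 24 subjects (8 per 10/20/30 g
arm) sampled 14 times over a 24 h baseline day and 13 times post-dose —
648 observations, 336 baseline and 312 post-dose, which pins the convention
that the pre-dose sample at the dose hour belongs to the baseline count.
The validation arm (7 subjects, 15 g single then 15 g BID × 7 days) ships
with the listed sampling times; the source trial reports 17 multiple-dose
observations per subject where the schedule lists 15, an unexplained
discrepancy we document rather than invent samples for. "Twice daily" is
implemented as q12h; with a terminal half-life near 15 h, 14 doses reach
steady state (the last two intervals differ by < 0.5% everywhere, a tested
invariant). Adult weights are drawn from a normal (mean 72.5, SD 8 kg)
truncated to the observed 54.5–86.9 kg range; the source reports only
median and range, so the shape is our choice.

What the generator does *not* emulate: assay error is Gaussian rather than
heavy-tailed-truncated, so about 0.06% of simulated observations fall under
the 4 µg/mL quantification limit even though the real trial recorded none —
a tail property to keep in mind when interpreting simulation minima; there
are no dropouts, no sampling-time deviations, and no food effects. Passing
tests therefore validate the computational chain, not these aspects of real
data.

## Exposure metrics and baseline adjustment

Exposure is corrected by time-matched baseline subtraction: the adjusted
concentration is `max(0, dose_day(t) − baseline_day(t))` at matching
relative times. With residual error off (the default for exposure
simulations, since medians of individual-prediction metrics are the
quantities of interest), adjustment recovers the exogenous contribution
exactly, by superposition.

NCA is deliberately minimal: Cmax/Tmax by sampled maximum (earliest on
ties), Ctrough at the end of the interval, AUC by linear trapezoid over the
window, no terminal-slope extrapolation — every reported metric is
interval-bounded. Metrics are computed on a 0.1 h simulation grid by
default. This matters: on the 13-point trial grid the sampled maximum
misses the true absorption peak by ~7% at steady state, and simulated
profiles (as opposed to observed ones) carry no obligation to the clinical
schedule; a `grid = "trial"` option reproduces the sparse-grid behaviour.
The single-to-multiple accumulation contrast simulates both arms on common
random numbers (the same subjects), the standard paired design that removes
between-subject variability from the ratio. Model-implied accumulation of
the 12 h AUC is ~41–43% (analytically, `AUCτ,ss / AUC12h,single =
655/458 ≈ 1.43` at the typical parameters).

## Estimation: FOCE with interaction

The marginal likelihood of each subject's data has no closed form. FOCE-I
approximates it in two steps, per subject:

1. **Conditional mode.** Minimize the exact joint −2 log density of the
   observations and `η`, with the proportional-error variance evaluated at
   the conditional prediction (the "interaction"). The package solves this
   with a damped Gauss–Newton iteration in compiled code: analytic gradient
   given the prediction sensitivities `G = ∂f/∂η` (central differences of
   the analytic model, step 1e-5), Gauss–Newton Hessian from the same `G`,
   Levenberg regularization, step cap at 1 log unit, convergence at
   gradient norm ~1e-7. The inner problem can be shallowly multimodal (a
   `D1`/`V1` trade-off with sparse absorption-phase sampling), so the mode
   is always solved from two deterministic starts — zero and the warm start
   from the previous outer iteration — keeping the lower joint density.
2. **Linearized marginal.** With `η̂` in hand,
   `y ~ N(f(η̂) − G η̂, G Ω Gᵀ + diag(σ² f(η̂)²))` gives the
   −2 log marginal contribution. The `n log 2π` constant is included, so
   the objective is directly comparable to exact quadrature; only
   differences matter for likelihood-ratio tests.

The test suite pins this objective against a 64-node adaptive
Gauss–Hermite quadrature of the true marginal likelihood on small instances
(within 0.5 units, measured ~0.1) and against the closed form when
`Ω = 0` (exact).

**Outer optimization.** The linearized objective depends to first order on
`η̂`, so discrete changes in mode selection leave small kinks that defeat
quasi-Newton line searches from distant starts. The outer search is
therefore a restarted Nelder–Mead simplex (restart until a round improves
by < 0.05 units) followed by a gradient polish (nlminb with explicit
central differences at step 1e-5, which sits well above the objective's
numerical floor); the polish result is only accepted if it improves. Omega
is log-Cholesky parameterized, so positive semidefiniteness is structural.
Fixed effects and sigma are log-transformed. A full 24-subject fit takes
roughly 20–60 s on one core.

Relative standard errors, when requested, come from the numerical Hessian
of the objective in the log-parameterization (delta method). The weight
covariate model of the original analysis — estimated power exponents on
`CL/F` and `V1/F` — is available (`covariate = "power_weight"`) for the
likelihood-ratio exercise: forward inclusion at ΔOFV > 3.84 (p < 0.05,
1 df), backward retention at > 6.63 (p < 0.01); the final model instead
fixes the exponents at the empirical 0.75/1 values through the scaling
rule.

**Bootstrap.** Subjects are resampled with replacement; each replicate is
refit from the original estimates. Because a resample is a multiset of the
original subjects, the replicate objective reuses the per-subject
likelihood with multiplicity weights. Replicates are optimized with a fixed
simplex budget (500 + 250 evaluations, conditional modes warm-started from
the original fit) and count as converged when a second simplex round moves
the OFV by < 2 units; non-converged replicates (typically ~25% under this
budget) are excluded and counted. Medians and
2.5/97.5 percentiles summarize the converged replicates.

**What recovery tests can show.** With 24 subjects, the sampling
distribution of the fixed-effect estimates has a CV of roughly 4–8%, and
maximum likelihood under proportional error carries a small downward
attenuation (the ML prediction for replicated noisy measurements sits
~σ² below their mean). Recovered `V2F`/`QF` in particular scatter widely —
the peripheral compartment is informed only by the terminal phase, where
the endogenous baseline dominates. Single-dataset recovery lands the
targeted parameters (`R1`, `CL/F`, `D1`) inside the published bootstrap
CIs most of the time, not always; that scatter is a property of the design,
not of the optimizer.

## Pediatric dose selection

For each integer weight and candidate dose, 100 subjects are simulated with
full IIV after allometric scaling, dosed q12h for 7 days, and the
steady-state AUC over the final interval is computed on the simulation
grid. The attainment metric integrates the **total** (endogenous +
exogenous) concentration: the target window 653–1214 h·µg/mL derives from
observed adult exposure after 15 g BID, and at pediatric weights the
endogenous term — which rises as clearance falls with weight, `1000·R1/CL·τ`
≈ 500–650 h·µg/mL at 10–14 kg — is the larger share of what a 2 g dose
achieves. An exogenous-only AUCτ (also returned, `auc_exo`) would sit far
below the window at every low-dose cell and support no fixed-dose regimen
at all.

Band attainment pools the simulated subjects of each integer weight in the
band uniformly — the pediatric weight distribution inside a band is not
part of the analysis and uniform pooling is our declared choice; it is the
main tolerance driver when comparing pooled percentages. `select_bands()`
partitions the weight axis greedily: extend the band while some dose keeps
pooled attainment above the threshold, close it with the best dose.
Band edges found this way can shift by a kilogram between runs at 100
subjects per cell; the stable claim, and the tested one, is that the
published five bands (2/4/7/10/14 g for 10–14/15–24/25–37/38–51/52–60 kg)
each attain > 70%.

## Numerical choices, degenerate inputs, limitations

* Times are hours; profiles must be strictly increasing in time for NCA;
  overlapping infusion events are legal (rates add).
* `Tmax` ties break to the earliest time; window edges interpolate
  linearly; AUC windows outside the sampled range are an error, never an
  extrapolation.
* `Q/F = 0` or `V2F = 0` is the one-compartment limit, not an error;
  `Ω = 0` collapses the FOCE objective to its exact closed form;
  `ω = 0` makes shrinkage undefined (reported `NA`).
* Simulation sizes in the test suite are chosen so Monte-Carlo error is
  small against each tolerance (up to 5000 subjects for median checks,
  200 bootstrap replicates, 100 subjects per pediatric cell).
* The model is built and validated on healthy adult males over
  54.5–86.9 kg; pediatric predictions rest entirely on the allometric
  assumptions, and disease effects on serine turnover are out of scope.
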