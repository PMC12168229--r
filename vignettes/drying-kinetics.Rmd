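---
title: "Thin-layer drying kinetics, moisture diffusivity and quality indices with drykin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-layer drying kinetics, moisture diffusivity and quality indices with drykin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drykin)
```

## The problem

Sliced plant tissue dried in a thin layer under combined infrared and
convective heating loses moisture in a falling-rate regime governed by
internal diffusion.  Practitioners summarise such experiments in three
layers of increasing mechanism:

1. **Semi-empirical thin-layer models.**  The moisture ratio
   $\mathrm{MR}(t) = (M_t - M_e)/(M_i - M_e)$ (dry-basis moisture
   normalised to start at 1) is fitted with closed-form decay curves.
   The equilibrium moisture $M_e$ is negligible for high-moisture
   produce dried to low water activity and defaults to zero here, so
   $\mathrm{MR} = M_t / M_i$.
2. **Fickian effective diffusivity.**  The slab solution of Fick's
   second law links the late-time log-linear decay of MR to a single
   lumped transport coefficient $D_\mathrm{eff}$ (m²/s).
3. **Arrhenius temperature sensitivity.**  Diffusivities across
   temperatures yield an activation energy $E_a$ (kJ/mol) from
   $\ln D_\mathrm{eff}$ versus $1/T$.

Alongside the kinetics, endpoint quality is summarised by the CIELAB
total colour difference $\Delta E$, the browning index, the shrinkage
ratio $S_r = 1 - V_d/V_o$, the rehydration ratio $R_r = M_r/M_d$, and a
shelf-stability classification of measured water activity
($a_w < 0.6$, strict).

## Units and the factor-of-two contract

Times are minutes everywhere except inside the diffusion and Arrhenius
internals, which convert to seconds in exactly one place
(`estimate_deff`) so that $D_\mathrm{eff}$ lands on the conventional
$10^{-10}$ m²/s scale.  Slice thickness is stored as the full thickness
in millimetres; the half-thickness $L$ in metres that enters
$D_\mathrm{eff} = 4 L^2 |\mathrm{slope}| / \pi^2$ is always derived via
`half_thickness()`, never stored, because the slab solution's $L$ is
half the slice thickness and the silent factor-of-two is the classic
failure mode of this analysis.

## The eleven-model registry

`thinlayer_models()` lists the registry; `fit_thinlayer()` fits one
model by bounded Levenberg–Marquardt least squares (via minpack.lm) and
`fit_thinlayer_all()` screens all eleven, ranking by ascending reduced
chi-square, ties by ascending RMSE, then descending $R^2$ — the
selection rule conventional in this literature.  Three registry choices
deserve explanation:

* **Modified Page** is implemented as
  $\mathrm{MR} = \exp(-(kt)^n)$, the standard form that actually
  distinguishes it from Page's $\exp(-k t^n)$.
* **Modified Henderson–Pabis** uses three independent amplitudes,
  $a e^{-kt} + b e^{-gt} + c e^{-ht}$; tying the third amplitude to the
  first would make the six-parameter family rank-deficient.
* **Thompson** is stated inversely, $t = a \ln \mathrm{MR} + b (\ln
  \mathrm{MR})^2$.  It is fitted in that inverse space (ordinary least
  squares of $t$ on $\ln \mathrm{MR}$ and its square — deterministic,
  no optimiser) and evaluated for $\mathrm{MR}(t)$ by solving the
  quadratic along the branch through $\mathrm{MR}(0) = 1$, clamping at
  the parabola vertex beyond its turning point.  Root-solving inside
  the optimiser would be both slower and less stable.

### Starting values, bounds, multistart

Every rate constant is seeded from a log-linear pre-fit of
$-\ln \mathrm{MR}$ on $t$; exponents start at 1, the Midilli amplitude
at 1 and its linear tail at 0.  For the multi-exponential families
(two-term, Verma, modified Henderson–Pabis) the neutral start "all
amplitude in the first term" is itself rank-deficient, so secondary
rates are staggered ($\times 3$, $\div 3$) and amplitudes split.
Bounds are generous envelopes around the magnitudes seen in practice:
rates in $(10^{-8}, 10)$ min⁻¹, exponents in $(0.1, 5)$, amplitudes in
$(-2, 2)$, the Midilli tail in $(-0.01, 0.01)$ min⁻¹.  `multistart`
(default 8) restarts jitter the start log-uniformly one decade either
side for scale-type parameters and additively for amplitudes, under a
caller-supplied seed, and the lowest residual sum of squares wins.
Non-convergence after all restarts is flagged on the returned object —
never silent.

## Goodness of fit

`gof_stats()` computes the battery on the MR scale: SSE,
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/N}$,
$\chi^2 = \mathrm{SSE}/(N - n)$, $R^2 = 1 -
\mathrm{SSE}/\sum(y_i - \bar y)^2$, a modelling efficiency computed
against the mean prediction, $SE = \sqrt{\mathrm{SSE}/(N-1)}$,
$SEE = \sqrt{\mathrm{SSE}/(N-n)}$ and the residual SD.  The identity
$\chi^2 (N - n) = \mathrm{RMSE}^2 N$ holds exactly and is enforced by
property tests.  EF and $R^2$ are reported separately even though they
coincide whenever the mean prediction equals the mean observation.

## The slope method and its window

`fick_mr()` evaluates the truncated slab series
$$\mathrm{MR}(t) = \frac{8}{\pi^2} \sum_{j\ge 0}
  \frac{1}{(2j+1)^2}
  \exp\!\Big(-\frac{(2j+1)^2 \pi^2 D_\mathrm{eff}}{4L^2} t\Big),$$
whose one-term truncation is the late-time asymptote.  Note the
truncated sum at $t = 0$ is below 1 by the analytic tail
$(8/\pi^2)\sum_{j \ge J}(2j+1)^{-2} \approx (8/\pi^2)/(4J)$ — about
$9\times10^{-4}$ at 200 terms — so resolving $t=0$ to $10^{-4}$ takes
roughly 2500 terms.  This is a property of the series, not a numerical
defect.

`estimate_deff()` regresses $\ln \mathrm{MR}$ on time over a
moisture-ratio window, default $\mathrm{MR} \in [0.02, 0.7]$: the
asymptote holds late in drying, and including early points (where
higher series terms still matter) biases the slope.  On full-series
curves the default window recovers the generating diffusivity to within
2%, which quantifies the one-term approximation bias; on one-term
curves recovery is exact regardless of the window.  The regression is
further restricted to the declining phase of the series (up to the
running MR minimum), because the slope method is defined on the
falling-rate period and pathological or noisy series can rise at late
times.  The estimate inherits the slab assumptions: uniform initial
moisture, symmetric transfer, negligible surface resistance,
diffusion-only transport, constant $D$, negligible shrinkage.  No
shrinkage-corrected diffusivity is attempted.

`fit_arrhenius()` requires explicit per-condition temperatures and
fails loudly without them, because drying experiments indexed by
infrared power do not determine a sample temperature by themselves.

## The synthetic experiment generator

`simulation_spec()` fixes the study conditions the package is validated
under; they are deliberately not tuning knobs.

* **Condition grid and truth.**  Nine power-by-airflow cells (1500,
  3500, 5500 W/m²; the airflow labels of the bundled reference table)
  with published Midilli–Kucuk constants for infrared-dried white onion
  as the default generator truth, or the published diffusivity grid
  (plus a 4/6/8 mm thickness series) for the Fickian mode.
* **Sampling.**  Five-minute intervals over 500 minutes, matching the
  several-hundred-minute horizon of such experiments.
* **Noise.**  Additive Gaussian on the MR scale, sd 0.005, truncated at
  $10^{-4}$: balance-reading error is approximately additive in mass
  and hence in MR, and this magnitude lands refit $\chi^2$ near the
  $10^{-5}$–$10^{-4}$ magnitudes of real fits.
* **Temperature map.**  Linear in power, 310 K at 1500 W/m² to 350 K
  at 5500 W/m².  This is an explicit, documented fiction needed only to
  exercise the Arrhenius stage; it is quarantined in the spec object so
  no analysis code depends on it implicitly.  Notably, combining it
  with the reference diffusivity grid yields activation energies of
  roughly 13–19 kJ/mol — below the 18–29 kJ/mol typical of published
  onion-drying work, whose (unreported) sample-temperature spans were
  evidently narrower.  The tests therefore anchor Arrhenius correctness
  on exact round trips of curves generated *from* known $E_a$ values,
  not on the band.
* **Masses.**  A 500 g fresh load at 85.8% wet-basis moisture converts
  MR trajectories to mass curves in grams.

Quality tables are generated from simple documented maps: shrinkage
falls with power (0.25 down to 0.16, airflow damping the fall),
rehydration rises with power and thickness (3.5 to 5.1), water activity
stays in 0.37–0.47 against a fresh reference of 0.962, and dried
colours drift from a fresh CIELAB reference (80, 2, 12) by a target
$\Delta E$ growing with power and thickness.

What the generator does *not* emulate: case hardening, shrinkage-driven
non-constant diffusivity, temperature dynamics during a run, batch
effects between replicates, and heteroscedastic late-time balance
error.  Passing tests therefore demonstrate the estimators invert their
own generative assumptions at realistic noise — not that those
assumptions hold for any particular dryer.

A caveat discovered while validating: some bundled reference constants
are internally inconsistent with the several-hundred-minute drying
horizon.  The 1500 W/m² slow-airflow row ($k = 0.001$ min⁻¹) reaches
only MR ≈ 0.56 by 500 minutes, and rows with a non-zero linear tail
$b\,t$ floor late-time MR above the ratio equivalent to 6% wet-basis
moisture (0.0106).  `drying_time_to()` exposes this as a diagnostic —
it returns `NA` when a target is unreachable — and drying times are
deliberately not asserted as a test invariant.

## Rational response surfaces

`fit_surface()` fits ratios of polynomials in (optionally
log-transformed) process variables, the functional family used to map
responses such as drying time, $\Delta E$, $S_r$, $R_r$ or the Midilli
constants onto power, airflow and thickness.  The denominator's
constant is fixed at 1 for identifiability.  Fitting linearises first
(multiply through by the denominator; one QR solve), then polishes the
true residual with Levenberg–Marquardt — deterministic and exact on
noiseless data from the same template.  Published coefficient sets for
such surfaces are not bundled as ground truth: their unit conventions
are typically ambiguous (radiant intensity appears variously in W/m²
and W/cm²), so the package fits the family to data rather than
replaying coefficients.  Evaluation outside the fitted variable ranges
warns; a denominator within $10^{-9}$ of zero is a domain error, not a
number.  A design with fewer points than twice the coefficient count
warns rather than fails, since the classic nine-cell grid fitted with
a six-term quadratic is exactly such a case.

On the nine-cell reference grid, the fitted drying-constant surface
$\hat k(I, V)$ is not pointwise monotone in power (the reference $k$
values themselves are not), but it predicts a strictly higher $\hat k$
at 5500 than at 1500 W/m² at every airflow level — the net-increase
form of the usual "drying accelerates with radiant power" finding.

## Browning-index constant

The chromatic coordinate is
$X = (a^* + 1.75 L^*)/(c\,L^* + a^* - 3.012 b^*)$ with $c = 6.645$ by
default, and $\mathrm{BI} = 100(X - 0.31)/0.17$.  Much of the browning
literature uses $c = 5.645$; the constant is an explicit argument
(`bi_denominator_constant`) rather than a hidden convention.  With the
6.645 default, typical pale-flesh colours yield slightly negative BI
values; the index is scale-sensitive by design and documented as such,
not "fixed".

## Problem sizes

The validation suite uses 100-point noiseless curves for parameter
round trips, 41-point curves (10-minute sampling over 400 minutes) for
diffusivity round trips, 45 noisy screens (5 seeds × 9 conditions) for
the model-selection study, a 200-replicate Monte-Carlo study for noisy
parameter dispersion, and 1000 random cases for the statistic
identities.  These sizes were chosen to estimate each property
comfortably; all are the package's own validation choices.

## Worked example

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 42)
bundle <- simulate_experiment(spec)
res <- run_pipeline(bundle$curves, quality = bundle$quality, seed = 42)
res$best                      # winning model per condition
res$deff[["I1500_V1.5"]]      # slope-method diffusivity
res$arrhenius                 # per airflow-thickness group
```

## Known limitations

* Slab geometry only; no finite-element or variable-$D$ solver.
* No sorption-isotherm (equilibrium moisture) modelling; $M_e = 0$
  unless supplied.
* No model averaging or information criteria; ranking follows the
  $\chi^2$/RMSE/$R^2$ convention of this literature.
* No kinetic modelling of browning or shrinkage over time; quality
  indices are endpoints.
* Water activity is stored and classified, never predicted.
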