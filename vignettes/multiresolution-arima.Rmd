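---
title: "Multi-resolution ARIMA characterization of cerebral physiologic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution ARIMA characterization of cerebral physiologic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrarima)
```

## The problem

Continuous neuromonitoring after moderate-to-severe traumatic brain injury
produces high-frequency arterial blood pressure (ABP), intracranial pressure
(ICP) and oximetry waveforms. Bedside practice reduces these to
minute-by-minute means and derived cerebrovascular-reactivity indices —
moving Pearson correlations such as PRx (ICP vs MAP), PAx (pulse amplitude
vs MAP), RAC (pulse amplitude vs CPP), RAP (pulse amplitude vs ICP) and COx
(rSO~2~ vs CPP) — and then often averages further, to hours or days, before
statistical modelling. Averaging does not remove serial dependence: both the
raw means and the derived indices carry autoregressive and moving-average
structure at every temporal resolution, and models that ignore it
(e.g. treating hourly means as exchangeable observations) mis-state their
own uncertainty.

`cvrarima` characterizes that structure. It takes per-patient
minute-resolution tables (or simulates realistic ones), reduces them over a
non-overlapping resolution ladder, classifies stationarity, grid-searches
ARIMA orders, compares model criteria across clinical subgroups, and
evaluates one-step-ahead forecasts.

## The model

On the differenced scale the working model for each patient x signal x
resolution cell is the standard ARIMA(p, d, q):

$$\Delta^d X_t = c + \sum_{i=1}^{p} \phi_i\, \Delta^d X_{t-i}
  + \sum_{j=1}^{q} \theta_j e_{t-j} + e_t,
  \qquad e_t \sim \mathcal N(0, \sigma^2).$$

Fits are maximum likelihood (`stats::arima`, CSS-initialized). For each cell
the package records the log-likelihood and recomputes
$\mathrm{AIC} = 2k - 2\ell$ and $\mathrm{BIC} = k \log n_\mathrm{eff} -
2\ell$ with $k = p + q + \mathbb 1[\text{constant}] + 1$ (innovation
variance) and $n_\mathrm{eff}$ the length after differencing, so that the
three criteria are mutually consistent. The optimum minimizes AIC or BIC or
maximizes LL; ties go to the smaller $p+q$, then the smaller $p$. A constant
is estimated only when $d = 0$ inside the fit: under differencing a constant
encodes a deterministic drift that the model deliberately omits.

Two conventions deserve emphasis:

* **Universal pre-differencing.** Every series is first-differenced once
  before the grid, and the grid's own `d` ranges over {0, 1}; reported
  `total_d` therefore lies in {1, 2}. The stationarity stage still reports
  the two-test *agreement flag* (ADF fails to reject a unit root AND KPSS
  rejects stationarity), but the flag documents the evidence rather than
  gating the differencing.
* **`p` starts at 1** in the default grid, so pure-MA models are
  unreachable; widen `p_range` to include 0 if you want them.

## Stationarity testing

No installed unit-root machinery ships with base R, so the two tests are
implemented in the package:

* **ADF** — regression of $\Delta x_t$ on $x_{t-1}$, a constant, and
  AIC-selected augmentation lags up to $\lfloor 12 (n/100)^{1/4} \rfloor$;
  p-values interpolate the Dickey–Fuller $\tau_\mu$ table (constant case)
  and are clamped to [0.01, 0.99].
* **KPSS** — level-stationarity statistic with a Bartlett-kernel
  (Newey–West) long-run variance at bandwidth
  $\lfloor 4 (n/100)^{1/4} \rfloor$; p-values interpolate the standard
  critical-value table and are bracketed at [0.01, 0.10]; the rejection flag
  compares against the 0.05 critical value directly.

The constant-only / level specification (no trend term) is the conventional
default for physiologic means that fluctuate around a setpoint. Cohort
tables label cells by the KPSS outcome alone; the ADF result enters only the
agreement flag. Calibration is verified in the test suite: on seeded
length-1000 series, iid Gaussians are labelled stationary and random walks
non-stationary in well over 90% of replicates, and first differencing a
random walk clears the flag.

## Signal derivation conventions

* 10-s frames are half-open `[t, t + 10)`; a frame containing any missing
  sample is `NA` (no silently shortened means).
* AMP, the cardiac pulse amplitude, is the amplitude of the dominant Fourier
  component of each demeaned 10-s ICP frame inside a configurable cardiac
  band (default 0.66–3 Hz, i.e. 40–180 bpm); a pure sinusoid of amplitude
  *A* returns exactly *A*. AMP is invariant to constant offsets by
  construction.
* Index windows hold 30 consecutive 10-s means (300 s) and are
  right-aligned: the value at minute *t* uses the 300 s ending at *t*,
  updated every minute. Windows containing any `NA`, or with zero variance
  in either series, give `NA` rather than a reduced-n correlation, so the
  effective window length never varies silently.
* COx-a reuses the MAP 10-s means as its ABP input.
* Raw signals reach minute resolution as the mean of the minute's six 10-s
  means.

## Resolution reduction and the gap rule

Missing runs of up to 4 consecutive minutes are linearly interpolated
between flanking observations; runs of 5 or more split the series into
separate contiguous segments (5 sits on the rule's boundary and is treated
conservatively, as exclusion). Leading and trailing gaps are trimmed, never
extrapolated. Downsampling takes non-overlapping block means within each
segment; a block is emitted only when at least 50% of its expected points
are observed, and a trailing partial block is dropped. Downstream stages use
the longest segment by default — concatenating across a long gap would
fabricate temporal adjacency. Interpolation happens once, at 1-min
resolution, before any reduction. Sufficiency thresholds: 30 observed points
for stationarity testing, 50 for the grid search; cells below threshold are
reported `NA` and excluded downstream, never errors.

## The synthetic cohort

The study's clinical data are not public, so the package ships a seeded
generator that gives every stage a known ground truth. It is a
sum-of-sinusoids-plus-noise abstraction, not a hemodynamic ODE — the
analysis characterizes statistical structure, and the generator only needs
to place that structure where the pipeline expects it:

* ABP = baseline + slow-wave component + cardiac sinusoid + white noise,
  where the slow component is a random-phase sum of six sinusoids confined
  to 0.005–0.05 Hz (the vasogenic band).
* ICP receives the slow component scaled by $g \cdot \kappa$ with fixed
  attenuation $\kappa = 0.5$ and coupling $g \in [-1, 1]$: $g = +1$ is fully
  passive pressure transmission (PRx near +1 downstream), $g = -1$ is
  counter-regulation (negative PRx). Cardiac tones in the two pressure
  channels are independently phased; the coupling acts on the slow band
  only, which is what 10-s averaging isolates.
* rSO~2~ channels track the slow component of CPP with a gain sharing the
  sign of $g$; PbtO~2~ is a smoothed random drift plus noise.
* Defaults: 50 Hz sampling, 1.2 Hz cardiac frequency (72 bpm), MAP baseline
  87 mmHg, ICP baseline 12 mmHg, slow-wave amplitude 5 mmHg — desk-scale
  values matching typical adult TBI cohort means, with the cardiac harmonic
  well inside Nyquist.
* Cohort covariates are drawn from fixed marginals (78% male; log-normal age
  with median 38 years; three pupillary-response levels; Marshall classes
  II–VI dichotomized at <5 vs ≥5). `subgroup_effects` can shift generating
  parameters for a named stratum so subgroup tests have known ground truth.
* The ARMA series generator runs the defining recursion with a burn-in of at
  least $10(p+q)$ discarded samples and integrates `d` times; AR and MA
  polynomials are checked for stationarity/invertibility up front.

What the generator does **not** emulate: ICP waveform morphology (P1/P2/P3
peaks), drainage artifacts, non-Gaussian artifact bursts, or nonstationary
autoregulation. Passing tests therefore certify the pipeline's statistical
machinery on signals with the right spectral placement and coupling — they
do not validate clinical conclusions on real recordings.

## Subgroup comparisons

Per-patient optimum criteria (AIC, BIC, LL) are compared across sex, age
(<40 vs ≥40), hypoxia, hypotension, pupillary response (three levels) and
Marshall group (<5 vs ≥5). Each comparison is independently gated by
Shapiro–Wilk normality at 0.05: two normal groups get a pooled-variance
t-test (Welch by flag), otherwise a two-sided Mann–Whitney U (exact when the
smaller group has ≤8 observations and no ties — verified in the tests
against brute-force enumeration of rank arrangements); three normal groups
get one-way ANOVA, otherwise Kruskal–Wallis. The raw 0.05 threshold is used
per cell with no multiplicity correction by default (a Benjamini–Hochberg
option exists). Under a simulated global null the per-cell rejection rate
sits near the nominal 5%.

## Forecast evaluation

One-step-ahead forecasting uses fixed per-patient orders: coefficients are
estimated once on the first half of the series (`train_fraction = 0.5`),
then the model state is filtered forward over the test half without
re-estimation, emitting each prediction before its observation is revealed.
This fit-once/filter-forward scheme is deterministic and fast; per-step
refitting is available by flag and agrees closely on stable series. If the
differenced training data are constant (a pure ramp), the closed-form
deterministic predictor is used instead of ML. Agreement is summarized by
Pearson r and Bland–Altman bias with limits of agreement
$\bar d \pm 1.96\, \mathrm{SD}(d)$ (sample SD), with differences oriented as
forecast − observed throughout.

## Numerical and reproducibility choices

* All simulators take explicit seeds and restore the caller's RNG state;
  identical configurations are bit-identical on repeated calls.
* Failed ARIMA optimizations return non-converged records with infinite
  criteria instead of raising, so grid completeness is auditable.
* Correlations are clipped to [−1, 1] against rounding overshoot; degenerate
  windows return `NA`.
* Pipeline CSVs carry one `#` comment line naming the stage, a hash of the
  configuration and the seed; empty cell = missing; re-running the same
  configuration reproduces the data CSVs byte-for-byte. Per-cell wall-clock
  fit times are written to a separate `timings.csv`, the one output that is
  host-dependent and exempt from the byte-identity contract.
* Problem sizes used in the shipped tests and acceptance script — 20
  order-recovery series of length 3000 on a p ≤ 5, q ≤ 5 grid; 100 + 100
  calibration series of length 1000; 200 null cohorts of 40 patients with
  one fixed-order fit per patient; a 5-patient, 8-hour determinism cohort at
  resolutions {1, 60, 1440} min — are the package's chosen desk-scale study
  conditions: large enough for the stated statistical properties, small
  enough to run on a single CPU in minutes.

## Worked example

```{r, eval = FALSE}
library(cvrarima)

cfg <- pipeline_config(
  sim = sim_config(seed = 42, n_patients = 5, duration = 480),
  resolutions = c(1, 5, 10),
  p_range = 1:3, q_range = 0:3)
res <- run_pipeline(cfg)

head(res$stationarity_table)   # % stationary / non-stationary / NA per cell
res$median_models              # population median (p, d, q) per signal
res$forecasts                  # per-patient r and Bland-Altman agreement
```

## Known limitations

* The grid is exhaustive, not pruned; at the full default ranges (220 cells)
  on long series it is slow by design — the paper-scale search is explicitly
  a batch job, and the package's supported mode is scaled grids.
* ADF/KPSS p-values are table-interpolated, so they saturate at the table
  edges ([0.01, 0.99] and [0.01, 0.10]); decisions at α = 0.05 are unaffected.
* Seasonal ARIMA, exogenous regressors and interval forecasts are out of
  scope.
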