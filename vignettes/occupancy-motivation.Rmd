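---
title: "Models and methods: from receptor occupancy to motivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from receptor occupancy to motivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occmot)
```

`occmot` quantifies the link between dopamine-receptor blockade and
motivated behavior in operant tasks. This vignette is the package's
account of the models it implements, the numerical choices behind them,
and what its synthetic-data validation does and does not establish.

## PET kinetics

### The simplified reference tissue model

A dynamic PET scan yields, for each brain region, a time–activity curve
(TAC): radioactivity concentration per frame over roughly an hour. For a
reversibly binding radioligand and a reference region devoid of specific
binding (the cerebellum for the dopamine ligands at issue), the
simplified reference tissue model (SRTM) writes a target-region TAC as

$$C_t(t) = R_1\,C_r(t) + \left(k_2 - R_1 k_{2a}\right)\,
  C_r(t) \otimes e^{-k_{2a} t},
\qquad k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

with delivery ratio $R_1$ (unitless), clearance $k_2$ (1/min), and
binding potential $BP_{ND}$ (unitless), the quantity of interest.
`fit_srtm()` uses the standard basis-function scheme: for each candidate
$k_{2a}$ on a grid, the convolution basis is precomputed and $(R_1,
k_2 - R_1 k_{2a})$ solved by weighted linear least squares; the grid
minimum is then polished by one-dimensional bounded optimization.

Numerical choices:

* **Grid**: 100 log-spaced $k_{2a}$ values on $[0.006, 0.6]$ /min, wide
  enough to bracket $BP_{ND}$ from 0 to ~20 at typical $k_2$; a solution
  on the grid edge raises a warning flag.
* **Convolution**: uniform 0.05-min internal grid, trapezoidal
  quadrature in recursive form (exact for the trapezoid rule), sampled
  at frame midpoints. The reference TAC is linearly interpolated from
  its frame midpoints with 0 activity at injection.
* **Weights**: proportional to frame duration, the usual proxy for
  frame-count precision when decay correction is out of scope.

The tests validate the scheme two ways: the forward generator is checked
against an independent direct-integral oracle on a 0.01-min grid (0.1%
agreement per frame), and the grid + refinement fit is checked against a
joint 3-parameter Nelder–Mead fit of the same objective ($|{\Delta}BP_{ND}|
< 10^{-3}$), plus noiseless round-trips recovering $BP_{ND}$ to better
than 1%.

### Occupancy

Receptor occupancy is the fractional loss of binding potential under a
blocking drug. `occupancy_from_bp()` implements the per-region form
$100\,(1 - BP_{ND}^{treat}/BP_{ND}^{base})$; `lassen_occupancy()`
implements the graphical (Lassen) form, regressing the per-region
reduction $BP^{base} - BP^{treat}$ on $BP^{base}$ — under uniform
blockade the slope is the occupancy, exactly so in the noiseless case.
Two open choices were settled as follows: the Lassen regression uses a
**free intercept** by default (a zero-intercept variant is available by
flag), because a free intercept absorbs any non-displaceable shift
instead of biasing the slope; and the pipeline reports **both** methods
per condition, defaulting to Lassen for multi-region input where the
across-region constraint is what lends the estimate its stability.

### Dose and washout calibration

Two one- and two-parameter models map treatment to occupancy:
$Occ(\%) = 100\,Dose/(ED_{50} + Dose)$ for an acutely washed-out
antagonist dosed at scan time, and $Occ(\%) = Occ_{Day0}e^{-\lambda Day}$
for an antagonist with multi-day washout. `fit_hill()` uses the exact
algebraic inversion when given a single (dose, occupancy) pair and
otherwise minimizes squared error in occupancy space over $ED_{50}$ only
— the asymptote is fixed at 100% on pharmacological grounds, and no
weighting is applied because replicate occupancy estimates carry similar
uncertainty. `fit_decay()` fits by nonlinear least squares in the
natural percentage scale, with a log-linear OLS used **only to
initialize**: fitting in log scale would be biased by noise truncation
near zero occupancy. The initializer is clamped strictly inside the
parameter bounds ($Occ_{Day0} \le 99.5$) because a Levenberg–Marquardt
start pinned on a bound can stall there; a second neutral start guards
against a bad log-init, and the lower residual sum wins.

## Behavioral models

### Trials, refusals, aggregation

A trial is correct when the bar is released in the half-open window
(200, 1000] ms after the go signal; releases at or before 200 ms
(including before go) are early, later or absent responses are late.
The boundary convention — 200 ms exactly is early, 1000 ms exactly is
correct — follows from treating "within 200 ms" as an error and
"between 200 and 1000 ms" as success. Early and late are pooled as
refusals; `aggregate_refusal()` also drops, per session, everything
before the first correct trial (start-of-session refusals reflect
impatience, not low motivation) and reports empty cells as absent, never
as rate 0. Count conservation (refusals + corrects = presentations per
cell) is enforced by test.

### Reward-size family

The inverse model $E = 1/(aR) + e$ relates refusal rate to reward size
$R$ in drops; $a$ (drop⁻¹) is the incentive impact, $e$ a
reward-independent refusal floor. Four nested sharing structures are
fitted — (#1) $a$ per condition with $e \equiv 0$, (#2) $a$ per
condition and one shared $e$, (#3) one shared $a$ with $e$ per
condition, (#4) both per condition — and compared by BIC. Structure #1
fixes $e$ at zero rather than omitting it; the two readings are
indistinguishable in fit but the zero-fix keeps the models strictly
nested.

"Random effects" over a handful of treatment conditions are implemented
as condition-specific fixed parameters counted individually in the BIC
penalty; with at most a few condition levels this is practically
indistinguishable from a marginal random-effects likelihood while
keeping the selection surface transparent.

Likelihood: **binomial on presentation counts** is the default — it is
the principled likelihood for rates and makes $n$ in the BIC the total
presentation count. A gaussian-on-cell-rates mode mirrors mixed-model
practice (cells as observations, $n$ = number of cells, one extra
residual-variance parameter) and is the mode to use when reproducing
LMM-style comparison tables; since the observation unit behind a
published BIC is often ambiguous, the fit object records the $n$ it
used. Model probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ inside
the binomial log-likelihood to keep it finite. Optimization is bounded
L-BFGS-B ($a \in [10^{-3}, 10^3]$, $e \in [0, 1]$) from three
deterministic starts ($a_0 \in \{0.5, 2, 8\}$), and the full model is
additionally started from each nested solution so the nesting
inequality $\log L_{\#4} \ge \log L_{\#1..3}$ holds by construction.
BIC ties below $10^{-6}$ resolve to the fewer-parameter model.

The incentive impact is reported normalized by the control condition
($a_c/a_{CON}$), making 1 the no-effect value and letting conditions be
placed on a common (occupancy, normalized incentive) axis — the join
`build_incentive_occupancy_table()` emits, with no smoothing.

### Cost family and RT relation

The work/delay task prices a reward in remaining cost units (CU): extra
instrumental trials (workload) or matched delay periods (0.3, 3.6, 7.2 s
mean durations). Refusal rates follow $E_{type} = k_{type}CU + E_0$ with
the intercept constrained equal across the two trial types within a
fitting unit — the intercept is the cost-free motivation level and must
not double as a second free slope. Variants facet the coefficients by
subject × condition, condition, subject, or nothing; each unit is an
independent least-squares fit and the variant BIC is the **sum of the
per-unit BICs** (each unit contributing its own $n$ and a 4-parameter
count: two slopes, intercept, residual SD). Fitted rates outside [0, 1]
at observed CU raise a flag but the linear fit is retained, as the model
is linear by construction. The RT relation (cell mean RT on cell refusal
rate) uses the same faceted-OLS machinery with variants pooled/by
subject/by condition/by both.

## The synthetic-data module

The generators are first-class, tested code; their defaults are the
study conditions every recovery test runs under.

* **PET**: the reference TAC is a fixed two-exponential analytic curve
  (uptake 0.9/min, washout 0.04/min, peak 25 kBq/mL near 3.5 min) —
  any smooth realistic input suffices for SRTM validation, which is
  about the kinetic transform, not the input shape. Target regions span
  $BP_{ND}$ 0.2–3.5 across ten regions (striatal through cortical).
  Treatment scans apply a **uniform fractional blockade** to every
  region's $BP_{ND}$ and reuse the baseline noise stream, so zero true
  occupancy reproduces the baseline TAC bit for bit.
* **Behavior**: refusals are Bernoulli draws from the model rates
  (clipped to [0, 1]); reward sizes are drawn equiprobably from
  {1, 2, 4, 8} drops; delay durations are uniform on the three cued
  ranges; RTs of correct trials are linear in the cell's refusal
  probability (intercept 280 ms, slope 150 ms per unit rate, SD 25 ms,
  clamped into the response window) and refused trials carry no RT.
  Refused trials are independent presentations by default;
  `repeat_refused_trials` instead emits explicit repeat-until-success
  chains, since aggregation counts presentations either way. Whether
  real refusal probabilities apply to presentations or to unique trials
  after repeats is not asserted; both streams are available.
* **Noise**: Gaussian on TAC frames (fraction of peak activity),
  Gaussian in percentage points on occupancy series (truncated to
  [0, 100]), binomial on refusals with no overdispersion.
* **Seeds**: one master seed per config; every generator stream derives
  a fixed substream from it, so outputs are bit-reproducible and
  streams never alias across stages.

What passing recovery tests do **not** show about real data: no
learning or satiety drift within or across sessions, no overdispersion
from session-level state, no arterial input or violation of the
reference-region assumption, no partial-volume or motion artifacts in
TACs. The generators validate the estimators under the stated model,
not the model against animals.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale, chosen to put
Monte-Carlo error well inside the asserted tolerances: 2,000
presentations per reward size for incentive-impact recovery (binomial
SE ≈ 0.18 drop⁻¹ at $a ≈ 5$), 100 replicate washout series at 3
percentage points of noise (SE of the mean day-0 estimate ≈ 0.3 pp),
100-run model-recovery sweeps for the BIC structure checks, and $10^5$
presentations for generator-mean checks at 5σ binomial bounds. All
stochastic tests fix seeds; the pipeline hashes its configuration into
the report provenance so identical configs are verifiably identical
runs.

## Known limitations

* SRTM assumes one-tissue kinetics in the target and a binding-free
  reference; violations bias $BP_{ND}$ in ways the package does not
  model (no partial-volume correction, no decay weighting, no voxelwise
  maps).
* The Hill model fixes its maximum at 100% occupancy; saturable
  non-specific effects would be absorbed into $ED_{50}$.
* The linear cost model can predict rates outside [0, 1]; it is used
  for its interpretable slopes, not as a generative model at extreme
  CU.
* Condition-specific fixed parameters stand in for random effects; with
  many conditions or partial pooling needs, a true mixed model
  (e.g. via `lme4`) would be preferable to the faceted-BIC scheme.
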