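---
title: "Wheat growth simulation and LAI assimilation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wheat growth simulation and LAI assimilation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safyr)
```

## The problem

Destructive field sampling gives accurate but sparse snapshots of crop
status; optical satellites give frequent but indirect ones. This package
implements the standard bridge between the two for winter wheat: a
minimal light-use-efficiency growth model (SAFY) whose few free
parameters are re-estimated per field by forcing the simulated leaf area
index (LAI) through LAI retrieved from canopy reflectance. Once the
model matches the observed canopy dynamics, biomass and grain yield fall
out of the calibrated simulation.

## The growth model

SAFY tracks three daily states from emergence: leaf area index $LAI$
(m² m⁻²), dry aerial mass $DAM$ (g m⁻²), and thermal time $SMT$
(°C·day). Daily mean temperature $T_a$ and global radiation $R_g$ drive
the recurrence:

$$\Delta DAM = ELUE \cdot F_T(T_a) \cdot (1 - e^{-K \cdot LAI})\,
  \varepsilon_c R_g$$

where $\varepsilon_c$ is the photosynthetically active fraction of
global radiation, $K$ the Beer–Lambert interception coefficient, and
$F_T$ a quadratic temperature response that is 0 at or beyond
$T_{min}$/$T_{max}$ and 1 at $T_{opt}$. Thermal time accumulates as
$\max(T_a - T_{min}, 0)$ per day. A fraction

$$Pl(SMT) = \max\!\big(0,\; 1 - Pl_a e^{Pl_b \cdot SMT}\big)$$

of each biomass increment goes to leaves, expanding the canopy by
$\Delta LAI^+ = \Delta DAM \cdot Pl \cdot SLA$; leaf allocation stops at
$SMT = \ln(1/Pl_a)/Pl_b$, which is the LAI peak. Once $SMT$ passes the
senescence threshold $STT$, the canopy decays by
$\Delta LAI^- = LAI \cdot (SMT - STT)/R_s$ per day, and the simulation
ends when senescence is underway and $LAI < 0.1$ (or after a 300-day
cap that guards the optimizer against non-terminating parameter
combinations). Grain yield is $GY = HI \cdot DAM_{max}$, reported in
t ha⁻¹ (×0.01 from g m⁻²).

Shipped defaults (winter wheat): $\varepsilon_c = 0.48$, $K = 0.5$,
$T_{min}/T_{opt}/T_{max} = 0/18/26$ °C, $SLA = 0.022$ m² g⁻¹,
$R_s = 6875$ °C·day, $DAM_0 = 4.2$ g m⁻², $HI = 0.5$,
$Pl_a = 0.16$, $Pl_b = 0.0025$ (°C·day)⁻¹. The three *sensitive*
parameters re-estimated per plot are the emergence day $D_0$, the
effective light-use efficiency $ELUE \in [1.3, 2.5]$ g MJ⁻¹ (which
absorbs unmodelled water/nitrogen stress), and
$STT \in [600, 1500]$ °C·day.

### Interpretation choices the equations leave open

* The production equation is read as a *daily increment* accumulated
  onto $DAM_0$ — the only reading consistent with a positive initial
  mass and with the leaf-expansion increment.
* Initial LAI is unstated in this model family's usual summaries; we
  use $LAI_0 = DAM_0 \cdot SLA$ (= 0.0924), the only mass→area link the
  model defines.
* The thermal-time sum would go negative on cold days if taken
  literally; the daily increment is clamped at 0 so $SMT$ is a proper
  accumulator (otherwise the senescence rule loses meaning).
* The senescence decrement is capped so $LAI \ge 0$.
* On days where growth and senescence both apply (possible when
  $STT < \ln(1/Pl_a)/Pl_b$), the increment is applied before the
  decrement. In that overlap regime LAI is *not* guaranteed unimodal —
  day-to-day weather variation can make it wobble around its peak. With
  the calibrated partition pair (allocation ends at $SMT \approx 733$)
  and $STT \ge 800$ the phases cannot overlap and the trajectory has a
  single interior peak; tests assert the phase-conditional
  monotonicity in general and strict unimodality in the non-overlap
  regime.
* $D_0$ is an integer day-of-season; optimizer proposals are rounded
  before simulation.

## LAI from reflectance

Six broadband vegetation indices (EVI, EVI2, MSR, NDVI, OSAVI, RVI) are
computed from blue/red/NIR reflectance, and empirical inversion models
map an index to LAI. Three functional forms are supported — linear
$y = ax + b$, power $y = ax^b$, exponential $y = ae^{bx}$ — fitted by
least squares on the original scale (log-linear closed forms provide
starting values; direct nonlinear refinement makes the minimized loss
match the reported RMSE diagnostics). The package ships the published
exponential OSAVI model $LAI = 0.21\,e^{4.68 \cdot OSAVI}$
(`osavi_reference_model()`), the best-ranked of the six.
`split_and_evaluate()` reproduces the evaluation protocol: a seeded
random two-thirds/one-third modeling/validation split, stratified by
acquisition date because dates differ strongly in LAI range, with
models ranked by validation R² (ties by RMSE).

A single-response NIPALS partial least squares regression
(`fit_plsr()`) is provided for multi-index prediction; with the full
component count it reproduces ordinary least squares, which the tests
use as its oracle.

## The optimizer

Per plot, the assimilation minimizes the root-mean-square LAI misfit

$$J(D_0, ELUE, STT) = \sqrt{\tfrac{1}{n} \sum_i (S_i - M_i)^2}$$

over the sensitive parameters, where $S_i$ is simulated LAI at the
$i$-th observation day ($LAI_0$ before emergence, 0 after senescence
completes) and $M_i$ the observed LAI (inversion-derived or measured —
both routes are supported so tests can separate optimizer error from
inversion error).

The minimizer is a shuffled-complex-evolution variant: a uniformly
sampled population of $m \times p$ points is repeatedly shuffled into
$m$ complexes; each complex is (1) checked by PCA for dimensional
collapse, restoring any direction carrying $<10^{-6}$ of total variance
with 1%-of-bound-width jitter on the worst half, (2) evolved by $2p-1$
simplex steps — reflection through the centroid of a
fitness-rank-weighted sub-simplex, half-way contraction on failure,
uniform redraw within the complex's bounding box as a last resort — and
(3) given one draw from the multivariate normal fitted to the complex
when no improvement was found. Iteration stops when the best value
improves by less than 0.01% (relative) for 20 consecutive cycles or
after 10,000 evaluations. Out-of-bounds proposals are clipped, so every
evaluated point is feasible; the best-ever point is retained, so the
reported value is monotone in budget. The move coefficients (reflection
1.0, contraction 0.5), the triangular selection weights, the step count
and the defaults $m = 3$, $p = \max(m+1, 2n+1)$ follow the
shuffled-complex literature; they are all exposed in `spuci_config()`.
Both printed population constraints ($p \ge m+1$ and the family
convention $p \ge n+1$) are enforced.

On benchmarks the implementation reaches $10^{-6}$ on a 5-D sphere and
$10^{-3}$ on the 2-D Rosenbrock well inside the 10,000-evaluation
budget on essentially every seed (tested: ≥9/10 and ≥8/10).

## Calibrating the partition coefficients

$Pl_a$ and $Pl_b$ are calibrated once per site from one season of
measured LAI and dry mass: for each $Pl_a$ on a grid over
$[0.01, 0.3]$, $Pl_b$ is solved in closed form from the condition that
allocation ends at the thermal time of the observed LAI peak
($Pl_b = \ln(1/Pl_a)/SMT_{peak}$, clamped to $[10^{-5}, 10^{-2}]$);
the sensitive parameters are then re-optimized and the pair minimizing
the dry-mass RMSE wins. Because $D_0$ is unknown at calibration time,
$SMT_{peak}$ is accumulated from the prior emergence day (about 10 days
after sowing). With a peak near $SMT = 733$ °C·day the grid point
$Pl_a = 0.16$ yields $Pl_b \approx 0.0025$, the standard calibrated
pair.

## The synthetic world

No field data accompany this package, so a generator emulates the trial
the analysis assumes: 48 plots (2 varieties × 4 nitrogen × 3 water
levels × 2 replicates), 7 reflectance acquisition days spread over
green-up through senescence, 6 destructive sampling stages, one harvest
yield per plot.

* **Weather**: temperature is a sinusoid with its trough in mid-January
  (−1 °C) rising to ~25 °C in June, sd 1.5 °C daily noise; radiation is
  a solstice-phased sinusoid from ~6 MJ m⁻² day⁻¹ midwinter to ~23 in
  June (sd 1.5). Magnitudes emulate a semi-arid continental site; an
  earlier draft tied radiation to the temperature phase with maritime
  magnitudes and produced agronomically implausible canopies
  (peak LAI < 1), so the radiation curve was set once to these values
  and not revisited.
* **Truth**: $D_0 \sim$ sowing + U{8..14} days; $ELUE$ = variety base
  (1.85/1.95) × nitrogen multiplier (0.85/0.95/1.05/1.10) + N(0, 0.04);
  $STT$ = 1000 + water offset (−100/0/+100) + N(0, 30); all clipped to
  the recovery bounds. Treatment effect sizes are invented; only their
  monotone direction (more nitrogen → higher yield) is asserted.
* **Observations**: LAI + N(0, σ_LAI) with σ_LAI = 0.3 (the order of
  reported LAI retrieval errors), dry mass × (1 + N(0, 0.1)), yield +
  N(0, 0.3) t ha⁻¹. Reflectance is constructed by inverting the OSAVI
  reference model — red drawn from a plausible range decreasing in LAI,
  NIR solved from the OSAVI definition, blue/green as fixed fractions
  of red, + N(0, 0.002) — so that with zero noise
  reflectance → indices → `predict_lai()` closes on the truth to 1e-6.

Everything is deterministic under a master seed, and generator calls
save/restore the caller's RNG state.

**What a green test establishes — and what it does not.** Recovery
tests on this world show the pipeline is self-consistent: the optimizer
finds parameters the generator hid, through the same model that
generated them. They do not establish that SAFY describes real wheat,
that the OSAVI model transfers across sites, or that field-scale
accuracy matches the synthetic bars: real canopies violate the model's
structure (no explicit water balance, index saturation at high LAI,
reflectance anisotropy), which is precisely why the published
field-data accuracies are far below the synthetic ones.

## Numerical choices

* Nonlinear inversion fits use `nls` with a `scaleOffset` so the
  relative-offset criterion remains meaningful on zero-residual data;
  the log-linear closed form is the fallback if refinement fails.
* The multinormal resample regularizes the complex covariance by
  $10^{-10}$ on the diagonal; a diagonal fallback covers indefinite
  cases.
* Non-finite objective values become $+\infty$ and the point is kept,
  so a pathological parameter region cannot crash a run.
* The daily recurrence precomputes every weather-only series (thermal
  time, stress, partition, decay factor); the assimilation cost calls a
  lean vector engine (~0.25 ms per evaluation), which keeps a full
  10,000-evaluation optimization near 2 s per plot.
* Metric conventions: R² defaults to the squared Pearson correlation
  (the printed ratio definition is available as `mode = "literal"` but
  is unbounded); nRMSE normalizes by the mean of the *estimates*;
  consistency classes are left-closed (`[10, 20)` is "good").
* CSVs use integer day-of-season rather than calendar dates: the model
  is a day-indexed recurrence and the synthetic world has no calendar
  anchor.

## Limitations

Single crop, single season, no soil water or nitrogen dynamics (stress
is folded into ELUE by design); no radiative-transfer inversion; no
raster-scale products; the optimizer is serial. The calibration's
closed-form $Pl_b$ assumes the observed LAI peak day is close to the
true allocation stop — coarse acquisition schedules blur this by a few
days, which the grid tolerance absorbs.
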