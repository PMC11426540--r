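---
title: "Modelling PSA-guided adaptive therapy in metastatic castrate-resistant prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PSA-guided adaptive therapy in metastatic castrate-resistant prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psadapt)
```

## The model

Metastatic castrate-resistant prostate cancer (mCRPC) under abiraterone is
modelled as three competing cell types: testosterone-dependent `T+` cells,
testosterone-producing `TP` cells (which upregulate CYP17A and supply the
androgens `T+` cells need), and testosterone-independent `T-` cells, which
are resistant to the drug. Their counts $x_i$ follow Lotka–Volterra
competition dynamics

$$\frac{dx_i}{dt} = r_i x_i \left(1 - \frac{\sum_j a_{ij} x_j}{K_i}\right),
\qquad i \in \{T^+, T^P, T^-\},$$

with intrinsic growth rates $r = (0.0027726,\ 0.0034657,\ 0.0066542)$ per
day (derived from doubling times of the LNCaP, H295R and PC-3 cell lines;
time units are days throughout — the `T+` doubling time is
$\ln 2 / r_{T^+} \approx 250$ days), a competition matrix $A$ with unit
diagonal and off-diagonal coefficients in $(0, 1]$, and carrying capacities
that encode the drug's mechanism:

* $K_{T^P}$ is 10000 cells off treatment and collapses to 100 under
  abiraterone (the drug blocks the CYP17A pathway);
* $K_{T^+} = \mu\, x_{T^P}$ is coupled to the current `TP` density, with
  $\mu = 1.5$ off treatment and $0.5$ under treatment — `T+` cells live off
  the testosterone their neighbours produce;
* $K_{T^-} = 10000$ cells always: resistant cells ignore the drug.

Serum PSA is an observation on this state, not an extra dynamical
variable. Because cell types secrete PSA at different rates, the package
models it as a convex combination

$$\mathrm{PSA}(t) = \alpha\, x_{T^+}(t) + \beta\, x_{T^P}(t) +
(1 - \alpha - \beta)\, x_{T^-}(t), \qquad
0 \le \alpha \le 1,\ 0 \le \beta \le 1 - \alpha.$$

The corners of this simplex are the limit cases in which a single type is
the sole PSA producer; $\alpha = \beta = 1/3$ recovers the common
"PSA tracks total burden" assumption up to scale.

## Protocols and the outcome measure

Two controllers are compared. Continuous maximum tolerable dose (MTD)
keeps treatment on for the whole course. The classical adaptive therapy
(AT) protocol treats until PSA falls to half of its baseline (its value at
$t = 0$), pauses until PSA recovers to baseline, and repeats — a hysteresis
state machine driven entirely by PSA. By convention a run only counts as
adaptive therapy if treatment was actually discontinued at least once
before progression; otherwise AT is reported as not applicable (`NA`).

Success is measured by the time to competitive release,

$$\mathrm{TCR} = \min\{t \ge 0 : x_{T^-}(t) \ge x_{T^+}(t) + x_{T^P}(t)\},$$

the first time the resistant clone becomes the tumor majority. Treatment
keeps cycling after TCR until the horizon; TCR is only the first crossing.
The simulation horizon defaults to 10000 days, comfortably beyond the
largest TCR of interest (~5400 days), and both thresholds and horizon are
arguments of `run_simulation()`.

```{r example, eval = FALSE}
pat <- representative_patient("responder")
mtd <- run_simulation(pat$params, pat$init, "MTD")
at  <- run_simulation(pat$params, pat$init, "AT", psa_weights(0, 1))
c(mtd = mtd$tcr, at = at$tcr)   # ~202 vs ~499 days
```

## Patient categories and presets

Off treatment the system settles into a coexistence equilibrium whose
`T-` frequency defines the response categories: best responders exclude
`T-` entirely (equilibrium frequency below 1e-6 — a numerically robust
reading of "absent"), non-responders hold a high resistant share (at or
above 20%, the boundary inclusive), responders sit in between.
`untreated_equilibrium()` solves for this point directly: on each of the
seven non-empty supports the equilibrium conditions are linear (the
coupling $K_{T^+} = \mu x_{T^P}$ keeps them linear), candidates must be
non-negative, and local stability is checked through the eigenvalues of a
finite-difference Jacobian. If several supports are stable the largest is
returned, making classification deterministic. Frequencies are invariant
to the carrying-capacity scale, so the classification is scale-free.

`representative_patient()` carries the standard preset for each category:
a category-specific competition matrix and initial cell counts
$(606.06,\ 757.58,\ 1.94\cdot 10^{-10})$, $(560.36,\ 747.59,\ 47.10)$ and
$(319.63,\ 707.76,\ 273.97)$. These initial conditions equal one tenth of
the untreated equilibrium at capacity 10000 — a derived observation the
package verifies rather than a definition. One caveat worth recording: the
identity is exact (to print precision) for the best-responder and
non-responder presets, but the standard responder initial conditions
deviate from the exact equilibrium of their matrix by up to 0.4 cells —
they satisfy the equilibrium equations only to about 1 part in $10^4$ and
are evidently themselves the output of a rounded numerical solve. The
package keeps the standard printed values verbatim in the preset (they are
the study conditions) and anchors the cohort generator to the exact
equilibrium instead.

## Numerical design

**Integration.** The piecewise-smooth system is integrated with
`deSolve::lsodar` (adaptive, stiff-capable) at `rtol = 1e-8`,
`atol = 1e-12`. The absolute tolerance must sit far below the smallest
meaningful population — the best-responder preset starts with
$1.94\cdot 10^{-10}$ resistant cells and the dynamics span 14 orders of
magnitude. Reported TCRs move by less than 0.1% when both tolerances are
tightened 100-fold (asserted in the test suite).

**Events.** Threshold crossings (PSA switching, the TCR margin) are
located by the solver's root finder rather than read off a sample grid; at
each switch the carrying-capacity regime flips and integration restarts
from the event state — the vector field is discontinuous there and no
smoothing is applied. Because the active AT event function jumps from the
half-baseline threshold to the baseline threshold at the moment of a
switch, crossing direction is enforced by the hysteresis itself and an
event can never re-fire at the switch point. Ties at $t = 0$ do not fire
(treatment starts on regardless). A degenerate baseline
$\mathrm{PSA}(0) = 0$ (only possible with $\alpha = \beta = 0$ and no
initial `T-` cells) degrades to a never-switching run reported as
AT-not-applicable rather than an error.

**Extinction tail.** Carrying capacities are floored at $10^{-9}$ cells so
$K_{T^+} = \mu x_{T^P} \to 0$ never divides by zero; populations are never
forcibly zeroed (the continuous-model convention). The floor alone,
however, makes the per-capita decline rate as large as $10^{13}$/day while
a population underflows through the sub-cell range, which stalls any
error-controlled integrator. The per-capita decline is therefore capped at
100/day — still a 10-minute half-life, i.e. instantaneous extinction on a
time scale where doubling times are hundreds of days — and the cap only
engages once $\mu x_{T^P}$ drops below about one cell, far outside the
macroscopic regime where TCR and PSA switching are decided. Capping
changed no reported TCR by even one part in $10^{12}$ in the full scan; it
only lets post-release locked-on courses integrate cleanly to the horizon.

**Reporting.** Event times are kept at full precision internally;
comparison tables print whole days, matching the convention of the
reference results. Percent improvements are computed from unrounded TCRs
and rounded to the nearest integer percent. Note the sensitivity: a
±1-day ambiguity on a 202-day baseline moves the percentage by ±0.75
points, so rounded percentages can differ by one from values recomputed
from rounded tables.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis
assumes: the six off-diagonal competition coefficients are drawn
independently and uniformly from $\{0.4, 0.5, 0.6, 0.7, 0.8, 0.9\}$ (all
$6^6$ combinations admissible), each patient is classified from their
untreated equilibrium, and initial conditions are `init_fraction` (default
0.1) times that equilibrium at capacity 10000 — the same construction that
produces the representative presets. Under uniform sampling roughly 80% of
virtual patients are non-responders; the three categories of the
representative presets are design choices, not the typical draw.

`synthesize_psa_series()` adds the one stochastic element: PSA sampled at
a clinic-visit cadence with multiplicative lognormal noise of unit mean
and chosen coefficient of variation. The underlying model is
deterministic, so noise is off by default; it exists to exercise protocol
logic against discrete, noisy measurements.

What the generator does *not* emulate: measurement-driven switching (the
simulated protocols act on continuous PSA), inter-patient variation in
growth rates or carrying capacities, PSA secretion dynamics (production
delay, serum decay), and any correlation structure among competition
coefficients. Passing tests therefore validate the dynamical and protocol
machinery under the study's assumptions — not the fidelity of those
assumptions to clinical PSA kinetics.

## Limitations

* PSA is a memoryless observation; delayed or decaying PSA kinetics are
  out of scope.
* Resistance is qualitative — `T-` is fully resistant, the others fully
  sensitive; no quantitative-resistance continuum.
* No stochastic (birth–death) version of the dynamics; populations are
  continuous, and sub-cell counts are a sanctioned regime of the model.
* The three representative competition matrices stand in for the full
  taxonomy of admissible matrices; the cohort generator samples that space
  uniformly instead of reproducing a clinical case mix.

## Problem sizes used by the tests and drivers

The packaged analyses are desk-scale: single simulations to a 10000-day
horizon cost tens of milliseconds; the 0.05-step weight-simplex scan is
231 adaptive-therapy runs per category (693 in total, about half a minute);
the long-time equilibrium oracle integrates $10^5$ days; the shipped
cohort driver samples 200 virtual patients.
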