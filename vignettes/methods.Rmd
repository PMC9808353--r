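---
title: "Methods: multi-state Markov forecasting of elderly care demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-state Markov forecasting of elderly care demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecast)
```

## The model

`carecast` treats elderly health as a five-state discrete-time Markov
chain. The states are an ADL-based disability grading — healthy, mild,
moderate, severe — plus death, which is absorbing: its matrix row is
exactly `(0, 0, 0, 0, 1)` and cumulative death mass is non-decreasing
along any trajectory. One step of the chain is the wave gap of the
estimation panel, 3 years by default, and the transition matrix is
stratified by five age bands (65–69, 70–74, 75–79, 80–84, 85+). The chain
is assumed *time-homogeneous*: the matrices estimated from one wave pair
are applied at every projection step, which encodes the substantive
assumption that age-specific morbidity, care standards and mortality stay
at their estimation-period values. Nothing enters or leaves the cohort
(no migration, no new 65-year-olds): the projected population is the
closed baseline cohort, which is exactly what an "oldest-old in 15 years"
question needs, and why the default reporting threshold keeps only
cohorts with attained midpoint age ≥ 80.

### Cohort aging

The matrices are stratified by age *band*, but a 15-year projection
crosses bands. Each baseline cell becomes a cohort carrying a
representative midpoint age — 67, 72, 77, 82, and 87 for the open band —
incremented by the step length after every transition; the matrix applied
at each step is that of the band containing the *current* midpoint (ages
≥ 85 use the open band). For a 65–69 cohort projected five 3-year steps
this gives the band sequence 65–69, 70–74, 70–74, 75–79, 75–79. This
band-switching scheme is the simplest one consistent with age-stratified
matrices, and it is checked against an explicit matrix-chain oracle in the
test suite. The open-band midpoint (default 87) matters only through band
lookup, and any value in [85, ∞) gives identical dynamics after the first
lookup; it is configurable via `age_groups(open_midpoint =)`.

Populations are projected as real-valued masses and rounded only at
reporting. Rounding inside the recursion would compound over five steps;
mass conservation (living + dead = baseline, to 1e-9 relative) is a tested
invariant precisely because the update is exact linear algebra.

### Transition estimation

Two estimators share one contract (row-stochastic output, absorbing death
row, both defined on the (age band × baseline state) grid):

* **Empirical**: `P(a,i,j) = (n(a,i,j) + α) / (n(a,i) + 5α)`. With α = 0
  this is the rowwise MLE; an empty row is then an error naming the cell.
  α = 0.5 is the suggested smoothing when sparse rows produce exact 0/1
  probabilities; such cells (row total < 20 and a raw proportion of 0
  or 1) are flagged on the returned object regardless of α, because
  published matrices of this kind do contain rows estimated from single-
  digit samples.
* **Multinomial logit**: maximum likelihood for
  `P(y=j|x) = exp(xβ_j)/(1 + Σ_k exp(xβ_k))`, reference category healthy.
  The *saturated* design (one indicator per grid cell) has the empirical
  proportions as its MLE — the package exploits this as an oracle
  equivalence test (agreement to 1e-6) rather than as a shortcut: the fit
  is still run through the likelihood machinery. The *additive* design
  (age + state main effects, 9 columns) is the package's smoothed
  alternative in the spirit of "adjusting extreme values": it pools
  information across cells and cannot produce the empirical zeros.

Numerically, the likelihood is maximized on grouped counts with an
analytic gradient via L-BFGS-B, box-constrained to |β| ≤ 30. The box is
the separation policy: a zero cell drives its log-odds to −∞, and a cap at
30 keeps the fitted probability below ~1e-13 — indistinguishable from zero
at the 1e-6 contract — while the optimizer stays finite; capped
coefficients raise a warning. The saturated fit is warm-started at the
closed-form log-ratios (shifted rowwise into the box so that log-ratio
*differences*, which determine the probabilities, are preserved), so
convergence is immediate and exact for interior cells.

Per-probability confidence limits are per-cell binomial Wald intervals
`p ± z·sqrt(p(1−p)/n)` clipped to [0, 1] (simultaneous Goodman-type
intervals are deliberately not used: the downstream perturbation analysis
is defined per probability), or percentile bootstrap over multinomial
row resamples. An observed 0 or 1 gives a degenerate zero-width Wald
interval — flagged by the smoothing machinery above rather than patched
here. Empty rows get (0, 1) limits and a warning.

### Demand

The human-population-ratio method is the WHO workforce-planning identity
`demand_s = ratio_s × population_s`. Schedules are configuration, not
code: the defaults are low = 1:10 / 1:8 / 1:6 / 1:4 and high = 1:5 / 1:4
/ 1:2.5 / 1:1.5 (staff : elders for healthy/mild/moderate/severe),
back-derived from the published demand-per-population table and validated
against every cell of it except one — the high-healthy cell, which prints
9.38 where the arithmetic gives 9.37 at 2 decimals; we treat that as a
source rounding artifact and exclude it from tests. Ratios must be
non-decreasing in severity. The default totalling policy is
*round-then-sum* (round each state's demand to 2 dp in millions, then
add), because that is the convention that reproduces the published totals
exactly; *sum-then-round* is available and differs by at most
4 × 0.005 = 0.02 million.

### Validation and uncertainty

The chi-square goodness-of-fit statistic is `Σ (O−E)²/E` with the
expected vector rescaled to the observed total, `df = k − 1`. The default
comparison is the four living states among survivors (df = 3) — the
published validation statistic's df is unstated, so the five-category
variant is supported and the choice is recorded in the validation
artifact. Expected categories must be positive; the error message advises
pooling rather than silently dropping cells.

Two interval methods:

* **Bound perturbation** pushes *all* transition probabilities to a
  confidence limit simultaneously and directionally: for the lower
  population bound, every deterioration entry (any move to a worse state,
  death included) takes its upper limit and the rest their lower limits;
  the upper bound reverses this. Perturbed rows no longer sum to 1, and
  the source method is silent on the repair, so the package renormalizes
  each row proportionally (and validates row-stochasticity to 1e-9). The
  result is labelled a *scenario bound*, not a calibrated interval — the
  directional extreme of every cell jointly is far outside the joint
  confidence region.
* **Monte Carlo** draws each living row from Dirichlet(counts + 1) — the
  conjugate posterior under a uniform prior, guaranteeing row-stochastic
  draws — projects under each draw, and takes percentile limits. This
  replaces the source's opaque WinBUGS simulation with an explicit,
  seeded resampler.

## The synthetic generator

`simulate_panel()` draws each individual's follow-up state independently
from the matrix row of their (age band, baseline state); default cohort
sizes reproduce the emulated survey's published marginals (n = 13,269,
heavily weighted to the 85+ band, baseline split 78.42 / 11.01 / 5.15 /
5.42%). `simulate_census()` splits per-state totals (defaults: 107.3,
6.4, 2.2, 2.9 million, the published 2010 65+ distribution) over age
bands by fixed weights with largest-remainder rounding, so state totals
are conserved exactly as integers. The age-by-state baseline of the
source is unpublished; the default weights (0.35, 0.28, 0.20, 0.11,
0.06) were chosen once to follow the shape of the 2010 Chinese 65+
census age pyramid and are not revisited. `fixture_panel()` is a
*deterministic* panel whose columns independently reproduce the published
descriptive marginals (including 57.38% female and the survivors-only
follow-up percentages); its joint distributions are arbitrary, so it
serves descriptive-summary tests only.

What a green test therefore establishes: the estimators recover the
generating matrix under independent multinomial sampling, and the
pipeline's arithmetic matches its oracles. What it does not establish:
robustness to features of real survey data the generator omits — survey
weights, attrition and loss to follow-up (everyone has a follow-up state
here), interviewer effects, within-household correlation, or covariates
beyond age and baseline state.

All generators take an explicit seed and restore the caller's RNG state
(`with_seed` internally), so stochastic tests are reproducible without
global side effects.

## Degenerate inputs and tie-breaks

* Largest-remainder rounding breaks fractional-part ties by position
  (first band wins), a deterministic choice that keeps census simulation
  byte-reproducible.
* The bundled matrix fixture is printed at 4 decimals, so raw rows sum to
  1 only within ~2e-4; the loader validates the transcription at 5e-4
  (integrity errors name the row) and renormalizes rows proportionally,
  after which the 1e-9 row-sum invariant holds everywhere downstream.
* `age_band_for()` errors below 65 (no matrix exists there) and maps all
  ages ≥ 85 to the open band.
* An all-zero perturbed row (possible only with pathological limits)
  cannot be renormalized and errors.

## Known limitations

* The additive logit design is a main-effects smoother; it will not
  reproduce genuinely interactive age × state patterns (the saturated
  design exists for that, at the price of sparse-cell noise).
* Scenario bounds from perturbation are conservative by construction and
  must not be reported as 95% confidence intervals.
* The projection is closed-cohort: questions about the *whole* 80+
  population of a future year (including those younger than 65 at
  baseline) are out of scope.
* Transition matrices are per-3-year-step; no annualization or
  continuous-time intensity estimation is attempted, so changing
  `step_years` changes the meaning of the matrices, not just the clock.
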