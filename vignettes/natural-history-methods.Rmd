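---
title: "Methods: a continuous-growth microsimulation of breast-cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a continuous-growth microsimulation of breast-cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcscreen)
```

## The model

`bcscreen` simulates, woman by woman, the latent natural history of
invasive breast cancer and superimposes mammography screening
programmes on it. The model has five submodels.

**Tumour onset.** Onset is defined as the moment a tumour reaches
0.5 mm in diameter; from there growth is treated as deterministic
given the woman's growth rate. The age at onset follows the two-stage
clonal expansion (Moolgavkar–Venzon–Knudson) model: susceptible cells
acquire an initiating event as a Poisson process of rate $\nu$ per
year; initiated clones grow as a linear birth–death process (division
rate $\alpha$, death rate $\beta$, both per cell-year) whose cells
acquire the malignant event at rate $\mu$. Writing $r_1 < r_2$ for the
roots of $\alpha z^2 - (\alpha+\beta+\mu)z + \beta = 0$, and
$A = r_2 - 1$, $B = 1 - r_1$, $g = \alpha(A+B)$, the probability that
a clone initiated $u$ years ago has not yet produced a malignant cell
leads to the closed-form onset hazard

$$h(t) = \nu\,\frac{\mu}{\alpha}\,
  \frac{1 - e^{-gt}}{A + B e^{-gt}},$$

whose integral is also closed-form (the identities $\mu = \alpha A B$
and $g = \alpha(A+B)$ collapse the partial fractions):

$$H(t) = \nu\left[\frac{\mu}{\alpha A}\,t
  - \frac{1}{\alpha}\log\frac{A+B}{A + Be^{-gt}}\right],
  \qquad F(t) = 1 - e^{-H(t)}.$$

The hazard rises smoothly from zero and saturates at
$\nu\mu/(\alpha A)$ around age $\log(B/A)/g$, which is what lets the
model mimic the flattening of breast-cancer incidence after
menopause. Both closed forms are verified in the test suite against
numerical quadrature of $h$.

**Growth.** Tumour volume grows exponentially from the onset volume
$V_0 = (\pi/6)(0.5)^3\,\mathrm{mm}^3$: $V(t) = V_0 e^{t/r}$. The
*inverse growth rate* $r$ (years per $e$-fold of volume; larger $r$ =
slower tumour) is a gamma random effect across women. Tumours are
spherical, so diameter and volume are interchangeable via
$v = (\pi/6)d^3$.

**Symptomatic detection.** The hazard of symptomatic detection is
proportional to the concurrent tumour volume,
$\lambda(t) = \eta V(t)$, giving
$\Lambda(t) = \eta V_0 r\,(e^{t/r}-1)$ and the exact inverse-transform
sample $t = r\log\!\left(1 + E/(\eta V_0 r)\right)$, $E \sim
\mathrm{Exp}(1)$. Size at symptomatic detection follows from the
growth curve; larger and faster-growing tumours surface sooner.

**Nodal spread.** Conditional on tumour volume $v$ at detection, the
number of positive lymph nodes is negative binomial with mean
$c\,v^{\omega}$ and dispersion `size`; the mean is nondecreasing in
volume, reflecting a spread process that accumulates with tumour
burden. The same node-count uniform is reused across detection
scenarios via the quantile function, so a woman's nodal burden is
coupled between scenarios.

**Screening and competing mortality.** A programme is an ordered list
of round ages. At each round attended while the tumour is latent
(onset before the round, symptomatic detection strictly after it),
detection occurs with probability
$\mathrm{expit}(\beta_0 + \beta_1 d)$ evaluated at the latent diameter
at that age — no extra size noise. Screen detection is the first
positive round. Other-cause death ages are drawn from a life table by
piecewise-constant-hazard inversion. Post-diagnosis
breast-cancer-specific survival is a mixture-cure model: cure
probability $\mathrm{expit}(c_0 + c_d d + c_n n)$ and Weibull survival
for the uncured with scale $\exp(s_0 + s_d d + s_n n)$, conditional on
the diameter $d$ and node count $n$ *at detection*. The mode of
detection influences survival only through these features: that is
exactly the stage-shift mechanism by which early detection helps, and
it keeps the survival model identifiable from registry-style inputs.

For every woman two breast-cancer survival times are drawn — one from
the screen-detection scenario's stage, one from the would-be
symptomatic stage — and the other-cause death age is shared between
scenarios. The two draws are sampled independently (not
quantile-coupled): a woman's survival difference can therefore be
negative, and the lower percentile of per-round survival differences
is allowed to dip below zero, which is the behaviour the metric is
meant to exhibit. The realised outcome is whichever comes first:
screen detection, symptomatic detection, or death before diagnosis.

## Outcome definitions

* **Overdiagnosed** — screen-detected, with other-cause death before
  the would-be symptomatic detection age.
* **N-shifted / T-shifted** — not overdiagnosed, and the nodal (size)
  category at screen detection is below the would-be symptomatic
  category; N-shift takes precedence and absorbs doubly-shifted
  cases. T boundaries are 20 and 50 mm; N boundaries 0, 3, 9 nodes.
  A value exactly on a boundary belongs to the lower category — the
  printed stage table is ambiguous there, and with continuous sizes
  the convention never moves a tally.
* **Lead time** — would-be symptomatic age minus screen age
  (screen-detected only; nonnegative by construction).
* **Survival difference** — all-cause death age under screen
  detection minus under symptomatic detection; counting both from the
  would-be symptomatic date is equivalent and removes lead-time bias.
  Exactly zero for everyone not screen-detected.
* **Life-expectancy gain per mammogram** — per round, the sum of
  survival differences of cases detected at that round divided by
  the mammograms performed at that round (days); its reciprocal is
  mammograms per life-year gained.

Averages of lead time and survival difference are taken over *all*
screen-detected cases, overdiagnosed ones included; restricting to
non-overdiagnosed cases is a one-line subset on the records if a user
prefers the alternative denominator. Both the share of overdiagnosed
cases among all screen-detected and per-round shares are reported, so
either denominator convention can be recovered.

Interval cancers are symptomatic cases occurring after at least one
attended screen and before the end of the screening window (last
round age plus one interval); the tally merges them with other
symptomatic cases, and the per-round breakdown attributes them to the
preceding round.

## Randomness and reproducibility

A master seed spawns one sub-seed per simulation chunk (default
100,000 women); within a chunk all uniforms are drawn up front in a
fixed order. A run is therefore bit-reproducible given `(seed, n,
chunk_size)`. All programmes passed together to `simulate_cohort()`
reuse the same latent histories and the same per-round detection
uniforms (indexed by round age), i.e. common random numbers: an
extended programme can only detect the same woman earlier, never
later, and programme contrasts are free of between-arm noise. The
mammogram performed at the detecting round is counted as performed
(it is an examination that happened); attendance is 100% by default
with an optional per-round attendance probability.

## Parameters

The default set is **synthetic** (`default_nh_params()`,
`inst/extdata/params_synthetic.json`). No individual-level data stand
behind it; it was calibrated once so that the no-screening pipeline
reproduces summary features of a Northern-European screening setting,
and then frozen:

| Parameter | Value | Units / meaning |
|---|---|---|
| $\nu$ | 0.051 | initiation events/year; sets lifetime risk ≈ 15% |
| $\alpha$, $\beta$, $\mu$ | 1, 0.902, 1.1e-4 | clone division/death/transformation rates; shape incidence rise and its saturation near age 70 |
| $r \sim \Gamma$ | shape 1.4, rate 2.0 | mean inverse growth rate 0.7 y (volume-doubling median ≈ 6 months) |
| $\eta$ | 2.6e-4 | per mm³·year; median symptomatic diameter ≈ 22 mm |
| NB nodal | size 0.32, mean $0.008\,v^{0.5}$ | ≈ 35–45% node-positive at symptomatic sizes |
| Sensitivity | expit(−4.0 + 0.5 d) | 0.5 at 8 mm, ≈ 0.98 at 16 mm |
| Cure | expit(2.7 − 0.06 d − 0.30 n) | case fatality ≈ 26% without screening |
| Uncured survival | Weibull(1.2, e^{2.0 − 0.015 d − 0.08 n}) | median ≈ 4–6 y, stage-dependent |

The synthetic Gompertz–Makeham life table
($\lambda(x) = 3\times10^{-4} + 8\times10^{-6}e^{0.105x}$, terminal
age 110) has life expectancy 84.2 years at birth, resembling a modern
high-income female population; `derive_other_cause_table()` supports
building a real other-cause table by subtracting cause-specific from
all-cause rates (floored at zero).

Because the set is synthetic, passing tests demonstrate the
*correctness of the machinery* — samplers match their closed forms,
competing events resolve exactly, categories conserve, common random
numbers give the documented monotonicities — and the *plausibility* of
aggregate outputs, not agreement with any specific national registry.
Users with fitted estimates (e.g. maximum-likelihood fits of the
onset/growth/detection submodels to a screening cohort) should supply
them via the parameter JSON, together with the Hessian-based
covariance in place of the synthetic one used for illustration.

## Numerical choices

* The onset CDF is evaluated on a cached grid (ages 0–120 in steps of
  0.05 y) and inverted by monotone linear interpolation; the grid bias
  is below $2\times10^{-4}$ in CDF units, an order of magnitude under
  the Monte-Carlo noise of the largest runs used. Uniform draws above
  $F(120)$ mean the woman never develops a tumour (`Inf`).
* A screen scheduled exactly at the symptomatic-detection age is
  pre-empted by symptomatic detection (symptomatic events own the
  closed boundary); a detection tied with death resolves to death.
* All death ages are truncated at the life-table terminal boundary
  (`max(age) + 1`), where death is forced.
* Survival draws use inverse-CDF sampling throughout so that shared
  uniforms give monotone coupling where coupling is wanted.
* Parameter-uncertainty draws that violate positivity constraints are
  rejected and redrawn, with the rejection count recorded.

## Problem sizes

The test suite verifies distributional agreement at $10^5$–$10^6$
draws per sampler and runs end-to-end cohorts of 2–5×10⁴ women per
property; the whole suite completes in a few minutes on one core. The
acceptance script uses five runs of one million women for the
programme tallies and 25 parameter draws × 200,000 women for the
uncertainty intervals; these sizes give Monte-Carlo errors well below
the differences being reported (≈0.3% on counts of order 10⁵ per
million).

## Limitations

* Invasive cancers only: ductal carcinoma in situ — likely the larger
  share of real-world overdiagnosis — is outside the model.
* No false positives or recall/specificity modelling, so harms are
  understated on that axis.
* Attendance defaults to 100% of invited rounds; no attendance
  selection effects.
* No covariates (density, BMI, HRT): the submodels are
  population-homogeneous apart from their random effects, though the
  architecture accepts covariate-dependent parameter files.
* The default parameterisation is synthetic, calibrated to summary
  statistics; absolute outputs should be read as illustrative until
  fitted parameters are supplied.
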