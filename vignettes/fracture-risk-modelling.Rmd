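---
title: "From a district fracture registry to FRAX-style probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a district fracture registry to FRAX-style probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipfrax)
```

## The problem

Country-specific fracture risk tools need two local ingredients: age- and
sex-specific hip-fracture incidence, and all-cause mortality. In much of
Eastern Europe and Central Asia, hospital discharge data alone
undercount hip fractures badly, because a large share of patients is
never admitted — they are managed as outpatients, in primary care, or
never reach medical attention at all. A credible incidence study in such
a setting therefore canvasses every care pathway in a well-delineated
catchment area (inpatient and outpatient units, primary care, coroners,
home-visiting nurses and community informants) over a fixed window, and
then filters the pooled reports down to countable events.

`hipfrax` implements that analytic chain end to end: registry filtering,
incidence estimation with exact small-count confidence intervals,
imputation of major osteoporotic fracture (MOF: hip, clinical spine,
forearm, humerus) rates from hip rates, competing-risk integration to
10-year and remaining-lifetime fracture probabilities, and projection of
fracture counts onto population pyramids.

## Registry model and filters

A registry row is one suspected fracture report with its eligibility
attributes. Eligible cases are low-energy (fall from standing height or
less), non-pathological, in permanent residents at or above the minimum
age, with an event date inside the study window. Filters run in the fixed
order *window, residence, age, energy, pathological* so that each removed
record is attributed to exactly one reason; the surviving set is
invariant to the order (set intersection commutes), and the suite checks
this by permutation. Repeat reports of the same fracture — the same
person and the same proximal-femur site code within the observation
window — collapse to the earliest record, with date ties broken in favour
of radiograph-confirmed records and then by record id. Records whose site
code is unrecorded are admitted only when radiograph-verified.

`person_key` is an input column: probabilistic record linkage across
facilities is deliberately out of scope, as is any cross-site collapsing
(a hip fracture and a contralateral or different-site fracture in the
same person are two events).

## Incidence and exact intervals

Person-years per band are census headcount times the one-year window; no
mid-year adjustment is attempted because the catchment population is a
single census figure. For `k` events over `E` person-years the package
reports `1e5*k/E` with the exact (Garwood) interval from chi-square
quantiles, `lo = qchisq(alpha/2, 2k)/(2E)`, `hi = qchisq(1-alpha/2,
2k+2)/(2E)`. The exact method is the defensible default at the counts a
district registry produces (1–13 events per band): it guarantees nominal
coverage, at the price of conservatism that fades as counts grow.

Display rounding follows the convention of printed incidence tables —
half-up to integers at or above 1 per 100,000, one decimal below 1 —
and is applied only at the formatting edge; nothing internal is rounded.

Two reproduction caveats are worth recording, because the packaged
district fixture reconstructs a published surveillance table cell for
cell. First, two of the printed rate cells (men 65–69 and 70–74) are one
unit above half-up rounding of `1e5*k/E`; the printed values behave like
double rounding (469.48 → 469.5 → 470). Second, the printed confidence
intervals cannot be reproduced by the exact Poisson interval under any
consistent rounding rule — at larger counts they are systematically a
few units wider on both sides, and mid-p, Byar and Wald-type
alternatives fit even worse. The generating tool is unidentifiable from
the printed digits, so the package keeps the exact method and the test
suite documents (rather than masks) the 12 non-matching interval pairs
and the two double-rounded rate cells.

## Hazards, survival and fracture probability

Rate tables become piecewise-constant hazard schedules on their own age
bands: no graduation or interpolation to single ages, matching the
resolution of the data and keeping every integral closed form. The
terminal age defaults to 110 and acts as absorbing truncation. With
fracture hazard $h_f$, death hazard $h_d$ and a relative-risk multiplier
$RR$ on the fracture hazard, the probability of a first fracture within
horizon $T$ of age $a$ is

$$P = \int_0^T RR\,h_f(a+t)\;
  \exp\!\Big(-\!\int_0^t \big(RR\,h_f + h_d\big)\,du\Big)\,dt ,$$

accumulated segment by segment: a segment of length $\Delta$ with
constant hazards $(f, d)$ entered with event-free mass $S_0$ contributes
$S_0\,\frac{f}{f+d}\big(1-e^{-(f+d)\Delta}\big)$ to fracture,
the analogous $d/(f+d)$ share to death-first, and multiplies $S_0$ by
$e^{-(f+d)\Delta}$. Fracture, death-first and event-free masses sum to 1
to machine precision, which the suite asserts at `1e-12`. The remaining
lifetime probability is the same integral run to the terminal age.

Design choices made where the convention was genuinely open:

* **First fracture is absorbing.** The integral is a time-to-first-event
  probability; recurrence is not modelled.
* **No post-fracture excess mortality.** Published national calibrations
  fold an excess-mortality term into the hip model; its coefficients are
  not public, so mortality here is all-cause throughout. Results carry a
  note to that effect.
* **A single multiplicative, age-invariant relative risk** stands in for
  the proprietary multi-factor clinical-risk machinery (`risk_profile()`,
  e.g. RR ≈ 1.8 for a prior fragility fracture). It scales only the
  fracture hazard.
* **Continuous closed-form integration** rather than 6- or 12-month
  cycles; the discrete-time multistate chain exists only as a test
  oracle, which converges to the closed form at rate $O(\Delta t)$ and
  agrees to six decimals at $\Delta t = 10^{-4}$ years.

MOF incidence is imputed band-wise as hip rate times an age/sex-specific
MOF/hip ratio. The well-known Scandinavian ratio tables are cited, not
printed, in the surveillance literature this package accompanies, so the
packaged ratio table (`inst/extdata/mof_hip_ratio_synthetic.csv`) is
**synthetic and illustrative**: smoothly declining with age, women above
men, floored at 1.6. Ratios below 1 are rejected — MOF includes hip by
definition, which also yields the tested dominance property
(MOF probability ≥ hip probability at every age).

## Projections

Expected counts are rate × persons summed over bands at or above the
age cut (default 50), with rates held fixed over calendar time — the
stated stable-incidence assumption of demographic burden projections.
Reproducing any particular national table requires that country's UN
population-prospects pyramids, an external download; the method is
instead pinned down by exact linearity, additivity and element-wise
oracles on synthetic pyramids. `uncertainty_bands()` adds parametric
Poisson percentile intervals around a point projection: counting noise
only, not demographic or rate uncertainty.

## What the synthetic generator does and does not emulate

`simulate_registry()` draws band counts as Poisson(rate × persons),
ages uniformly within bands (no within-band age distribution is
published; uniform is the neutral choice), dates uniformly in the
window, pathway labels from a stated mix (default: about a third
inpatient, a quarter outpatient-only, ~29% primary-care-only, ~11%
community-identified — the care setting the package's fixture depicts),
and appends decoy records that each violate exactly one eligibility
criterion, labelled in a hidden `decoy` column so filter tests can
assert exact behaviour. All randomness flows from one explicit seed
through an RNG-state-preserving wrapper; no global state leaks.

It does **not** simulate under-ascertainment (cases missed by every
pathway): the published 41% non-presentation figure is a finding about a
particular setting, not a generative mechanism, so a green
parameter-recovery test establishes correct estimation from *observed*
reports, not robustness to unobserved ones.

Parameter recovery is tested at province scale: the district truth rates
applied to a catchment 25× the district (≈1.7M adults 40+, band counts
~50–600). The scale was fixed analytically before the test was first
run: exact-interval coverage is ~97–98% at district-size counts purely
from conservatism, and settles to ~95.3% at the scaled counts, which is
what the 94–96% recovery criterion presupposes. The two double-rounded
rate cells and the interval-method mismatch described above are the only
known departures from the printed fixture table.

## Numerical notes

* Band membership is `age_lo <= age < age_hi`; the terminal band is open.
* Zero-population bands with zero events report rate 0; events in a
  zero-population band are an error.
* `survival()` and the probability integrals error outside schedule
  support rather than extrapolating.
* Segment integration skips zero-length segments and handles
  `f + d = 0` exactly (no contribution, survival unchanged).
* Display rounding is half-up (`floor(x + 0.5)`), not banker's rounding,
  to match how incidence tables are printed.

## Limitations

Incidence from one district and one year carries wide intervals and an
untestable catchment-population estimate; the package propagates the
rates it is given and cannot repair denominator error. The probability
engine is a mechanically faithful but deliberately reduced FRAX-style
core: no BMD input, no multi-factor risk model, no post-fracture excess
mortality, no country calibration service.
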