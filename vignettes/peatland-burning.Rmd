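---
title: "Synthesising tropical peatland burning from macro-charcoal records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesising tropical peatland burning from macro-charcoal records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatfire)
library(dplyr)
```

## The problem

Macroscopic charcoal (> 100 µm) preserved in peat profiles records local
burning of vegetation and peat soils. Individual records, however, differ
in extraction technique, quantification method, sampling resolution and
chronological quality, so asking regional questions — has burning of
tropical peatlands increased over the last two millennia, and where? —
requires a standardisation and compositing pipeline. `peatfire`
implements that pipeline as reusable, tested components: chronology
building, influx conversion, a record-wise rescaling transform,
bootstrap composite curves, change-point detection, a 20th-century
change classification, and site-level statistics, together with a
synthetic-data generator that provides ground truth for every stage.

## Site inclusion rules

Three rules gate a record's entry into a synthesis:

* **Tropical band** — absolute latitude at most 30° (closed interval),
  with an explicit allowlist mechanism for scientifically valuable
  sites marginally outside the band.
* **Peat criterion** — at least 30 % organic matter, or failing that at
  least 15 % carbon; when neither measurement is available the
  published description of the site (an `is_peat` flag) decides. The
  rule that fired is recorded per site.
* **Chronology quality** — at least two age controls within the last
  3000 years (ages ≥ −1000 CE), which is what makes interpolation over
  the 0–2000 CE analysis window defensible.

Every excluded site appears in the run manifest with exactly one
reason, so included + excluded always accounts for the input table.

## Age-depth models

Records arrive with already-calibrated calendar ages (depth, age CE,
1σ). `fit_age_model()` builds a Monte-Carlo ensemble of piecewise-linear
chronologies: each draw samples every control age from its normal error
distribution and is accepted only if age strictly decreases with depth;
a draw that fails 1000 resampling attempts is sorted monotone and
flagged. There is no extrapolation beyond the outermost controls. As
control uncertainties shrink to zero the ensemble collapses onto exact
linear interpolation, and the ensemble age spread at a control
converges to that control's stated σ — both properties are asserted in
the test suite.

Downstream influx calculations use the **median chronology** (one dated
series per site); the full ensemble is retained for uncertainty
diagnostics only. Fully Bayesian accumulation models and radiocarbon
calibration are out of scope by design: the synthesis needs dated
samples and accumulation rates, not posterior accumulation histories.

Accumulation rate at a depth is the segment quotient Δdepth/Δage of the
segment containing it, summarised as the median across draws. A sample
midpoint lying exactly on a control depth is assigned to the deeper
segment; this convention is arbitrary and affects only zero-measure
inputs.

## From concentration to PRS

Concentrations (particles cm⁻³) become influxes (particles cm⁻² yr⁻¹)
by multiplying by the local accumulation rate. Influx values are then
rescaled record-wise with proportional relative scaling:

$$\mathrm{PRS}_i = \frac{C_i}{C_{\max}} \times 100 \times \frac{f}{N}$$

where $C_{\max}$ is the record's maximum influx, $f$ its number of
positive values and $N$ its length. The transform maps every record
onto a common 0–100 scale while penalising records where charcoal is
rarely registered: adding a zero sample shrinks all nonzero values by
$(f/(N+1))/(f/N)$. It is invariant to rescaling a record by any
positive constant — which is precisely why records quantified in
different units can be composited. $f$ and $N$ are computed over the
full record before any windowing or binning; a window switch on
`add_prs()` exposes the alternative.

## Composite curves

Compositing is two-stage: records are binned into non-overlapping 25-yr
bins over 0–2000 CE (bin value = arithmetic mean of member samples;
empty bins are `NA`, never 0), then smoothed with a locally weighted
scatterplot smoother — a tricube-weighted local *linear* fit over a
fixed 200-yr metric window (±100 yr). The smoother is written in the
package because the standard R smoothers parameterise their windows as
span fractions rather than metric widths; it reproduces constants and
straight lines exactly and is deterministic. The 25-yr bin width is the
compilation's median sampling resolution; the 200-yr window suppresses
sample-level noise while keeping centennial structure.

The group curve is the per-bin NA-ignoring mean across sites, smoothed.
Uncertainty comes from resampling **sites** with replacement (records
are the exchangeable unit, not samples), recomputing and re-smoothing
per-bin means 1000 times, and taking the 5 % and 95 % percentiles per
target. Because the local-linear smoother is linear in the response,
the smoother matrix for a given pattern of occupied bins can be
precomputed and each bootstrap replicate reduced to a matrix product;
the generic path handles replicates whose missing-bin pattern differs.
Resampling operates on the site list sorted by id, so the composite is
invariant to input row order. Groups smaller than
`min_composite_sites` (default 5) receive no curve — a handful of
records cannot support a regional band, which is why an Oceanian-realm
composite is never produced by the default 58-site preset.

An 800-km great-circle buffer (`select_landscape_sites()`, haversine
distance on a 6371-km sphere) pairs non-peat landscape records with the
peat network when a landscape comparison is wanted.

## Change-point detection

Composite curves are scanned for an at-most-one-change shift in mean
and variance under a Gaussian likelihood. The segment cost is the
profile deviance $n\log\hat\sigma^2_{\mathrm{MLE}}$, the statistic is
the likelihood gain of the best two-segment split over the one-segment
fit, and the default penalty is MBIC-style $4\log n$ (three extra
parameters plus the change location). Both segments must contain at
least two points; ties break to the smallest split index; a variance
floor of 1e-12 keeps the log finite on degenerate (constant) segments,
and floored fits are flagged. The scan is an $O(n)$ cumulative-moment
computation, and the test suite verifies it against brute-force
enumeration of every admissible split.

One dating convention deserves note. The split index τ is the last
point of the first segment, so the change itself lies *between*
targets τ and τ+1. Reporting the year of target τ would date every
detected change half a step early — systematically so on smoothed
step responses, where the pre-change target sits at the foot of the
smoothing ramp. `changepoint_on_composite()` therefore dates the
change at the midpoint of targets τ and τ+1, i.e. at the bin boundary
between the two regimes, while still reporting `tau_index` itself.

## 20th-century change map

Per site, the mean PRS over 1900–2000 CE (closed) is contrasted with
the mean over 0–1900 CE (1900 exclusive — the boundary year belongs to
the recent window only); the difference Δ and the relative change
Δ / (0–2000 CE mean) are reported. Window means use raw dated samples
rather than bins (a config switch could bin first; raw samples use all
information). Δ is classified into eight signal classes — boundaries
closed on the side away from zero: (50, ∞) extremely strong positive,
(15, 50] strong positive, (5, 15] positive, (0, 5] weak positive, {0}
no change, [−5, 0) weak negative, [−15, −5) negative, [−50, −15)
strong negative — plus a mirrored "extremely strong negative" for
values below −50, which the original eight-class table does not cover;
such values are flagged rather than clamped. Sites lacking samples in
either window are excluded with a logged reason.

## Site-level statistics

Site summaries use the median PRS over the last two millennia, cube-root
transformed toward normality. Groupings: elevation (lowland < 500 m,
upland 500–1500 m inclusive, highland > 1500 m), human footprint
(wilderness < 1, intact 1–4 inclusive, highly modified > 4), ecosystem
type, and realm. Group differences are tested with the Kruskal-Wallis
rank-sum test and one-way ANOVA — both delegated to the standard R
implementations and cross-checked in the tests against hand-coded
rank/sums-of-squares oracles to 1e-8. Climate space is ordinated with
correlation-matrix PCA; components are oriented so the
largest-magnitude loading is positive, making signs reproducible across
platforms.

Regression follows a screening protocol: candidates must correlate with
the response at |r| > 0.25 (0.3 is the screen used before ordination;
both are exposed); collinear pairs (|r| > 0.8) lose the member less
correlated with the response; backward elimination then removes the
largest-p term until all terms sit below 0.05. An empty surviving set
yields an intercept-only report, not an error. p-values are reported
as-is, with no multiplicity adjustment. A linear mixed-effects variant
is deliberately absent. Per-period reports use the windows 0–850,
850–1900 and 1900–2000 CE.

## The synthetic-data generator

The generator is the package's ground-truth instrument, emulating the
structure of a ~58-site tropical compilation (16/15/16/8/3 sites across
the Neotropical, Afrotropical, Indomalayan, Australasian and Oceanian
realms):

* **Influx model** — log-normal baseline (log mean log 5, log σ 0.7,
  with ±0.3 between-site variation in log level) × step multipliers ×
  linear per-century trend, Poisson pulse events (2 per kyr, ×10) for
  discrete fire episodes, and Bernoulli zero-inflation (p = 0.2)
  applied last — reproducing the skewed, zero-inflated series PRS was
  designed for.
* **Regional contrast** — Indomalayan and Australasian sites default to
  a ×5 step at 1900 CE, Neotropical and Afrotropical to ×0.5, Oceanian
  to none, so the 20th-century divergence the pipeline should recover
  is known per site.
* **Chronology** — piecewise-constant accumulation rates, log-normal
  around 0.05 cm yr⁻¹ per inter-control segment and rescaled so a
  150-cm core spans 3200–4800 yr (guaranteeing coverage of the last
  3000 years and ~25–35 yr median sample resolution at 1-cm slices);
  age controls evenly spaced in depth including the core top, whose age
  is the collection year (2000 CE) known exactly; other controls carry
  30-yr Gaussian noise; 3–10 controls per core.
* **Determinism** — one global seed; every site, core, age model and
  bootstrap derives its own stream through an integer hash of its
  identifier, so results are identical across machines and invariant to
  processing order.

Concentration is defined as observed influx divided by the local true
accumulation rate, which makes charcoal mass (concentration × slice
thickness) exactly equal influx integrated over the slice's time span —
an identity the tests assert at 1e-9 as a guard against unit errors.

What the generator does *not* emulate: taphonomy and charcoal
transport, hiatuses and minerogenic intrusions, age-model structure
beyond piecewise-linearity, spatial autocorrelation between nearby
sites, and laboratory-method differences beyond what scale invariance
absorbs. Passing end-to-end tests therefore demonstrates that the
pipeline recovers regimes of this generative family — not that the
real compilation satisfies these assumptions.

## Numerical choices and degenerate inputs

* Variance floor 1e-12 in the change-point cost; floored segments
  flagged.
* Smoothing targets with no in-window point give NA; with one point,
  the weighted mean; local-linear fits with degenerate in-window spread
  fall back to the weighted mean.
* All-zero records transform to all-zero PRS with `c_max` recorded
  as 0; empty median windows return NA with a warning.
* Sample midpoints outside the modelled depth range are dropped with a
  logged count; a series with no overlap is refused.
* Class boundaries, elevation/footprint boundaries and the tropics
  band are closed as documented above; each is a one-line change if an
  alternate convention is wanted.

## Problem sizes used in the tests

The test suite exercises the PRS identities on 1000 random records, the
change-point scan against exhaustive search on 500 series (n ≤ 200),
detection power on 500 simulations of an 80-point series with a 2σ
shift, ensemble calibration at 2000 draws, bootstrap band coverage on
200 twenty-site groups at B = 1000, and full-pipeline regime recovery
on 100 replicates of the 58-site preset. These sizes give Monte-Carlo
standard errors comfortably below the asserted margins. One known
limitation surfaces there: with only 8 Australasian sites the single
change-point locks onto pre-1900 composite wander in roughly a tenth
of replicates, so per-region localisation to 1850–1950 CE sits at
~87 % for that group (the 16-site Indomalayan group is essentially
always localised). Small groups need either more records or a
multiple-change method before their change-point years should be
trusted to half a century.
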