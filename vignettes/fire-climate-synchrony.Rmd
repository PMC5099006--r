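---
title: "Fire-scar chronologies and fire-climate synchrony: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire-scar chronologies and fire-climate synchrony: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firesync)
```

# The problem

Multi-century fire histories in temperate rainforests are reconstructed
from two lines of tree-ring evidence: dated fire scars on surviving trees,
and pulses of tree establishment (post-fire cohorts) that follow
canopy-opening fires. `firesync` implements the full analysis chain for
such a record: building a composite fire chronology from crossdated
fire-scar series, constructing extreme-event years from reconstructed
climate indices (PDSI, ENSO, PDO, AO), testing fire-climate synchrony
with a one-dimensional bivariate Ripley's K under Monte Carlo envelopes,
testing fire frequency across climate phases with G-tests, and modelling
the spatial pattern of burning with AICc-ranked Poisson GLMs. A synthetic
generator with known ground truth stands in for field data, so every
stage is testable end to end.

# Composite chronology

A calendar year is a **fire event** when at least two distinct trees
carry a dated fire scar in that year (`detect_fire_events()`,
`min_trees = 2`). The two-tree rule guards against misdated or
non-fire injuries; it is the standard convention in fire-scar
compositing. Years scarred on a single tree are promoted to events by
`verify_single_scar_events()` only when a post-fire cohort — at least
`min_cohort = 5` trees establishing in the window
`(fire_year, fire_year + 10]` — corroborates them. Two choices here were
genuinely open:

* **Cohort size.** No universal threshold exists for how many recruits
  constitute a cohort; we use five, matching the usual sample-depth
  convention for when a chronology segment becomes reliable, and expose
  it as `min_cohort`.
* **Window orientation.** Cohorts are *post*-fire, so the window is open
  at the fire year and closed ten years after; establishment in the
  window of an already-detected event corroborates that event and is not
  available to promote a nearby single-scar year.

Interval statistics follow the standard definitions: the **mean fire
interval** (MFI) is the arithmetic mean of successive composite event
years, identical to span/(n − 1); the **point fire interval** (PFI) pools
within-tree scar intervals across trees with at least two scars. No
Weibull median interval is fitted — only mean intervals are reported.
Severity is classified per event from evidence presence alone: `"mixed"`
when at least one burned plot shows a post-event cohort, `"low"` when the
event is recorded by scars only.

# FHX input and output

`read_fhx()`/`write_fhx()` handle the Fire History Exchange plain-text
matrix (both `FHX2 FORMAT` and `FIRE2 FORMAT` headers are accepted;
`FHX2` is emitted). One parsing rule deserves note: a scar is by
definition recorded by a recording tree, so a scar code appearing in a
non-recording context is promoted to recording status (with a warning)
rather than rejected. The writer emits a canonical document on which
read-after-write is exact; because the first and last cells of a series
carry the pith/bark markers, generated fixtures keep scars strictly
inside the series span.

# Extreme climate events

Climate "events" are the `k = 50` most positive or most negative annual
values of an index within the analysis period (`select_extreme_years()`).
For two- and three-way phase interactions the indices are first ranked in
the direction of each phase and combined (`combine_phase_events()`,
`k = 100`). The combination rule was an open design point — "the 100
highest or lowest ranked values" of two or three series can be read as a
union, an intersection, or a joint ranking. We adopt the **minimum
rank-sum** rule as the default because it always returns exactly `k`
years and degenerates to the single-index top-`k` when the series
coincide; union and intersection are available via `rule=`. All ranking
is tie-broken toward earlier years, making every event set deterministic,
and all event sets are invariant under monotone transformations of the
index values. Three-way interactions are analysed over 1700 onward by
default (`threeway_start`), the period holding most events in records of
this kind; two-way sets use each pair's own common period, clipped at the
last fire year (`analysis_end = 1893`).

# Bivariate event analysis

The synchrony statistic is a one-directional, one-dimensional bivariate
Ripley's K. With fires \(f\) and climate events \(c\) on a domain of
\(T\) years,

\[
\hat K(t) \;=\; \frac{T}{n_1 n_2} \sum_f \sum_c w(f,t)^{-1}\,
\mathbf 1[\,0 \le f - c \le t\,],
\]

counting climate events in the *backward* window of \(t\) years ending at
each fire — fires may respond to previous and current climate, never
future climate, so a climate event in the fire year itself counts at lag
0 and the window at lag \(t\) holds \(t + 1\) years. \(w(f,t)\) is the
fraction of the window inside the domain (Ripley-style edge correction:
fires near the start of the record are up-weighted, not discarded;
`edge_correction = "none"` disables this for cross-checks). Under
independence \(E[\hat K(t)] = t + 1\) exactly, which the results report
as the analytic null expectation.

`bea_envelopes()` builds pointwise Monte Carlo confidence envelopes
(default 95% and 99%, 1000 replicates) by redrawing the climate-event
years uniformly without replacement from the domain. That null destroys
all temporal structure of the climate events while fixing their number;
because "randomizing a climate series" can also be read as preserving its
internal spacing, a circular-shift null is available via
`null_model = "circular_shift"`. A lag is classified *synchronous* when
the observed K is above the upper envelope, *asynchronous* below the
lower, *independent* inside; `classify_synchrony()` reports contiguous
runs as windows of years prior to fire. Envelopes are pointwise, not
simultaneous; the per-tail probability of each band (e.g. 0.025 at the
95% level) is carried in `alpha_report` so output states the level
explicitly rather than a nominal "p".

Two numerical points:

* **Tie-breaking.** The observed and simulated K live on a shared
  discrete lattice (annual data, rational weights), so the observed
  value frequently *equals* the envelope bound, especially at short
  lags. Counting ties as "inside" makes the pointwise test conservative
  (we measured ~2.3% exceedance where 5% is nominal). Ties are
  therefore broken at random — an infinitesimal jitter, about `1e-9` of
  one pair's contribution, is added to the observed and simulated
  statistics before ranking — the standard device for exact Monte Carlo
  tests of discrete statistics. With it, the pointwise exceedance rate
  under independence is ~4.7%.
* **Default lag range.** `t_max = 40` years covers the multidecadal
  windows such analyses report (synchrony windows extending into the
  30-some years prior to fire) while staying well below the domain
  length.

`randomization_sanity()` re-runs the analysis with uniformly drawn
random "fire" years against each climate set; non-independent lags
should then appear only at the envelopes' nominal rate, confirming that
detected synchrony is not an artefact of the climate events' internal
autocorrelation.

# Frequency analysis

`build_contingency()` tabulates fires by climate-phase category with
expected counts proportional to the number of years in each category
(equal likelihood of burning in all years), and `g_test()` computes the
log-likelihood-ratio statistic \(G = 2\sum_i O_i \ln(O_i/E_i)\) (with
\(0\ln 0 = 0\)) against the chi-square distribution. Williams'
correction is off by default — it is not part of the emulated protocol —
but available. With few fires the expected counts are small; results
carry an `approx_suspect` flag whenever any expected count is below 5,
and an exact Monte Carlo multinomial p-value is available via
`simulate_p = TRUE`. Phase categories are binary by default (in the
extreme set vs not); the contingency builder accepts arbitrary
multi-level assignments.

# Spatial models

Per-plot scar abundance and fire-event frequency are modelled as Poisson
GLMs (log link, fitted by iteratively reweighted least squares via
`stats::glm`). Six conceptual predictors enter all-subsets selection (64
models): distance to the nearest former habitation site, distance to
shoreline, elevation, slope, aspect, and vegetation type as a single
dummy block with blanket bog as the reference level. Aspect is circular,
so it enters as **northness** (`cos` of the azimuth) by default, with raw
degrees available for strict emulation of protocols that used them.
Models are ranked by
\(\mathrm{AICc} = -2\ell + 2K + 2K(K+1)/(n-K-1)\); Akaike weights,
evidence ratios and the deviance-based pseudo-R²
(\(1 - D_{res}/D_{null}\); the definition is stated because several
pseudo-R²s circulate) are reported per model. `model_average()` averages
coefficients over the smallest top set whose cumulative weight reaches
95%, with absent predictors contributing zero (shrinkage averaging), and
reports per-predictor relative importance as summed weights. No
overdispersion correction is applied by default: the emulated protocol
specifies plain Poisson.

# The synthetic generator

`synthetic_config()` describes the study system the package emulates: 30
plots in a ~2 km landscape with three habitation sites, four vegetation
types, elevations 0-150 m; four AR(1) climate indices over 1300-2000
(PDSI rescaled to the conventional −6..+6 dynamic range, ENSO-PDO
innovations cross-correlated); an annual Bernoulli ignition process per
plot with
\(\mathrm{logit}\,p = \beta_0 + \beta_{dist}\,d + \gamma\,(-\mathrm{PDSI}_{t-1})\),
i.e. burning concentrated near habitation sites and after dry years, and
a human-ignition switch-off after 1893 that ends the fire record; and a
sampling model in which each of three trees per plot records each plot
fire with probability 0.6 as a season-undetermined (`U`) scar — season is
typically indeterminable in rot-prone coastal material — plus post-fire
establishment pulses and background establishment.

The defaults were calibrated once so that a default run yields totals on
the order of the emulated record — ~20 composite events, ~85 scars on
~49 scarred trees over roughly 1370-1890 — and were then frozen; tests
assert these totals only within a factor of two, reflecting the
generator's stochastic spread. The generator is deliberately simpler
than reality in ways that matter for interpretation: fires are
plot-level Bernoulli draws with no spatial spread between plots, climate
forcing is a single lag-1 drought term, recording probability is
constant over tree age and fire intensity, and there is no tree death or
wood decay. Passing recovery tests therefore shows the *analysis chain*
is correct under the model's assumptions, not that real records have
this structure.

# Problem sizes and test design

The test-suite simulations use sizes chosen to balance statistical
resolution against a default run of a few minutes: oracle equivalence of
the K implementation on 1000 random instances (both series up to 20
events, domains up to 200 years); envelope calibration over 500
independent datasets (16 fires, 50 climate years, 600-year domain, 1000
replicates each, lags to 10); planted lag-3 forcing recovered across 100
seeds; G-test size over 1000 simulated null datasets of 60 fires (60 was
chosen because the *exact* size of the G-test at balanced expecteds is
within half a percent of nominal there, whereas smaller fire counts make
the exact size visibly sub-nominal through count granularity — at 40
fires it is 3.85%); and Poisson-GLM slope coverage over 500 replicates
of 30 plots with true decay −0.002 per metre.

# Known limitations

* The K envelopes are pointwise; simultaneous (rank-envelope) inference
  is not implemented.
* The uniform null fixes only the number of climate events; the
  circular-shift null preserves their spacing but not their
  relationship to any covariate.
* MFI/PFI assume the composite record is complete within its period;
  no detection-probability correction is applied.
* The FHX writer emits one canonical dialect; exotic FHX variants (year
  annotations elsewhere, embedded comments) are not preserved
  byte-for-byte, though their content parses.
* `g_test()`'s chi-square reference is unreliable for expected counts
  below ~5 — exactly the regime of a 16-event record split across
  phases — hence the `approx_suspect` flag and the Monte Carlo option.
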