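---
title: "Modelling organ travel distance and transport emissions under acuity-circle allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling organ travel distance and transport emissions under acuity-circle allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organmiles)
```

## The problem

Between 2017 and 2021 US solid-organ allocation replaced donor-service-area
boundaries with acuity circles (AC) — 250–500 nautical-mile priority rings
around the donor hospital — organ by organ: lung on 2017-11-24, heart on
2018-10-18, liver on 2020-02-04, kidney on 2021-03-15. Organs now routinely
travel farther, and farther often means flying instead of driving. This
package estimates, per organ, (i) the *excess* miles travelled after each
policy change relative to the pre-policy trend, and (ii) the carbon
emissions attributable to that excess under a range of travel-mode
assumptions, because the registry does not record how an organ actually
travelled.

The intended users are transplant health-services researchers with access
to registry extracts (the national registry data are restricted), and
anyone auditing or extending the methodology on synthetic data.

## Observation windows

Each organ gets a window equidistant around its implementation date: the
post period is the number of whole months elapsed from implementation to
the study end (2023-11-30), and the pre period has the same number of
months. Monthly bins are anchored at the implementation day-of-month, the
first post bin starts on the implementation date itself (a transplant on
that date is "post", `elapsed_post = 0`), and the final bin absorbs the few
trailing days up to the study end. This convention is what makes the four
windows start in November 2011 (lung), September 2013 (heart), May 2016
(liver) and July 2018 (kidney); purely calendar-month conventions shift
every start by a month and break the equal-length symmetry.

```{r windows}
cal <- default_policy_calendar()
sapply(names(cal$implementation),
       function(o) format(build_window(o, cal)$window_start, "%Y-%m"))
```

Cohort filters mirror registry practice: living-donor organs and records
missing a transplant center ID are excluded (in that order, each record
tallied under its first matching reason), then window membership is
applied. Unresolvable endpoints at the distance stage are dropped and
counted, not fatal — one bad address should not abort a national analysis.

## Distances

Trip distance is the great-circle (haversine) distance in statute miles
between the donor-hospital ZIP centroid and the recipient-center ZIP
centroid, on a sphere of radius 3958.8 miles (configurable; the choice of
radius moves distances by well under 0.3%). When the recipient ZIP is
missing, the centroid of the center's city-state address is used and the
trip is flagged. The gazetteer is an input CSV — no proprietary ZIP
database ships with the package; real runs can supply Census ZCTA
centroids.

## The interrupted time series

For each organ, let \(y_m\) be the mean trip distance over the trips in
monthly bin \(m = 1,\dots,2n\) (with \(n\) pre months). The segmented
regression is

\[
y_m = \alpha + \beta_1 m + \beta_2 \, \mathrm{post}_m
      + \beta_3 \, \mathrm{post}_m \, e_m + \varepsilon_m ,
\]

where \(\mathrm{post}_m = 1\{m > n\}\) and \(e_m = m - n - 1\) is months
elapsed since implementation (0 in the implementation month). So
\(\beta_1\) is the pre-period trend (miles/month), \(\beta_2\) the
immediate level change at the start of the post segment (miles), and
\(\beta_3\) the slope change; the post-segment slope is
\(\beta_1 + \beta_3\). The fit is unweighted ordinary least squares on the
monthly means (the analysis object is the monthly series, not the trips); a
count-weighted fit and heteroskedasticity-robust (HC1) p-values are
available behind flags. No autocorrelation structure or seasonal terms are
modelled, and no changepoint is estimated — the interruption date is known
policy.

Published summaries of this design sometimes report a single post-period
"trend" coefficient. `fit_its()` therefore reports \(\beta_3\) and
\(\beta_1 + \beta_3\) separately so either reading is inspectable. The
organ presets in `organ_presets()` interpret the reported post trends for
lung (3.40), heart (1.56) and kidney (2.71) as post-segment slopes
\(\beta_1+\beta_3\) (the surrounding language describes the month-to-month
trend in the post period), but liver's 0.34 as the slope-change
coefficient \(\beta_3\) (it is described explicitly as a change in slope),
giving a liver post-segment slope of 0.10. Only the level changes and the
three post-segment slopes above are treated as recovery targets; the liver
reading affects nothing downstream except the liver preset's slope.

**Counterfactual excess.** For each post month the counterfactual mean is
the pre-trend extrapolation \(\hat\alpha + \hat\beta_1 m\) (no
\(\beta_2,\beta_3\) terms). The excess is
\(\sum_{m>n} n_m (y_m - \hat\alpha - \hat\beta_1 m)\), the
observed-minus-predicted delta scaled by that month's procurement count
\(n_m\). Months with no procurements contribute zero (they are dropped
from the fit but retained in the result). Whether the pre segment is
summarised by fitted or raw means affects only diagnostics; the excess is
defined on post months only.

## Travel-mode scenarios and emissions

Mode of travel is not recorded, so a scenario grid brackets it: an organ
flies if and only if its trip distance strictly exceeds a threshold
(25, 50, 100, 150 or 200 miles; ties drive). Hearts, lungs and livers fly
by dedicated charter; kidneys fly on scheduled commercial flights, which
carry zero added emissions because the flight operates anyway — so for
kidneys, assumptions that prioritise flying are the *conservative* ones.

Emission factors are inputs (kg CO2e per mile by mode), shipped as a
versioned YAML config: 0.44 for a large petrol car, 2.06 for a short-haul
dedicated charter on a whole-flight basis (the flight exists only for the
organ; two people travelling per procurement, roughly 200 kg of added
weight), 0 for commercial. The charter value is an estimate on a
whole-aircraft basis, not an audited conversion factor — absolute emission
totals from this package should always be read as conditional on the factor
file supplied, and published absolute totals are not treated as
reproducible without the original factors.

**Counterfactual pricing.** Excess *emissions* for a scenario are
`total_post − counterfactual_post`, where the counterfactual rescales each
post trip's distance by its month's predicted/observed mean ratio (the
trip-level image of the excess-mile definition). Two pricings are offered:

* `observed_mode` (default): the rescaled trip keeps the mode assigned at
  its observed distance, so each trip's excess miles are priced at that
  trip's scenario mode. Under any cohort whose monthly deltas are
  non-negative this makes excess emissions monotone non-increasing in the
  threshold for charter organs and non-decreasing for kidneys — the
  directions the published scenario table exhibits — and at the lowest
  threshold the charter-organ excess reduces to (excess miles) × (charter
  factor).
* `reassign`: modes are re-assigned at the rescaled distance, so mode
  switches themselves enter the excess. This is a sensitivity variant; it
  generally *raises* excess near thresholds below the mean trip distance
  (a trip whose counterfactual falls back to driving keeps its observed
  charter emissions in full), and does not reproduce the published
  monotone directions.

`compose_bounds()` combines per-organ scenario totals into the
most-liberal (charter organs at the lowest threshold, kidney at the
highest) and most-conservative (the reverse) assumption sets. When each
organ's excess is monotone in the threshold these two compositions bracket
all \(5^4\) mixed compositions; the test suite verifies the bracketing
exhaustively on a positive-effect cohort.

## The synthetic cohort generator

The real registry is restricted, so `generate_cohort()` emulates an
extract. For a spec with generating parameters
(baseline, \(\beta_1\), \(\beta_2\), post slope):

* every monthly bin receives `monthly_volume` records (optionally with a
  linear volume ramp), dated uniformly within the bin;
* each trip distance is drawn from a gamma distribution whose mean is the
  segmented-model target for its month and whose coefficient of variation
  is `trip_noise` (gamma is a documented stand-in: it is right-skewed and
  strictly positive, and nothing downstream depends on the family beyond
  its mean — no trip-level distribution is reported for the real data);
* the recipient centroid is drawn uniformly from a continental-US-like
  bounding box and the donor centroid is placed by the direct geodesy
  problem (`destination_point()`) at a random bearing, so the haversine
  distance between the two registered pseudo-ZIP centroids equals the
  drawn distance to rounding error — no real gazetteer is needed;
* living-donor, missing-center-ID, missing-ZIP (with a resolvable
  city-state fallback) and fully-unresolvable fractions are honoured with
  deterministic per-month counts, so the filters and error paths run on
  every realistic cohort;
* generation is fully reproducible from the spec seed.

`preset_cohort_spec()` encodes the study conditions per organ: the
reported pre-period mean (the baseline is back-computed so the *average*
pre-period target equals it), pre slope, level change and post slope over
that organ's policy window, approximate analyzed monthly volumes
(heart 290, lung 198, liver 712, kidney 1543 — the reported analyzed
totals divided by the window lengths), default trip noise CV 0.8 (trip
distances in registry data are strongly right-skewed around monthly
means), ~14% living donors and 0.2% missing center IDs (the reported
exclusion counts relative to the analyzed totals), and a missing-ZIP rate
of 5 per 100,000 (ten fallback cases were reported nationally).

What the generator does *not* emulate: geographic clustering of centers,
organ-specific living-donation patterns, seasonality, the COVID-19 shock,
volume trends within organs, or any dependence of distance on donor/
recipient characteristics. Passing tests on synthetic data therefore
demonstrate that the *estimators and accounting are correct under the
stated model*, not that the model captures every feature of registry data.

## Numerical choices and degenerate inputs

* OLS is solved by `stats::lm`; the test suite pins it against a direct
  normal-equations solve at 1e-8 relative tolerance.
* The fit requires at least two observed months per segment; empty months
  are excluded from the fit and carry zero excess.
* The haversine argument is clamped to [0, 1] before `asin` so antipodal
  rounding cannot produce NaN; distance ties at a mode threshold drive
  (strict inequality).
* Specs whose generating trend line touches zero inside the window are
  rejected at construction.
* A post month with zero observed mean makes the counterfactual rescale
  undefined and errors; with strictly positive distances it can only arise
  from an empty month, which is skipped.
* Monte-Carlo checks (unbiasedness of monthly means and of the
  level-change estimator) run at 200 replicates, volume 50/month, CV 0.5,
  a 12+12-month window — large enough for 3-standard-error bias bounds to
  be meaningful while keeping the default test run fast.

## Known limitations

Straight-line distances understate road miles and say nothing about
routing or ischemia time; team travel to the donor hospital, recovery-
facility legs, courier legs and dry runs are all uncounted, so excess
estimates are lower bounds on logistical burden. Emission factors are
user-supplied estimates, commercial flights are assumed strictly
zero-marginal, and the mode thresholds are assumptions, not observations —
which is exactly why results are reported as a scenario grid with liberal/
conservative bounds rather than a single number.
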