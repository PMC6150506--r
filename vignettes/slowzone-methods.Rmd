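---
title: "Monitoring voluntary vessel slow-down measures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring voluntary vessel slow-down measures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowzone)
```

## The problem

Lethal collisions with large merchant vessels limit the recovery of several
baleen whale populations. A common mitigation design in estuarine waterways
combines a **speed reduction area** (SRA, a voluntary 10-knot
speed-through-water limit), a **no-go area** (NGA, voluntary avoidance, else
≤ 10 kn), and a **recommended route** (RR, keeping traffic on one side of a
sensitive passage). Because the measures are voluntary, their value hinges on
two questions this package operationalises:

1. **Compliance** — did mariners actually change behaviour, and along which
   dimensions (strict observance, partial slow-down, route choice)?
2. **Effectiveness** — by how much did the risk of a *lethal* strike fall,
   given where whales actually are?

Both are answered from Automatic Identification System (AIS) ship tracks,
a gridded surface-current model, and static relative-density surfaces for
the whale species of concern.

## Speed through water

Estuarine tidal currents are strong enough that a constant speed over ground
(SOG) does not mean a constant hydrodynamic speed. The limit is therefore
defined through water (STW). The conversion reconstructs the ground-velocity
vector from SOG and course over ground (COG) and subtracts the interpolated
current:

$$\mathrm{STW} = \left\lVert
  \begin{pmatrix} \mathrm{SOG}\,\sin(\mathrm{COG}) \\
                  \mathrm{SOG}\,\cos(\mathrm{COG}) \end{pmatrix}
  - \begin{pmatrix} u \\ v \end{pmatrix} \right\rVert .$$

Using COG for the velocity direction (true heading is not in the AIS feed we
model) attributes leeway/crab angle to the water speed; this is the
convention of the operational conversion modules this mirrors. The current
field is bilinear in space between cell centres and linear in time between
hourly snapshots. The operational uncertainty of such conversions is about
0.7 kn, dominated by the current model; the generator exposes a per-component
current-noise parameter so tests can reproduce an error budget of that order.

## Distance-weighted average speed

AIS reporting rates vary with speed, and a slow vessel spends more time (and
so emits more fixes) per nautical mile than a fast one. A naive per-fix mean
speed is therefore biased low whenever speeds vary. All average-speed
indicators instead use the **distance-weighted average speed**

$$\mathrm{DWAS} = \frac{\sum_i d_i v_i}{\sum_i d_i},$$

over track segments clipped to the zone of interest, with $d_i$ the in-zone
geodesic length of segment $i$ and $v_i$ its speed (mean of the endpoint
STWs, so the per-fix current correction propagates). The tests verify that
DWAS is invariant to the fix rate (10 s vs 120 s resampling moves it by
< 0.05 kn) while the naive mean shifts by the predicted time-weighting bias,
and that DWAS matches the continuous distance/time oracle within 2%.

## The indicator portfolio

A single compliance number hides the behaviours managers need to see, so a
portfolio of seven indicators is computed per zone × year × measure status:

| Indicator | Meaning | Key choices |
|---|---|---|
| I1 | % of transits with *every* in-SRA fix ≤ 10 kn STW | boundary inclusive (10.0 complies); one faster fix condemns the transit |
| I2 | % of transits using the NGA, partial / complete | complete = crosses both NGA chords with ≥ 99.9% of the between-chord path inside |
| I3 | % of transits north of the island | classified by which reference gate the ground track crosses; both/neither → excluded |
| I4 | slow-down effort: approach speed − in-zone speed | 3-km approach measured *along the track* backwards from first entry; distance-weighted means on both sides |
| I5 | per-transit DWAS in the zone | see above |
| I6 | % of in-zone distance above the limit | segment speed strictly > 10 kn |
| I7 | DWAS of the non-compliant distance only | absent when I6 = 0 |

STW is the speed basis for all SRA indicators and for the NGA speed check;
route-choice geometry (I2 membership, I3) uses positions only, since route
choice is a ground-track property. Transits with any positive in-zone length
enter the I1 denominator. Empty periods report absent indicators rather
than zeros.

## Speed models

Three questions are asked of per-transit DWAS with Gaussian linear mixed
models (REML, `lme4`), each with a year random intercept and Wald
normal-approximation confidence intervals and p-values:

1. `dwas ~ active + (1 | year)` — the overall shift under active measures,
   with the inactive-period mean as intercept;
2. `dwas ~ active_year + (1 | year)` — one dummy per active year, pooling
   inactive transits in the intercept, to track year-over-year improvement;
3. `dwas ~ ship_class + pilot + direction + flag + (1 | year)` on
   active-period transits — reference levels tanker, no pilot, upstream,
   Canadian flag.

The model family is fixed: the response is continuous speed, so the
identity-link Gaussian model is the only one supported. REML (rather than
ML) and the normal approximation for Wald intervals are declared choices;
the tests confirm that the mixed fit collapses to ordinary least squares
when the year variance is zero, and that 95% intervals cover planted effects
at 93–97% across 100 replicates. When covariates are confounded (for
example, every internationally flagged ship carries a pilot) the design is
rank-checked and the *flag* term is the one dropped, keeping the pilotage
effect interpretable.

Year-over-year distributional change is tested with the two-sample
Kolmogorov–Smirnov statistic. The one-sided "year A greater than year B"
orientation asks whether A's speeds are stochastically larger, i.e. the
statistic is $\sup_x(\hat F_B - \hat F_A)$; tests pin this against a
hand-built empirical-CDF oracle because R's `alternative` argument is
phrased in terms of CDF ordering, which is easy to invert silently.

## Lethality and risk

The probability that a strike is lethal rises with speed along a logistic.
Rather than importing regression coefficients, the curve is calibrated from
its two published operating points — 31% lethality at the 10-kn limit and
50% at 11.8 kn — which determine the two parameters exactly:

$$\beta_1 = \frac{\mathrm{logit}(0.50) - \mathrm{logit}(0.31)}{11.8 - 10}
          = 0.4445, \qquad
  \beta_0 = \mathrm{logit}(0.31) - 10\,\beta_1 = -5.245.$$

Risk is mapped on a planar grid (1-km cells by default): each track segment
is split across the cells it crosses, each cell accumulates distance and
distance × P(lethal | speed), and cell risk is the product of that weighted
distance with the species' relative density. Effectiveness between two
periods is

$$100 \left(1 - \frac{\sum_{\text{region}} \text{risk}_{\text{after}}}
                     {\sum_{\text{region}} \text{risk}_{\text{before}}}\right),$$

which is invariant to any global rescaling of the density surface — only
*relative* risk is claimed, matching the available 25-year density portrait.
The step-by-step spatial procedure behind the published analysis is not
publicly archived, so this reconstruction fixes four choices explicitly,
all config-exposed: 1-km cells; risk proportional to distance steamed (not
time); per-transit normalisation of the traffic term when comparing periods
of unequal volume; densities normalised to sum to one. For a single-speed
fleet on a uniform density the pipeline collapses to the closed form
$100\,(1 - P(v_\text{after})/P(v_\text{before}))$, which the tests verify
end to end through the gridding.

The industry-side cost is summarised as gate-to-gate transit time, with the
crossing instant of each reference transect interpolated linearly between
the straddling fixes.

## The synthetic study system

No AIS archive, current model or density surface is shipped; a generator
reproduces the statistical structure the pipeline must survive:

* **Geometry** — rectangular zones on a ~90 × 55 km east–west reach laid
  out like the real system (SRA ~5.4 nm wide inland, NGA on the north shore
  downstream, an island with north/south gates, transit-time gates at both
  ends).
* **Speed regimes** — cruising STW drawn per period from N(14.1, 2.6²) kn
  (inactive) and slow-down targets from N(11.3, 1.7²) kn (active), the
  published per-period summaries. About 10% of active-period transits draw
  a strictly compliant target (≤ 10 kn); ships never *accelerate* to meet a
  target. Route choice is north with probability 0.93, and 10% of
  north-route transits cut through the NGA; 90% of transits carry a pilot.
  These defaults are the study conditions, not tuning knobs.
* **Kinematics** — waypoint-following with first-order speed ramps
  (3 km before the zone, symmetric after); no behavioural agent model.
  The heading crabs into the current so the ground track stays on the
  route, making STW *exactly* recoverable from emitted SOG/COG plus the
  same current field — the round-trip identity the conversion tests rely
  on.
* **Currents** — a semidiurnal (12.42 h) along-channel sinusoid with a weak
  cross-channel amplitude gradient, materialisable on any grid/window.
* **Emission** — fixes are emitted at
  `clamp(60 s · (6 kn / speed)^0.5, 2 s, 180 s)` with optional dropout.
  The sublinear exponent makes the reporting rate grow more slowly with
  speed than the steaming rate, so slow ships contribute more fixes per
  nautical mile — the over-representation bias that motivates distance
  weighting. (A strictly proportional rate, exponent 1, would cancel the
  bias exactly; it remains available for sensitivity runs.)
* **Truth log** — every planted quantity (route, cruise and target speed,
  true DWAS, strict-compliance flag, pilot status) is recorded per transit
  so each pipeline estimate has a ground-truth counterpart.

What the generator does **not** emulate: antenna coverage geometry beyond
Bernoulli dropout, vessel interactions or traffic-lane congestion, seasonal
or interannual whale-density dynamics, and real shoreline/bathymetry. A
green test suite therefore shows the *computations* are right under the
study's statistical structure, not that the package has been validated
against the confidential archives.

## Numerical choices and degenerate inputs

* Geodesy is spherical (R = 6371.0088 km, haversine via `geosphere`);
  ellipsoidal corrections are ~0.1% and irrelevant at reach scale. Planar
  work uses a Lambert azimuthal equal-area projection centred on the study
  area; the projection error against geodesic distances is < 10⁻⁴
  relative at this scale (tested).
* Polygon clipping uses exact segment/edge intersection with an even-odd
  interior rule and a boundary tolerance that counts edge points as inside;
  convex polygons take a vectorised Cyrus–Beck path whose agreement with
  the exact clip is itself a test.
* Cleaning thresholds (35 kn absolute, 50 kn implied point-to-point,
  30-min gap, ≥ 5 in-area fixes, must span the channel midpoint) are
  deliberately generous for merchant traffic and are function arguments,
  not constants. Cleaning is idempotent.
* A transit with zero in-zone length is excluded from zone indicators with
  a log entry rather than contributing 0/0; empty periods produce rows with
  absent values; transits crossing both or neither island gate are logged
  unclassifiable.
* `0/0` percent reductions are refused: effectiveness over a zero-baseline
  region is an error by design.

## Problem sizes

The shipped tests and the acceptance script are sized to run comfortably on
one CPU: recovery experiments use 5 × 400 and 2000 transits (the published
designs), the coverage study 100 replicates of 5 × 60, the Monte-Carlo
surrogate 10⁴ draws per period, and the end-to-end scenarios a few dozen
simulated transits on 2–4-km analysis grids. Each piece scales linearly if
larger runs are wanted.

## Known limitations

* Zone geometry is synthetic-rectangular; the real boundary coordinates are
  published on nautical notices, not here, and the 2016 boundary adjustment
  near the pilot station is modelled only as "zones may differ by year".
* "Complete" NGA use is a declared operationalisation (chord-to-chord
  containment), since no formal definition is published.
* The risk maps are relative co-occurrence risk; no absolute strike counts
  are predicted, and densities are static.
* Company-level attribution of non-compliance is out of scope (requires
  confidential registry joins).
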