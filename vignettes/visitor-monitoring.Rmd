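---
title: "Estimating park visitation from social-media user-days"
author: "parkdays maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating park visitation from social-media user-days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Park agencies need visitation numbers for management, marketing and
conservation advocacy, but counters, surveys and ticket registers are
expensive and unevenly available. Geotagged social-media posts are a cheap,
continuously generated alternative signal: if people photograph their park
visits, the volume of geolocated content should track how many people were
there. `parkdays` implements the workflow for turning raw geotagged posts
into monthly visitation estimates and for judging — against official visitor
statistics where they exist — how much the signal can be trusted, per park
and per platform.

## The user-day statistic

The core statistic is the **social-media user-day (SUD)**: the number of
distinct (user, park, calendar day, platform) tuples,

$$\mathrm{SUD}_{p,m} \;=\; \#\{(u, d) : \text{user } u \text{ posted from
park } p \text{ on day } d \in m\},$$

summed over the days $d$ of month $m$. A user posting five photos in an
afternoon counts once; a user posting once on each of three consecutive days
counts three times. The second property is deliberate: it mirrors how trail
counters tally a multi-day visitor once per day, so SUD and counter-based
official statistics estimate the same thing up to a participation rate. The
first property is the defence against *participation inequality* — the
heavy-tailed distribution of posting activity in which a small fraction of
users produces most content. Raw post counts are dominated by that tail; the
per-day deduplication removes it entirely. The generator makes this
demonstrable: making the activity tail heavier inflates post counts but
leaves user-days bit-identical (`test-simulate.R`).

No attempt is made to estimate *unique visitors* across days: a
seven-day visit is seven user-days, by design.

## Spatial assignment

Posts are attributed to parks by polygon containment plus a metric buffer
(default **10 000 m**), which captures posts taken from water next to
archipelago parks, from viewpoints outside the boundary, and jittered
geotags. Rules, in order:

1. exclusion zones (optionally platform-specific, e.g. a city-centre zone
   that contaminates only one platform's place-tagged data) remove posts
   before anything else;
2. interior containment beats any buffer, with lexicographic `park_id`
   breaking the (rare) overlapping-parks tie;
3. otherwise the nearest boundary within the buffer wins; exact distance
   ties again break lexicographically;
4. everything else is retained as `unassigned` — counts over the four modes
   always partition the input.

Distances and buffers are computed in an azimuthal-equidistant projection
centred on each park's centroid (spherical Earth, $R = 6\,371\,008.8$ m), so
"10 km" is ground metres at any latitude; degree-based buffers would be
badly distorted at the high latitudes where many parks sit. The planar
approximation against ellipsoidal geodesics is well under 1% at park-plus-
buffer scales; the test suite checks assignment decisions against an
independent geodesic oracle, skipping only points within 1% of the decision
threshold where the two Earth models legitimately disagree. Buffered
polygons are produced by round-join polygon offsetting in the same
projection (`polyclip`), with arc tolerance `buffer_m / 200`.

The calendar day of a post is taken in a configurable **reporting
timezone** (default UTC, settable per country). The day boundary genuinely
matters — a 23:30 UTC post is the next day in UTC+2 — and source data
rarely state which timezone a "day" means, so the package makes the choice
explicit and deterministic. Timestamps without an offset are interpreted as
UTC and counted.

## Evaluation statistics

For a single year of monthly data (12 observations per park), the package
computes exactly the statistics that small-n series support — deliberately
no GLM/GLS/ARIMA or Granger-style modelling, which 12 points cannot carry.

**Popularity ranking.** Parks are ranked by annual total (rank 1 = most
visited) on the official side and the social-media side; agreement is
Spearman's $r_s$ with average-rank ties. Because $r_s$ only sees ranks, it
is invariant to any monotone rescaling of either total — platform adoption
rates cancel out.

**Monthly patterns.** Each park's 12 monthly counts are standardised to
proportions ($\sum_m \pi_m = 1$, each $\pi_m \in [0,1]$) and compared by
Pearson correlation. Pearson $r$ is invariant to the positive rescaling, so
standardisation changes nothing about $r$ itself; it exists to make curves
of very differently sized parks visually and numerically comparable.
All-zero series have no pattern: they propagate as missing (`NA`), never as
a zero correlation.

**Autocorrelation screening.** A 12-point series with strong short-lag
autocorrelation yields Pearson correlations whose effective sample size is
well below 12, so per-park ACF and PACF are computed up to lag 11 and
compared against the white-noise band $\pm z_{1-\alpha/2}/\sqrt{12}$
($\approx \pm 0.566$ at $\alpha = 0.05$). Under the default policy a park is
flagged when lag 1 or 2 of either function, on either the official or the
SUD series, is significant; flagged parks keep their correlation values but
are excluded from the cross-platform comparison and the trend fit. The
trigger lags, level and screened sources are all configurable because the
choice is a convention, not a theorem.

**Cross-platform comparison.** The per-platform distributions of park-wise
correlations are compared with a Kruskal–Wallis omnibus test (chosen over
ANOVA because the group spreads differ), followed by Dunn's post hoc
$z$-tests for each platform pair with Holm–Šidák familywise adjustment
$\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$ (step-down, running-maximum
monotonicity, capped at 1). Tie corrections are always applied in both KW
and Dunn; with no ties they reduce to the classical formulas. The
`combined` source is not a platform and stays out of the omnibus test.

**Popularity-vs-performance trend.** Pattern correlations are regressed on
$\log_{10}$ annual totals (official visitors or SUD) over non-excluded
parks; zero-total parks are dropped with a report because the logarithm is
undefined. A positive slope means the social signal is more faithful in
more visited parks.

## The synthetic generator

Real multi-platform post datasets are restricted by platform terms of
service, so the package ships a generator whose output has the statistical
structure the analysis assumes, making every stage testable end to end:

* **parks**: disjoint convex polygons on a jittered grid in a configurable
  region (default a boreal-latitude box), radii 2–12 km;
* **popularity**: annual visitors log-uniform between configurable bounds
  (default 200–20 000, two orders of magnitude, mirroring the spread
  between flagship and remote parks);
* **seasonality**: a circular unimodal profile
  $\pi_m \propto \exp\{\kappa \cos 2\pi(m - \text{peak})/12\}$ (default
  $\kappa = 1.5$), optionally a bimodal mixture for summer-plus-winter-sport
  systems; monthly counts are the annual total apportioned by
  largest-remainder rounding, so they sum exactly;
* **visits**: geometric visit lengths (default mean 2 days), uniform
  arrival day within the month; visits may straddle month ends;
* **posting**: each visitor-day independently yields content on platform
  $q$ with adoption probability $p_q$; the number of posts on an active day
  is a per-user draw from a discrete power law $P(k) \propto k^{-\alpha}$,
  $k \le 50$ (default $\alpha = 2.2$) — participation inequality that
  inflates posts, never user-days. Default adoptions (instagram 0.003,
  twitter 0.001, flickr 0.0003 per visitor-day) reproduce the observed
  country-level ratio of user-days to official visitors of roughly 0.4%,
  split roughly 71/25/4% across the three platforms;
* **geotags**: uniform within the park plus Gaussian jitter (default
  50 m); a small fraction (default 2%) is relocated uniformly over the
  region as mis-geotagged noise.

Everything is deterministic given `seed`; the visit/user-day lineage and the
posting intensities use separate seeded streams so intensity settings cannot
perturb user-days. `simulateUserDays()` is an analytic shortcut — monthly
SUD drawn as Binomial(visitor-days, adoption) — distribution-matched to the
full post-level path when noise is off, used where hundreds of replicate
systems are needed; the test suite checks the two paths agree in
distribution.

What the generator does **not** emulate: weather and event shocks,
demographic composition (age/gender adoption gradients), bot traffic,
cross-user correlation in timing beyond seasonality, repeat visitors, and
measurement error in official statistics (synthetic official counts are the
truth itself). Passing recovery tests therefore show the pipeline is
correct and well calibrated under clean conditions; they do not certify
accuracy on real, messier data.

### A consequence of deterministic truth

Because the synthetic monthly truth is a smooth seasonal curve with no
process noise, its lag-1 autocorrelation is essentially that of a cosine
(≈ 0.7) — far outside the white-noise band. Every synthetic park is
therefore flagged by the default screen, which with real, noisier data
flags only a subset. Simulation studies in the tests and the acceptance
script consequently run the correlation stage with the screen's trigger
lags disabled (`flag_lags = integer()`); the screen itself is exercised by
dedicated unit tests (alternating series, constant series, hand-computed
ACF). This is a property of the simulated world, not of the method.

### Calibration conditions

The type-I calibration of the Kruskal–Wallis comparison simulates **three
identically-parameterized platforms over identical parks** (equal annual
visitors, same peak month). With heterogeneous parks, a park's size and
profile shift all three of its platform correlations together; that shared
park effect makes KW conservative (it is a test for independent samples),
which would test the wrong null. Homogeneous parks make the park-wise
correlations exchangeable across platforms, isolating exactly the
platform-difference null. Rejection at nominal 5% is verified over 500
replicate systems.

## Numerical and design choices

* Spearman/Pearson/KW come from base R (`cor`, `kruskal.test`); Dunn's test
  and Holm–Šidák are implemented here and checked against closed-form hand
  oracles. ACF/PACF use `stats::acf`/`stats::pacf` (denominator $n$,
  Yule-Walker PACF) and are tested against direct-formula oracles.
* Ranking direction: rank 1 is always the most visited park.
* Undefined quantities (zero-variance or all-zero series, constant totals)
  are `NA`, never silently 0.
* Ties: average ranks everywhere; lexicographic `park_id` for spatial
  ties; pairs reported in lexicographic group order.
* Proportion sums are exact to 1e-9; CSV round trips preserve full double
  precision (`%.17g`).
* Row conservation is enforced and logged at every reader and at the
  assignment stage (`rows_in = accepted + rejected`; assignment modes
  partition posts).
* Problem sizes in the shipped tests and acceptance script — 20-park
  systems for recovery and trend studies (50 replicate systems per
  condition), 15 identical parks × 500 replicates for calibration, ≤ 200
  records for oracle fixtures — were chosen to make the full suite run in a
  couple of minutes on one core while leaving the stochastic checks with
  comfortable statistical margins.

## Limitations

* GeoJSON is the only polygon input format; geometries must already be
  WGS84 lon/lat (as RFC 7946 requires).
* The buffered-polygon representation treats any hole contours emerging
  from offsetting multipart geometries as additional outer parts when
  computing areas; containment (even-odd) is unaffected.
* Point-in-polygon runs directly in lon/lat and assumes parks do not cross
  the antimeridian.
* Official statistics are taken at face value; the package quantifies
  social-media error against them, not their own error.
* A single analysis year is assumed throughout the statistics layer;
  multi-year inputs are analysed year by year.
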