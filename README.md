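# parkdays

Visitor monitoring for national parks and other protected areas from
geotagged social-media posts.

Park agencies need visitation numbers, but counters, ticket registers and
surveys are laborious and unevenly available. Geotagged posts from
platforms such as Instagram, Twitter and Flickr are a cheap continuous
proxy — if handled carefully. `parkdays` is aimed at conservation
scientists and park-agency analysts who want to (a) turn raw geotagged
posts into monthly visitation series per park and platform, and (b) judge,
against official visitor statistics, where that proxy can be trusted.

## The statistic

The package's central quantity is the **social-media user-day (SUD)**: the
number of distinct (user, park, calendar day, platform) tuples,

```
SUD(park, month) = #{ (user, day) : user posted from park on day, day ∈ month }
```

A user uploading five photos on one day counts once; one photo on each of
three consecutive days counts three times — the same convention trail
counters apply to multi-day visitors. Deduplicating per day makes SUD
robust to participation inequality (a small fraction of users produces
most posts).

Around SUD the package implements the full evaluation workflow:

* **io**: delimited posts (configurable dialect), GeoJSON park polygons,
  monthly official statistics; strict validation with reject counts.
* **spatial assignment**: polygon containment plus a metric buffer
  (default 10 km, computed in a per-park azimuthal-equidistant projection),
  platform-aware exclusion zones, deterministic tie-breaking.
* **statistics**: Spearman popularity ranking (rank 1 = most visited);
  monthly-proportion standardisation and Pearson pattern correlation;
  ACF/PACF screening of the short series (white-noise band ±1.96/√12);
  popularity-vs-performance trends on log10 totals.
* **platform comparison**: Kruskal–Wallis omnibus test plus Dunn's post
  hoc z-tests with Holm–Šidák familywise adjustment.
* **synthetic data**: a seeded generator (seasonal visitation, log-uniform
  popularity, per-platform adoption, heavy-tailed per-user activity,
  geotag jitter and noise) so the whole pipeline can be validated without
  restricted platform data.

## Worked example

Simulate an 8-park system with three platforms of decreasing adoption,
run the pipeline, and compare platforms:

```r
library(parkdays)

cfg <- simulationConfig(n_parks = 8, seed = 42,
                        platforms = c(instagram = 0.05, twitter = 0.02,
                                      flickr = 0.005))
sim <- simulateDataset(cfg)
nrow(sim$posts)
#> [1] 10096

assigned <- assignPosts(sim$posts, sim$parks, buffer_m = 10000)
assignmentSummary(assigned)
#>   interior     buffer unassigned   excluded
#>       9818         80        198          0

ud <- computeUserDays(assigned, tz = "UTC")
nrow(ud)
#> [1] 4530

mm <- monthlySUD(ud, 2014, park_ids = parkIds(sim$parks),
                 platforms = names(cfg$platforms))
mm <- attachOfficial(combinePlatforms(mm), sim$official)
mm
#> MonthlyMatrix: 8 park(s) x 12 month(s); sources: flickr, instagram, twitter, combined, official
```

10 096 posts collapse to 4 530 user-days; 198 posts were mis-geotagged
noise landing outside every park and its buffer, and stay `unassigned`
(the four modes always partition the input). Popularity and patterns:

```r
tot <- annualTotals(mm)
off <- tot[tot$source == "official", ]
cmb <- tot[tot$source == "combined", ]
spearmanRanking(setNames(off$total, off$park_id),
                setNames(cmb$total, cmb$park_id))
#> Spearman rank correlation: 1.000 over 8 parks

corr <- parkCorrelations(mm, 2014, flag_lags = integer())
summarizeCorrelations(corr)[, c("source", "median_r", "share_ge_0.7",
                                "share_negative")]
#>      source  median_r share_ge_0.7 share_negative
#> 1  combined 0.9698217        1.000              0
#> 2    flickr 0.6324554        0.375              0
#> 3 instagram 0.9681029        1.000              0
#> 4   twitter 0.9082679        1.000              0
```

The combined annual user-days rank the parks exactly as the official
totals do (r_s = 1). The sparse platform (flickr, adoption 0.005) tracks
monthly patterns far worse (median Pearson r = 0.63) than the data-rich
ones — exactly the volume effect the comparison stage quantifies:

```r
comparePlatforms(corr)
#> Kruskal-Wallis: H = 9.215, df = 2, p = 0.009977 (n = 24 values)
#> Dunn's post hoc (Holm-Sidak adjusted):
#>     group_i   group_j      z    p_raw p_adjusted
#> 1    flickr instagram -3.005 0.002654   0.007941
#> 2    flickr   twitter -1.874 0.060953   0.118192
#> 3 instagram   twitter  1.131 0.257899   0.257899
```

(`flag_lags = integer()` disables the autocorrelation screen, which flags
every park of this deterministic synthetic world; see the vignette,
section "A consequence of deterministic truth".)

`runPipeline(pipelineConfig(...))` performs the same sequence from files
on disk and writes the result tables plus a run manifest;
`inst/scripts/parkdays-cli.R` wraps it for shell use
(`simulate | assign | sud | analyze | compare | run | report`).

## Package layout

```
R/                  implementation (S4 classes ParkSet, MonthlyMatrix;
                    camelCase exported functions)
tests/testthat/     unit, property and end-to-end suites with independent
                    brute-force/closed-form oracles
scripts/acceptance.R  headline-number reproduction (see above)
inst/scripts/       command-line wrapper
vignettes/          methods vignette (model, assumptions, design choices)
```
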