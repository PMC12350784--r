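# iomove

Movement-ecology analysis for GPS-tracked raptors that alternate between a
stationary **place of residency** and episodic **commuting** to disjunct
satellite areas — the movement syndrome shown by the ʻIo (Hawaiian Hawk,
*Buteo solitarius*). The package takes duty-cycled GPS fixes (hourly by day,
3-hourly by night; 16 fixes/day) through a complete, tested pipeline:

1. **Trajectory QC** — satellite-count/fix-dimension screening, speed and
   core-displacement outlier flagging, and horizontal-error calibration from
   stationary reference tags (RMS of 2-D centroid distances with a
   chi-squared CI).
2. **Behavioral segmentation** — exact dynamic-programming change-point
   detection on the coordinate series (per-segment Gaussian mean and
   variance per axis, minimum segment length, penalized model selection),
   then classification of segments into *stationary* vs *commuting* states
   by their coordinate SD.
3. **Home ranges** — continuous-time movement models (IID, OU, OUF) with
   measurement error fitted by the exact Kalman (state-space) likelihood and
   selected by AICc; autocorrelation-corrected kernel density estimation
   with bandwidth at the effective sample size `N_eff = duration / tau`;
   50% and 95% isopleths with areas in hectares and chi-squared CIs; paired
   t-tests of log areas between states.
4. **Recursion statistics** — visits to polygons and discs with exact
   linearly interpolated boundary-crossing times; commuting-trip counts,
   durations and between-trip residency relative to the 95% stationary
   isopleth; a two-step nest estimator (20-m/12-h revisit ranking, then a
   50-m/90-h residency-peak rule for the hatch date).
5. **Habitat selection (iSSA)** — 2-h step resampling, gamma/von Mises
   movement kernels, 30 matched available steps per observed step with
   percent-cover covariates at 40-m and 500-m buffers, conditional logistic
   regression (Newton-Raphson, observed-information SEs), selection-free
   kernel adjustment (`shape' = shape + b_log_sl`,
   `1/scale' = 1/scale - b_sl`, `kappa' = kappa + b_cos_ta`) and
   inverse-variance population pooling with a percentile bootstrap.
6. **Synthetic data** — seeded generators with exact ground truth for all of
   the above: dual-state commuting tracks (exact-transition OU + ballistic
   transits), nest attendance, patchy categorical landcover, habitat-biased
   step-selection walkers, and stationary calibration tags.

The conditional-logit model is written

```
L(beta) = prod_s  exp(beta' x_obs(s)) / sum_{j in s} exp(beta' x_j)
```

over strata `s` of 1 observed + 30 available steps; positive coefficients
are log relative selection strength (log-RSS) per unit (or SD) of the
covariate.

## Worked example

```r
library(iomove)

sim <- simulate_dual_state_track(sim_config(rng_seed = 11))
seg <- classify_states(segment_track(sim$track, min_segment_length = 100))
seg
#> <io_segmentation> bird sim: 6 segment(s), 5 change point(s)
#>   start_index end_index sd_easting sd_northing      state duration_days
#> 1           1       114   201.9380    279.9789 stationary      7.416667
#> 2         114       413   303.7741    290.4421 stationary     18.875000
#> 3         413       545  5957.8001   2477.8664  commuting      8.458333
#> 4         545       649  4156.0273   1748.3711  commuting      6.333333
#> 5         649       753  5755.4047   2527.7744  commuting      6.833333
#> 6         753       942   271.4925    293.1099 stationary     12.041667

summarize_states(seg, sim$track)$proportion_time_commuting
#> [1] 0.3606671

stat <- subset_track(sim$track, which(state_per_fix(seg) == "stationary"))
m <- fit_movement_model(stat, "OU", error_rms = 5.9)
m
#> <io_movement_model> OU: sigma2 = 83952.9 m^2, tau_p = 5.38 h,
#>   logLik = -7940.25, AICc = 15888.57 (n = 601)

akde_homerange(stat, m, 0.95)
#> <io_homerange> 95% isopleth: 168.1 ha (95% CI 149.7-190.2),
#>   N_eff = 267.4, h = 114.2 m
```

The simulated bird moves as an OU process with a 300-m per-axis SD
(sigma^2 = 9e4 m^2; the fit recovers 8.4e4) around its residency centre and
commutes to a satellite area 13 km away during its commuting session, whose
trips wind down before the session closes — hence the two-state structure
with an order-of-magnitude SD contrast and a final stationary segment. The
stationary 95% home range comes out near the analytic
`pi * 5.991 * sigma^2` ~ 160 ha for the fitted variance.

`run_analysis(analysis_config(rng_seed = 1))` runs the whole pipeline on the
default 10-commuter / 5-resident scenario and returns per-bird tracking,
area and commuting tables (commuting columns are `NA` for resident birds).

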