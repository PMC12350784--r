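---
title: "Models and methods behind iomove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind iomove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iomove)
```

`iomove` analyses duty-cycled GPS tracks of central-place foraging raptors
whose movement alternates between a stationary *place of residency* and
episodic *commuting* to geographically disjunct satellite areas. This
vignette records the models, the parameters that matter, the numerical
choices, and the places where the design was genuinely open — in enough
detail that a maintainer can judge every default.

## Data model and conventions

A track is a strictly time-ordered sequence of projected positions (metres)
with satellite count and fix-dimension metadata. Timestamps are stored in
UTC; the duty cycle (default: hourly fixes in the local day window
[06:00, 18:00), 3-hourly at night, hence 16 fixes/day) is evaluated at a
configurable local offset, default UTC−10. The day window is half-open so
the 18:00 fix belongs to the night block; that is what makes the per-day
count come out at 12 + 4 = 16.

Horizontal GPS error is summarized as the RMS of 2-D distances of
stationary-tag fixes from their per-tag centroid, so an isotropic per-axis
error `sigma` is reported as `sqrt(2)*sigma`; the per-axis alternative
(divide by `sqrt(2)`) is noted in the docs. The 95% CI treats the pooled sum
of squared deviations as `sigma_axis^2 * chi^2` on `2(n - n_tags)` degrees
of freedom (two coordinates per fix, one centroid per tag per axis) and is
widened, if necessary, to include the point estimate — the plain RMS and the
df-corrected scale differ at very small per-tag n.

Outlier screening flags a fix when the minimum speed needed to reach it from
*both* temporal neighbours exceeds `max_speed` (default 30 000 m/h) or when
it lies further than `max_core_distance` (default 50 km) from the
coordinate-wise median. Requiring both neighbour speeds makes the rule
robust to a single bad neighbour. Flags are returned, not applied; the
pipeline removes them.

## Change-point segmentation

The coordinate series is modelled per segment as independent Gaussian per
axis with segment-specific mean **and** variance, so change points respond
to shifts in either location or dispersion. For each number of segments `K`
the placement minimizing the summed negative log-likelihood is found exactly
by dynamic programming under a minimum segment length (default 225 fixes,
about two weeks at 16/day), and `K` minimizes `NLL(K) + beta*K*log(n)`.

The penalty multiplier defaults to `beta = 2.5`, not 1: each extra segment
frees two means, two variances and a break location, so a unit multiplier
(one parameter's worth) under-penalizes — on homogeneous white-noise tracks
(n = 600, minimum length 50) it introduced spurious splits in roughly a
fifth of replicates, while `beta = 2.5` produced none and did not impair
recovery of genuine variance shifts. Within-state positional autocorrelation
still produces occasional extra splits inside a state; these are benign
because classification is per segment and pools segments by state.

Segments are classified by deterministic 1-D k-means (quantile
initialization) on the log geometric-mean coordinate SD. The higher cluster
is *commuting*; if the cluster centres differ by less than `log(2)` (SD
ratio < 2) the split is judged spurious and all segments are stationary —
genuinely dual-state birds separate by roughly an order of magnitude, so a
factor-2 gap is noise. Segmentation runs on fix index, not clock time; the
duty cycle keeps sampling near-regular and gap handling is deferred to the
recursion stage.

## Continuous-time movement models and AKDE

Three stationary processes are fitted per axis (axes independent, isotropic
parameters): IID (no autocorrelation), OU with position autocovariance
`sigma^2 * exp(-dt/tau_p)`, and OUF with autocovariance
`sigma^2/(tau_p - tau_v) * (tau_p*exp(-dt/tau_p) - tau_v*exp(-dt/tau_v))`.
Measurement error adds `error_rms^2/2` per axis. The likelihood is evaluated
exactly by the Kalman recursion — a 1-D state for OU and a 2-D
(position, velocity) state for OUF, whose exact discrete transition has
eigenvalues `-1/tau_p`, `-1/tau_v`, stationary position variance `sigma^2`,
velocity variance `sigma^2/(tau_p tau_v)` and zero cross-covariance. Tests
verify equality with the dense multivariate-normal likelihood to 1e-6
relative at n = 200. Optimization is Nelder-Mead on log-scale parameters
with the stationary mean estimated jointly; `tau_v` is parameterized as a
logit fraction of `tau_p` to enforce the ordering. Models are compared by
`AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with ties broken toward fewer
parameters.

Home ranges use Gaussian-kernel density with the 2-D reference bandwidth at
the *effective* sample size: `h = sigma_hat * N_eff^(-1/6)` with
`N_eff = duration/tau_p` for OU/OUF (capped at n; the "number of range
crossings" heuristic) and `N_eff = n` for IID. The isopleth is extracted on
a 256x256 grid padded three bandwidths beyond the data extent; the area sums
pixel mass down the density ordering with sub-pixel interpolation at the
contour, and the CI scales the area by `chi^2` quantiles on `2*N_eff`
degrees of freedom — an approximation (one df per coordinate per effective
fix), flagged as such. On IID Gaussian data the 95% area lands within a few
percent of the analytic `pi * 5.991 * sigma^2` (kernel smoothing inflates it
by about `h^2/sigma^2`, under 10% at the tested sizes); the package's
acceptance check allows 15%.

State areas are compared by a classical paired t-test on log areas, with
the sign convention `log(stationary) - log(commuting)` (commuting larger
gives negative t) and a geometric-mean fold change.

## Recursion statistics

The trajectory is treated as piecewise linear between fixes. Disc crossings
are solved exactly from the chord quadratic; polygon crossings intersect
each chord with every edge and classify the sub-intervals by midpoint tests,
so tangencies cannot desynchronize the inside/outside parity. Visits merge
when the absence between them is shorter than the time threshold (0 = no
merging). Interpolated crossings that span a sampling gap longer than 12 h
are flagged low-confidence — the 3-h night spacing makes such chords common.
Conservation (inside + outside time = tracked window) holds to well under a
second, and tests pin the visit structure to a dense 1-s resampling oracle.

Commuting trips are completed excursions — an exit from the residency
polygon (the 95% stationary isopleth) followed by re-entry — evaluated only
within commuting segments; open excursions at a window end are reported
separately, never counted. Trip duration is the time outside ("time to
return"); residency bouts are the closed visit durations inside.

### Nest location and hatch date

The nest estimator scores every diurnal fix by the visits to a 20-m disc
centred on it (20 m ~ three times the GPS error), with absences shorter
than 12 h merged so only day-to-day returns count. Candidates are ranked by
the composite `revisits * residency / mean_return` rather than
lexicographically by revisits alone: continuous attendance merges into few
long visits, so a strict most-revisits ordering systematically prefers
incidentally passed-through locations over the attended nest (we verified
this failure on simulated attendance, where the lexicographic winner was
20-250 m off). The composite is log-additive in the three nest signatures
and well behaved because merged return times are bounded below by the 12-h
threshold. The reported location is then refined by three mean-shift
iterations (centroid of fixes within the search radius), which averages the
GPS error out of any single winning fix; recovery in simulation is then
typically within a metre of the true nest.

The hatch date is the local calendar date opening the earliest visit to a
50-m disc around the nest (no merging) whose duration reaches 90 h and whose
preceding absence is at most `return_near_zero` hours. The 90-h bar reflects
continuous brooding just after hatch; the near-zero-return default is 6 h,
not one nominal fix interval, because under the 1-h/3-h duty cycle a single
missed nocturnal fix registers, after linear interpolation, as an absence of
up to about two night intervals. The first visit of a series, having no
preceding absence, qualifies on duration alone.

## Integrated step-selection analysis

Tracks are resampled to a 2-h target interval (tolerance 0.5, so the 1-3-h
duty-cycle spacing passes and the hourly daytime data thin to 2 h), with
bursts split at holes. Observed step lengths get a gamma kernel (Newton on
the shape via the digamma equation; lengths floored at 1 m before logs) and
turn angles a von Mises kernel with mean fixed at zero (concentration from
`I1/I0 = mean cos`, capped at 500 on degenerate input). Each observed step
is matched with 30 available steps drawn from those kernels at the observed
start point and previous heading; draws landing outside the raster or on
water/barren are redrawn up to 100 times before the stratum is dropped.
Habitat covariates — forest and disturbed (agriculture + developed) percent
cover in 40-m and 500-m buffers by pixel-centre counting, plus the landcover
class at the endpoint — are standardized over the individual-state dataset
(constants stored so effects can be reported per SD or per natural unit);
the movement adjusters `step_length`, `log(step_length)`,
`cos(turn_angle)` stay in natural units so the fitted coefficients can
adjust the kernel directly. The raw turn angle is aliased with the von Mises
mean under the symmetric kernel and sits behind a flag, off by default.

The conditional logistic likelihood is maximized by Newton-Raphson with step
halving on internally rescaled columns; standard errors come from the
observed information. Covariates with no within-stratum variation are frozen
at zero with an infinite SE (they carry no conditional information), and
runaway estimates are flagged as separation rather than failing. An
independent fit by `survival::clogit` agrees to four significant digits in
the tests, the score is unbiased at the truth, and the 95% CI's type-I error
under the null sits at 5% over a thousand simulated stratum sets.

The selection-free kernel inverts the exponential-family tilt exactly:
`shape' = shape + b_log_sl`, `1/scale' = 1/scale - b_sl` (requiring
`1/scale > b_sl`), `kappa' = max(kappa + b_cos_ta, 0)`; the mean movement
rate is `shape' * scale'` per step interval. Population pooling is the
inverse-variance weighted mean with a percentile bootstrap that resamples
individuals and redraws each resampled coefficient from
`Normal(b_i, se_i^2)`; for m identical individuals the CI width converges to
`2*1.96*se/sqrt(m)` (the value the stated procedure implies). CIs
overlapping zero are labelled indifference, otherwise selection or avoidance
by sign.

## The synthetic generators: what they emulate, and what they do not

The generators' defaults are the study conditions: 16 fixes/day on the
1-h/3-h duty cycle, 2% missingness, 5.9 m horizontal error RMS, OU residency
with a 300-m per-axis SD and a 6-h position timescale, a satellite area
13 km away reached at 8 km/h (near-ballistic transits, so few fixes land
between the areas), lognormal trip durations with median 17 h and inter-trip
residency with median 28.3 h, and a default scenario of 10 commuters and 5
residents. Track length defaults to 60 days with one commuting session over
days 25-55 — long enough for two-state structure at several segments, short
enough that the full scenario runs in minutes. OU sampling uses the exact
discrete-time transition, so movement-model fitting faces no discretization
bias. A fresh stationary draw opens each residency or dwell bout (the
transit legs bridge the areas, so the discontinuity is below the process
SD).

Nest attendance ramps linearly from 0.2 at track start to 0.85 just before
brooding onset — little attendance before laying, near-continuous sitting in
late incubation — then holds a continuous bout of at least 96 h within GPS
error of the nest. The upper endpoint is deliberately below 1: at 0.95 the
fix-level Bernoulli model produces unbroken 90-h attendance runs *before*
the bout a few percent of the time, which no real incubating female shows
(daily recesses), and which would teach the hatch rule to fire early. A
scalar share gives the flat model. Bernoulli fix-level attendance remains a
simplification: real recesses are short and regular rather than independent
per fix, so occasional long simulated absences just before the bout (night
gaps spanned by interpolation) put joint nest-plus-hatch recovery near, not
at, 100%.

Landcover is a Gaussian random field smoothed at a 300-m patch scale and
thresholded at the target class-fraction quantiles — contiguous patches,
exact fractions up to ties, deterministic per seed. The step-selection
walker draws 200 candidate steps from the true kernel and picks one with
probability proportional to `exp(beta' x)`; candidates off-raster or on
water/barren get zero weight, which matches the redraw-truncated
availability used in fitting, so the conditional-logit estimating equation
stays consistent.

What passing tests on these generators do **not** show: robustness to
habitat-driven residency movement (the OU is habitat-blind), to
tag-failure gaps longer than the duty cycle, to non-Gaussian heavy-tailed
position error, or to nest attendance patterns outside the ramped-Bernoulli
family. Field-scale quantities (multi-hundred-day tracks, order-10^4-ha
commuting ranges) are represented at reduced scale.

## Problem sizes and determinism

Every simulation is exactly reproducible from its integer seed, and the
pipeline derives per-bird seeds from one configuration seed, so full runs
are deterministic end to end. The validation suite uses 200 replicates for
change-point recovery, 100 for OU recovery, nest recovery and
step-selection coverage, and 1000 for the null-calibration of the
conditional-logit CI; the acceptance script scales the Monte-Carlo blocks
to 30-50 replicates. These sizes put the Monte-Carlo error of each rate
well inside the margin it is checked against while keeping a full run in
the minutes range on a single CPU.

## Known limitations

- The OUF velocity timescale is weakly identified at 2-h spacing when
  `tau_v` is well below the fix interval; the fit then rides the boundary
  and AICc falls back to OU, which is the intended behaviour.
- The AKDE CI's `2*N_eff` degrees of freedom is a variance-scaling
  approximation, not the exact kernel-variance propagation.
- Percent cover uses pixel-centre inclusion; area-weighting partial pixels
  would shift covers by at most one pixel quantum at the 40-m radius.
- The conditional logit is a fixed-effects-per-individual analysis pooled
  afterwards; random-effects formulations are out of scope.
- Commuting-trip metrics depend on the residency polygon; a poorly resolved
  stationary isopleth (low effective sample size) propagates into trip
  counts.
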