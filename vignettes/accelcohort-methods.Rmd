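---
title: "Methods: accelerometer reduction and cohort inference in accelcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer reduction and cohort inference in accelcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcohort)
```

## The problem

Waist-worn accelerometers in child cohort studies record activity
*counts* and steps in short epochs (typically 15 s) over about a week.
Before any epidemiology can happen, the raw epoch stream must be reduced
to per-child outcomes through a chain of cleaning rules — spurious-count
removal, non-wear detection, wear-period delimitation, valid-day and
valid-child selection — and then standardized so that children who wore
the monitor for different lengths of time are comparable. `accelcohort`
implements that chain, the derived outcomes (mean cpm, sedentary and
MVPA time, steps, guideline adherence), and the survey-weighted cohort
statistics built on top of them, together with a seeded synthetic
cohort generator that emits full latent ground truth so every rule is
testable without access to restricted cohort data.

## Reduction rules and their boundaries

All counts-per-minute (cpm) thresholds are defined on 60 s epochs, so
15 s recordings are re-integrated (block sums) to 60 s before reduction;
applying minute-denominated cut-points at 15 s granularity would
quadruple boundary noise around each threshold. The re-integration
decision is visible in the pipeline (an explicit `reintegrate()` step)
so the alternative — scaling thresholds by `epoch/60` — can be compared
if wanted.

The rules, with every boundary inclusive exactly as conventionally
printed:

* **Spurious counts**: epochs at ≥ 11 715 cpm are biologically
  implausible and removed from both numerator (counts) and denominator
  (registered time). Spurious epochs are *not* zeros: they break
  zero-count runs during non-wear detection.
* **Non-wear**: every maximal run of consecutive zero-count worn epochs
  lasting ≥ 20 min. Runs of 19 min stay wear. The rule is literal
  ("consecutive zero"): the default interruption tolerance is 0 minutes,
  with a config knob (`nonwear_tolerance_minutes`) to probe sensitivity.
  A zero run spanning midnight is assessed once against the 20-min rule,
  then split at midnight for day accounting.
* **Wear days / start–end detection**: a day counts as a wear day if it
  has ≥ 150 registered minutes inside the waking window 07:00–21:59; the
  first and last such days delimit the observation period (days outside
  it, e.g. postal-transit days, are excluded with reason
  `outside_start_end`).
* **Valid days and inclusion**: ≥ 10 h (600 min) of registered time over
  the *whole* day makes a valid day; children with ≥ 2 valid days are
  included. The 150-min rule is evaluated on the waking window (it is
  tied to start/end detection), while the 10-h rule uses the full day;
  whether the original processing also windowed the 10-h rule is not
  stated in the source literature, so the more permissive full-day
  reading is used and both windows are explicit config fields.
* Spurious epochs are removed epoch-wise (they do not disqualify a whole
  day); day-level exclusion would discard hundreds of valid minutes for
  a single monitor glitch.

Every excluded day and child carries a machine-readable reason, and
`flow_table()` reconciles: included + every exclusion reason = total.

## Derived outcomes and the standard day

Worn minutes are classified sedentary (< 100 cpm), MVPA (> 2241 cpm) or
light (the residual class). The inequalities are strict, so minutes at
exactly 100 or 2241 cpm are light. Because registered time varies from
day to day, per-class minutes of each valid day are rescaled to a
**standard day** of 735 min (the conventional mean wear time across
reliable days): `class_min × 735 / registered_min`, so classes sum to
735 exactly. 735 is a fixed constant by default — results stay
comparable with the convention — rather than recomputed per cohort;
`standard_day` is an argument wherever it matters. Fractional minutes
are kept; `round_to_standard_day()` provides largest-remainder integer
rounding when a table wants integers.

Per child: `mean_cpm` pools total counts over total worn minutes across
valid days (a ratio of sums, *not* a mean of daily cpm); sedentary,
light and MVPA are means of per-day standardized values; `steps_day` is
the plain mean of per-valid-day step sums (steps are counts of events,
not time shares, so wear-time standardization is not applied to them);
adherence is standardized MVPA ≥ 60 min/day, boundary inclusive, so a
child at exactly 60.0 meets the guideline. Daily MVPA is averaged over
valid days only.

`cutpoint_sensitivity()` re-classifies the retained masked epochs under
alternative MVPA cut-points (the wear mask and day selection do not
depend on the MVPA threshold, so they are computed once); adherence is
non-increasing in the threshold by construction.

## Weighted inference

Sampling weights are consumed as given, treated as single-level
child weights; design-based clustered variance is an extension point,
and all uncertainty here comes from a seeded nonparametric bootstrap
over children. All estimators are invariant to rescaling the weights by
a constant.

* **Quantiles** are weighted inverse-CDF quantiles (the smallest value
  whose cumulative normalized weight reaches *p*); with equal weights
  this is the ordinary type-1 sample quantile, appropriate for the
  right-skewed activity outcomes.
* **Season adjustment** of group medians/IQRs uses direct
  standardization: within a group, children are reweighted so the
  group's season distribution matches the cohort-wide weighted season
  distribution, and weighted quantiles are taken from the reweighted
  sample. This was chosen over quantile regression with season
  indicators because it is exactly reproducible, distribution-free, and
  coincides with the regression estimate in balanced designs; the
  trade-off (no smoothing across empty cells) is handled explicitly: a
  group missing a season either renormalizes over its seasons
  (recorded in `missing_seasons`) or is suppressed, per the
  `incomplete` argument. Seasons are astronomical: spring 21 Mar–20 Jun,
  summer 21 Jun–20 Sep, autumn 21 Sep–20 Dec, winter otherwise.
* **Adjusted prevalences** come from a weighted logistic model via
  marginal standardization: each exposure level is substituted for the
  whole cohort and the predicted probabilities averaged with the
  weights. With no covariates this reduces exactly to the weighted
  crude prevalence. Non-convergence or separation raises a classed
  estimation error rather than returning silent garbage;
  `cohort_report()` catches it per factor, warns, and reports `NA`.
* **Pairwise comparisons** between group levels use two-sided bootstrap
  percentile p-values on differences of season-adjusted medians (or
  prevalences) — the source analyses do not print their pairwise test
  statistics, so a reproducible bootstrap substitute is used and
  documented, not asserted as equivalent. The Benjamini–Hochberg
  step-up rule at q = 0.05 (via `stats::p.adjust`) decides which pairs
  are annotated with letter superindices.
* **Moran's I** over regions uses a *pure* second-order
  nearest-neighbour weight matrix — neighbours-of-neighbours excluding
  self and excluding first-order neighbours, row-standardized — since
  higher-order neighbourhood conventions vary and this one is stated
  explicitly. The p-value is a two-sided seeded permutation test
  (default 9999 permutations). Binary (unstandardized) weights can be
  obtained by passing the `neighbours` matrix directly.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's properties are demonstrated.
Per child, a daily wear window (wear-on ~ 07:45 ± 24 min, wear-off ~
20:30 ± 24 min) is drawn, within-wear non-wear bouts are planted
(Poisson rate 0.7/day, length 25 min + lognormal extra, so every bout
is identifiable by the 20-min rule), and worn minutes follow a
bout-level three-state process (mean dwell 5/3/2 min for
sedentary/light/MVPA) with state-specific count distributions:
sedentary 1–98 cpm (mean ≈ 25), light truncated-lognormal in
(100, 2241), MVPA truncated-lognormal above 2241. Steps are coupled to
counts (`steps ≈ 0.024 × counts` with lognormal noise, zero when counts
are zero) and rare spurious spikes (rate 2 × 10⁻⁴ per worn minute,
12 000–20 000 cpm) are injected. One low-wear postal-transit day is
added before and after the 7-day protocol so start/end detection has
something to find.

Calibration was fixed once, from published cohort summaries for this
age group: sedentary occupancy 0.522 of wear (≈ 6.4 h/day of a 12.25-h
standard day), base MVPA occupancy 60.1/735, between-child lognormal
spread 0.355 (reproducing the observed IQR ratio ≈ 76/47), gender
multipliers 1.11/0.90 (boys/girls, median ratio ≈ 1.23 and adherence
≈ 63%/38%), ethnic-group multipliers equal to the published MVPA median
ratios, and count-distribution locations chosen so overall cpm lands
near 595 and steps near 10 200/day. Season (spring 1.02, summer 1.10,
autumn 0.95, winter 0.88) and region (North West 1.06, Midlands 0.94,
Northern Ireland 0.93) multipliers are not printed anywhere and were
chosen once as plausible magnitudes; they exist so that season
adjustment and the spatial statistics have signal to work with.

Two deliberate departures from physiological realism, and what they
mean for the tests: **(1)** sedentary minutes are strictly positive
(1–98 cpm) so that exact zeros occur only during non-wear — this makes
non-wear detection exactly identifiable and lets closure tests demand
bit-for-bit agreement between pipeline and truth. Real sedentary time
contains true zeros, so on real data the 20-min rule misclassifies some
long still periods; the `soft_nonwear_rate` option plants nonzero
artefacts inside non-wear to probe the other direction. **(2)** bout
states are drawn i.i.d. (a semi-Markov process with a degenerate
transition kernel); only the occupancies and dwell scales the reduction
rules are sensitive to are claimed, not realistic activity dynamics.
Passing closure tests therefore demonstrates the *rules* are
implemented exactly, not that the pipeline is robust to every artefact
of real recordings.

With `boundary_guard = TRUE` (default) generated counts stay ≥ 2 cpm
away from the 100/2241 cut-points and bout lengths away from the
19–21 min window, so classification and detection are unambiguous and
generator/pipeline closure is exact.

`simulate_cohort_table()` is a second, summary-level generator: it
draws child summary rows directly from a stated logistic adherence
model (defaults put girls/boys at the published 37.8%/63.3%) plus
multiplicative gender/season effects on MVPA minutes, for testing the
inference layer against closed-form truth without epoch simulation.

## Numerical and testing choices

Problem sizes were chosen so the full suite exercises every property
at meaningful scale: oracle fuzzing uses 10 000 random sequences per
reduction rule; generator closure uses a 200-child cohort; the
all-null FDR simulation uses 10 000 replicates of m = 36 tests;
inference recovery uses n = 500 children. Recovery of planted
parameters "within 2 bootstrap SEs" is assessed as *coverage* of ±2 SE
intervals across 100 seeded replicates (≥ 88%, i.e. the ~95% nominal
level minus three standard deviations of binomial Monte-Carlo noise):
a single fixed draw fails such a check ~5% of the time for any correct
estimator, so coverage is the form of the claim that is actually
falsifiable. Estimator bias is additionally bounded below one
percentage point over 200 replicates.

Degenerate inputs are errors, not guesses: empty samples, non-positive
weights, constant values for Moran's I, children reaching
summarization with fewer than two valid days, zero registered minutes
in standardization. Ties in largest-remainder rounding break by
position. Bootstrap replicates that fail to fit (resampled separation)
are dropped from SE computation rather than poisoning it.

## Known limitations

* Survey-design (clustered, stratified) variance is not implemented;
  bootstrap SEs treat children as independent.
* Bout-based MVPA definitions (e.g. 10-min bouts) and MET conversion
  are out of scope; the guideline here is total daily minutes.
* The reader handles plain-text epoch CSV dialects only, not
  proprietary vendor binaries.
* Non-wear is never imputed; diary-confirmed wear is not supported.
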