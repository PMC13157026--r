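---
title: "Models and methods behind photodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photodyn)
```

# The problem

Fiber photometry yields one fluorescence time series per sensor and
subject. In auditory noise-burst experiments the stimulus is a 10-s train
of ten band-limited noise bursts (500 ms on / 500 ms off) presented at
45, 65, 85 and 105 dB SPL, ten trains per level in a fixed ascending
order, with inter-train intervals drawn from 25, 30 or 35 s. Two subject
phenotypes are observed in ventral-striatal dopamine signals: a
*decrease* type, whose signal dips with every burst in an
intensity-dependent way and rebounds in the silent gap, and an *increase*
type, which additionally shows a large, fast positive transient at the
onset of the first burst only. The analytic chain quantifies these
responses per burst and per subject, classifies the phenotype, and tests
whether response extrema trend linearly with intensity while respecting
the fact that the 4 intensity measurements from one subject are
correlated.

photodyn implements that chain end to end, together with a synthetic
generator with known ground truth, so every stage can be validated
without recordings.

# Preprocessing

Raw traces (2--6 kHz acquisition) are downsampled to the 120 Hz working
rate (boxcar anti-alias filter + linear interpolation; both steps linear,
so z-scores are unaffected by gain or offset). Each trial is cut to
`[-5, +10)` s around train onset and normalised into z-scores using the
mean and standard deviation of the 5 s before onset. Two conventions are
fixed package-wide: windows are half-open, and sample `i` covers
`[i/rate, (i+1)/rate)`.

The 200-ms moving median (window forced odd = 25 samples at 120 Hz,
truncated at the edges) is applied only for presentation; metrics are
computed on unsmoothed z traces (a `smooth_metrics` flag exists for
sensitivity analysis). Z-scoring is performed after downsampling; the
order is not observable in the downstream metrics because both operations
are linear up to the baseline statistics.

# Response metrics and classification

For a subject and intensity the trials are averaged pointwise, then:

* **first response**: extrema of the burst-1 window `[0, 1)` s of the
  averaged trace;
* **average response**: extrema of the pointwise mean of the ten 1-s
  burst segments;
* **absolute z-score amplitudes**: `|z(onset) - z(peak)|` per burst, the
  onset sample serving as the per-burst baseline;
* **classification**: a subject is *increase* iff the maximum of the
  trial-averaged trace during the noise window `[0, 10)` s strictly
  exceeds 2.58 at any tested intensity (2.58 is kept configurable; a
  maximum exactly at threshold is *decrease*).

The classifier's search window spans the full train rather than single
bursts, because the observed first-burst transients and rebound peaks can
occur anywhere in the train; the per-burst metrics use 1-s windows so the
rebound in the silent half is captured with its burst.

Peak ratios (N2/N1 on negative, P2/P1 on positive peaks) are computed on
signed deviations from the onset value, so stable dips give ratios near
+1 and a vanished second transient gives ratios near 0. Ratios with a
near-zero denominator (`|first| < eps`) are reported as `NA` rather than
a number.

# Trend inference

The intensity trend of a response measure is the pooled OLS line of
`value ~ 1 + intensity` across all subjects, intensity in raw dB so the
slope is z-units per dB. Uncertainty uses the subject-level cluster
sandwich with the CR1/HC1-style factor
`c = G/(G-1) * (N-1)/(N-K)`; with G subjects as small as 6--12, normal
critical values are unreliable, so the p-value comes from a studentized
wild cluster bootstrap-t: the null `beta = beta0` is imposed (restricted
fit), each cluster's restricted residuals are multiplied by one Mammen
weight (`(1-sqrt(5))/2` w.p. `(1+sqrt(5))/(2 sqrt(5))`, else
`(1+sqrt(5))/2`; mean 0, variance 1, third moment 1), the unrestricted
model is refit, and

```
p = (1 + #{b : |t*_b| >= |t_obs|}) / (B + 1)
```

with `B = 10000` in production. Replicates with a degenerate bootstrap SE
count as exceedances (conservative). One subtlety is handled explicitly:
when all G weights of a replicate happen to be equal (probability
`0.7236^G` for Mammen, about 5.4% at G = 9), the bootstrap sample is an
affine transform of the original data and reproduces the observed
studentized statistic *exactly*, for every `beta0`. Counting these exact
ties as exceedances would bound the p-value below by about 0.054 at
G = 9 -- the 5% test could never reject, and test-inversion intervals
would be unbounded; published p-values from this design (e.g. p = 0.010
at n = 12, below the 0.021 tie floor) show that the method as practised
does not count them. photodyn therefore excludes exact ties
(relative tolerance 1e-9) from the exceedance count, deterministically
rather than by floating-point accident. Confidence intervals are obtained by
test inversion: the CI is the set of `beta0` with `p(beta0) >= alpha`.
The same weight draws are reused for every `beta0` (common random
numbers), which makes `p(beta0)` monotone on each side of the estimate
and lets bisection find the endpoints; the tolerance is
`1e-3 * cr_se`, floored at double resolution so near-degenerate fits
terminate.

Design choices that were genuinely open: the bootstrap imposes the null
(the restricted "WCR" flavour recommended in the wild-cluster literature,
and required by test inversion anyway; an unrestricted variant was
evaluated and rejects far too often at G = 9); "HC1" with clustering is
read as the CR1 factor above; two-sided p via `|t|`.

Paired comparisons (pupil, ramped vs damped) use the classical paired t
with two-sided p and, for families of comparisons, the Bonferroni
adjustment `p_adj = min(1, m p)`.

# The synthetic generator

The generator is a stated world, not a tuning knob. Stimulus schedules
reproduce the experiment's geometry exactly (10 x 1-s bursts per train;
fixed intensity order; ISI from {25, 30, 35} s; ramped envelopes 495 ms
rise / 5 ms fall, damped the reverse, flat 5/5 ms). Responses are built
from difference-of-exponentials (alpha-like) kernels, chosen because
their peak time and value have closed forms, which gives the tests
independent oracles:

* **dip**: amplitude `dip_slope * (dB - 45)` (default slope -0.020 z/dB,
  the scale of the reported average-minimum trend; 45 dB is the anchor
  because responses there are near flat), latency 0.35 s, rise/decay
  time constants 50/150 ms;
* **rebound**: fixed amplitude 0.4 z, 0.55 s after burst onset --
  intensity-independent, matching the observed non-trending rebound;
* **onset transient** (increase phenotype): alpha kernel, default 3.6 z,
  150 ms; multiplied by `habituation_factor^(burst-1)` within a train,
  default 0, so only burst 1 shows it (the observed P2/P1 near 0).
  Habituation could plausibly act per burst or per trial; the per-burst
  reading is the one consistent with both the P2/P1 phenomenology and a
  stable trial-averaged classification maximum, so that is the model.
* **envelope tracking**: the dip/transient latency is shifted by half the
  envelope rise time, so ramped trains peak later than damped ones --
  the qualitative ordering reported for ramped/damped experiments.

Subject heterogeneity: slope deviations `Normal(0, 0.004^2)` z/dB
(20% of the population slope, a realistic between-subject spread),
phenotypes Bernoulli, slow sinusoidal drift (0.1 z, 300 s), i.i.d.
Gaussian sensor noise. No pink noise and no bleaching: the baseline
z-scoring assumptions are deliberately satisfied, so green tests
establish correctness of the chain, not robustness to non-stationary
baselines.

**Amplitude units.** Kernel amplitudes are z-units by construction: the
raw trace is `noise_sd * (drift + response) + N(0, noise_sd)`, i.e.
responses are expressed as multiples of the sensor noise sd. Per-trial
baseline z-scoring then recovers the nominal amplitudes whatever the raw
gain. This is the only convention under which "slope -0.020 z/dB"
survives the pipeline's own normalisation; with `noise_sd = 0` the trace
is the z-unit signal itself and is analysed with mean-subtraction only.
A consequence worth knowing: after z-scoring, the per-sample noise is
always ~1 z, so `noise_sd` sets the raw-trace scale, not the effective
z-domain noise.

# Numerical choices and degenerate inputs

* Baseline sd of 0 raises an error naming the trial (no silent NaNs);
  noiseless synthetic traces use `normalize = FALSE`.
* Extrema ties break to the first occurrence; latencies are grid times.
* The moving median window is forced odd; edges use truncated windows,
  so the median-filter root property holds only away from the edges.
* Exact linear fits set `cr_se = 0` with an explicit `degenerate` flag.
* Every simulation function takes a seed and restores the caller's RNG
  state; cohort members get derived sub-seeds, all below 2^31.

# What the tests establish, and known limitations

The acceptance suite checks the sandwich against an explicit-loop oracle
(1e-10), bootstrap type-I error and CI coverage under a clustered null,
slope recovery through the full pipeline (mean over 200 cohorts within
10% of truth), 99% phenotype accuracy, preprocessing invariants, the
paired-t reference p (t = -4.40, df = 9 gives p = 0.0017), and the
ramped/damped latency ordering.

One calibration result deserves emphasis: even with exact ties excluded,
the Mammen-weight null-imposed bootstrap remains mildly conservative at
G = 9 (null rejection ~0.033 at alpha = 0.05 over 1000 simulations,
versus the binomial 95% band [0.036, 0.064] around nominal; CI coverage
~0.978 versus the [0.92, 0.975] band). The same harness with Rademacher
weights is close to nominal (~0.06), and the engine is verified
bit-exactly against a brute-force replicate, so the residual gap is a
property of the asymmetric two-point weight law at few clusters, not an
implementation artefact. The package keeps the Mammen default for
fidelity to the published method; inference at this G errs slightly on
the safe side, and the two corresponding acceptance tests are expected
to sit just outside their bands. Other limitations: the generator's noise model is
white (no 1/f component), the audio carrier is never synthesised (only
the intensity envelope drives responses), and occupancy analysis assumes
the tracker's piecewise-constant position semantics.
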