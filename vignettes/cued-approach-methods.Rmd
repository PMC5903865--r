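---
title: "Methods: peri-event analysis of accumbens units during cued approach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-event analysis of accumbens units during cued approach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedapproach)
```

This vignette documents the statistical machinery of the package: the task
and data model, each analysis stage with its defaults and assumptions, the
synthetic-session generator used to calibrate everything, and the numerical
conventions and known limitations. All empirical statements here are the
ones the test suite and `scripts/acceptance.R` compute.

## The task and the data model

A session is an alternating sequence of intertrial intervals (ITIs) and 5-s
auditory cues. ITIs are drawn from an exponential distribution with mean
30 s, truncated by rejection to [10, 150] s. We read the stated 30-s mean as
the *parent* distribution parameter; truncation removes more short than long
draws, so the realized mean is about 46 s. (The alternative reading — a
truncated distribution whose realized mean is 30 s — would require a parent
mean near 18 s; we chose the parent-parameter reading once and kept it.)
Each trial is CS+ with probability 0.5, independently per trial; no
run-length constraint is imposed because none is part of the task
definition.

A receptacle entry during the CS+ delivers reward and terminates the cue;
the CS− always plays 5 s and entries during it are recorded without
consequence. All times are seconds from session start, and every window in
the package is half-open, `[start, end)`, which removes double counting at
bin edges. The trial table derives, per cue onset: the response flag (any
entry during the cue), response latency, the rewarded entry time, the 10-s
pre-cue baseline window, and the injection-epoch label. For infusion
sessions the pre epoch is `[0, infusion_start)` and the post epoch is the
equal-length window starting at `infusion_end`; the infusion interval itself
belongs to neither. Trials whose baseline overlaps the previous trial's
consumption epoch are flagged, not dropped — whether the original analyses
excluded them is not knowable from the description, and flagging preserves
the choice for the analyst.

Two named baselines are used throughout: the 10-s pre-cue baseline for
Poisson classification and z-scores, and the 1-s pre-cue baseline for auROC
maps.

## Response classification

The classification statistic for a bin is the spike count summed over the
included trials (responded CS+ trials for cue analyses). Its null expectation
is λ = r̂ · w · n, with r̂ the baseline rate (total baseline spikes over all
included trials divided by total baseline time), w the bin width and n the
trial count. A unit is *excited* if any bin strictly exceeds the smallest
integer whose Poisson(λ) CDF reaches 0.999, and *inhibited* if any bin falls
strictly below the largest integer whose CDF is at most 0.01. The laxer
inhibition level compensates the floor effect of low-rate units; when even a
zero count is not improbable enough (P(X = 0) > 0.01), inhibition is
undetectable and the unit is flagged. The rule is deliberately any-one-bin —
no multiple-comparison correction across bins — so its family-wise null rate
over the ten 50-ms cue bins is 1 − 0.999¹⁰ ≈ 1%, which the calibration tests
verify by simulation.

Two windows are built in: cue (50-ms bins on [0, 0.5) s from CS+ onset,
excitation at 99.9%, inhibition at 99%) and consumption (400-ms bins after
the rewarded entry, both directions at 99%). The nominal 3-s consumption
window is not divisible by 400 ms; we use the seven full bins covering
[0, 2.8) s and drop the 200-ms remainder. Note that the exact null
"none" rate of the consumption rule is (1 − p_exc − p_inh)⁷ ≈ 0.87, not
1 − α per side: with seven chances per direction, roughly one unmodulated
unit in eight picks up a spurious label. The tests assert this exact
calibration rather than a rounder number. For infusion sessions,
classification uses the pre-injection epoch only, so drug effects cannot
leak into the unit labels.

One-sided bounds were chosen over two-sided 99% intervals (an open reading
of "below the 99% confidence interval"): the inhibition level is exposed as
a parameter, so the 0.5% two-sided reading is one argument away.

## auROC maps and PSTHs

For each bin, auROC compares the per-trial bin counts with a pooled baseline
sample — per-trial counts in bin-width bins tiling the 1-s pre-cue baseline —
using the Mann–Whitney identity with half credit for ties (essential for
integer counts). The pairing between all bin values and all pooled baseline
values is our resolution of an underspecified detail; it maximizes the
baseline sample without leaving the trial set. auROC is antisymmetric under
swapping sides and invariant to monotone transforms, and the implementation
is fuzz-tested against a trapezoid integration of the explicitly constructed
ROC curve.

The cue map uses 10-ms bins on [−1, 1.5] s with a 200-ms sliding mean; the
consumption map 200-ms bins on [−1, 5] s around the rewarded entry with an
800-ms sliding mean. Smoothing is a centered moving average truncated at the
track edges (no padding), and is *display only*: the raw and smoothed tracks
live side by side in the returned object, and every statistic downstream
consumes the raw track. The consumption map's baseline is described in the
source only as "the pre-cue epoch"; we use the same 1-s pre-cue second tiled
at the map's bin width and expose the window as a parameter.

With 10-ms bins at single-unit rates the counts are sparse, so per-bin auROC
saturates well below 1 even for strong gains — heat-map values near 0.6–0.7
already indicate robust excitation.

z-scored PSTHs use the 10-s baseline: each unit's per-bin trial-mean count is
z-scored by the mean and SD of bin-width-matched baseline counts; units with
zero baseline variance have no defined z and are excluded with their count
reported. The 100–300 ms response magnitude is exposed both as this z and as
the raw mean count, since the summary used for population comparisons could
be read either way.

## The vigor GLM and its tests

The count model is Poisson regression with log link of the spike count in
[0.05, 0.5) s post-cue — a window deliberately distinct from the 100–300 ms
magnitude window; both constants are named arguments — on three approach-vigor
covariates: distance from the receptacle at cue onset, latency to maximum
speed, and average approach speed, entered raw (a standardization flag is
recorded in the fit when used). Trials are pooled across a population's
units without per-unit intercepts, matching the population-level reading of
the analysis; a per-unit-offset variant exists for sensitivity checks. The
model is pure Poisson maximum likelihood: an additive error term on the log
scale has no role in a Poisson likelihood, so none is estimated.

Two populations are compared by the equivalence F statistic
F = [(SSt − SSp)/((m+1)(k−1))] / (SSp/DFp) on residual deviances (squared
Pearson residuals are available as an option), with numerator df
(m+1)(k−1) and denominator df DFp. Because the separate fits nest the
combined fit, SSt ≥ SSp and F ≥ 0 always. Under a true single population the
test holds its 5% level, which the suite verifies over 1000 random splits.

Adequacy of a single-population fit is assessed by the split-half bootstrap:
1000 seeded permutations, each splitting the trials 50/50 at random, fitting
both halves, and computing the F-test p against the full fit; an adequate
fit passes (p > 0.05) on about 95% of permutations. A caveat the tests make
explicit: because random splits are exchangeable, this procedure has no
power against heterogeneity that is symmetric under splitting — a population
stitched from two coefficient regimes still passes, while the equivalence
test applied to the *structured* split rejects it overwhelmingly. The
bootstrap checks calibration of the model family, not homogeneity of the
population.

Cross-population prediction applies one population's coefficients to
another's covariates (modeled count = exp(β₀ + Σβᵢxᵢ)) and compares modeled
with actual counts by rank-sum test. The next-trial reinforcement check is a
logistic regression of the trial-(t+1) response flag on the consumption-epoch
count (1–3 s after the rewarded entry) of trial t, with a Wald test on the
slope and an explicit flag for complete separation. Baseline-rate stability
across an infusion is tested by regressing post- on pre-injection rates
across units and asking whether the 95% CI of the slope excludes 1.

## Tracking

The locomotor index of a frame summarizes movement over the 9-frame
(~300 ms) window centered on it. The verbatim definition — SD of the
frame-to-frame position differences — is identically zero for uniform
motion, contradicting the accompanying gloss that the LI represents speed;
we therefore default to the pooled SD of the x and y coordinates over the
window, which is proportional to speed for uniform motion, and ship the
literal reading as a tagged alternative (`diff-sd`). Every derived series
records which method produced it. Both are translation- and
rotation-invariant and homogeneous of degree one in displacement.

The still/moving threshold fits a two-component Gaussian mixture (unequal
variances) to the defined LI values and places the threshold at the mixture
density's interior minimum between the component means, found by a dense
grid scan; the midpoint of means is the fallback when no interior minimum
exists, and components whose means are closer than the smaller component SD
raise a unimodality flag instead of a threshold. We use `mclust` for the
mixture fit: its model-based hierarchical initialization is deterministic,
which we prefer to random-restart EM because thresholds then do not depend
on a fitting seed. Movement-onset latency is the time from cue onset to the
first following frame (nearest-neighbor mapping of event times to frames)
whose LI exceeds the threshold.

Vigor covariates per trial: Euclidean distance from the receptacle at the
cue-onset frame; latency to the frame of maximum speed and mean speed, both
over [cue onset, receptacle entry) for responded trials and over the cue
window otherwise, with speed = per-frame displacement × fps. Gaps up to 3
frames are linearly interpolated; longer gaps make the trial's covariates
absent. Positions are in cm (a pixel-to-cm scale is applied upstream of the
package's inputs).

## The synthetic-session generator

The generator exists so that every stage above can be exercised against
known ground truth. Its defaults encode the study conditions: 5-s cues,
truncated-exponential ITIs as above, Bernoulli(0.5) cue identity; free-fed
behavior starts at a CS+ response probability of 0.9 and declines by 1% per
minute (reaching roughly a third of its initial value over a 2-h session),
while food-restricted behavior responds at 0.95 with no decline and responds
more to the CS− (0.35 vs 0.15); response latencies are truncated log-normal
on (0, 5] s, with shorter latencies under restriction so that restricted
approaches are faster. Where the study describes no value (latency shape,
CS− response levels, consumption durations), we chose once what a
practitioner would call realistic for this task and did not revisit it.

Spike trains are piecewise-inhomogeneous Poisson: baseline rate everywhere
except (a) the cue-gain window ([0.1, 0.3) s by default) of responded CS+
trials, where the expected count is exp(β₀ + β₁x₁ + β₂x₂ + β₃x₃) with the
trial's vigor covariates — the generative mirror of the fitted GLM — and
(b) the 3-s consumption window for consumption-modulated units. When a
rewarded entry falls inside the cue-gain window, the cue window takes
priority and consumption modulation starts at its end, so a trial's expected
cue-window count always matches the log-linear model. The drug toggle
multiplies the cue gain's excess over baseline by an attenuation factor for
exposed units, ramping linearly over the 12-min infusion; an analogous
factor attenuates the behavioral CS+ response probability.

What the generator does *not* emulate: refractory periods and bursting
(trains are exactly Poisson, so the unit-QC refractory criterion is
informative only for recorded data), licking microstructure, waveform
amplitudes beyond a metadata field, drift, and correlated noise across
units. Passing calibration tests therefore demonstrates correctness of the
statistics under the stated model, not robustness to every property of real
recordings.

Randomness follows R convention: session-level generators take a `seed` and
seed the RNG once; the same seed reproduces a session bit-exactly.

## Numerical conventions and problem sizes

Bin indices use an epsilon (1e−9) guard so that aligned-time arithmetic
lands on the half-open convention; Poisson bounds are computed through
`qpois` with an explicit largest-x-below-level correction for the lower
bound and are test-verified against term-by-term CDF summation; intercept-only
GLMs recover log(mean) to machine precision; degenerate inputs (empty trial
sets, silent units, zero baseline variance, complete separation, unimodal LI
distributions) return flagged results or errors rather than numbers.

The test suite's simulation sizes — e.g. 1000 units for classification
calibration, 1000 replicates for the F-test level and the logistic null,
100 replicates of 2000 trials for coefficient coverage, 200 units for the
auROC null — were chosen as the smallest sizes at which the Monte-Carlo
error of each check is comfortably below the margin being asserted.

## Known limitations

The package analyzes one session at a time; multi-session aggregation is a
thin layer left to the analysis scripts. The ANOVAs used on the original
cohort's behavior are out of scope (base R provides them); only the
rank-test/Holm–Šidák path used for pre/post epochs is built in. The
equivalence F test inherits the usual caveat of deviance-based F
approximations at small trial counts, and the adequacy bootstrap's
blindness to split-exchangeable heterogeneity is documented above by
construction rather than patched.
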