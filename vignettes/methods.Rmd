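---
title: "Methods: cue ensembles, representational similarity, and SWR coactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cue ensembles, representational similarity, and SWR coactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippens)
```

## The task and the analyses

The package analyzes electrophysiology sessions from a sensory-
preconditioning paradigm. Two auditory cues (X1, X2) are first paired with
two visual cues (Y1, Y2); the visual cues are then paired with outcomes
(Z1 for set 1, Z2 for set 2, only set 1 rewarded); finally the auditory
cues are presented alone. Reward seeking to X1 over X2 indicates an
*inferred* X→Z association that was never experienced directly. The
analyses ask how hippocampal unit activity supports that inference: which
neurons form cue-specific ensembles, whether activity during X resembles
the representation of the associated Y (a prospective code), whether X and
Y neurons interact at millisecond timescales, and whether X/Y/Z ensembles
co-fire within sharp-wave ripples (SWRs) during rest.

Because the recordings the analyses were designed for are not publicly
deposited, the package ships a synthetic-session generator with planted
ground truth. Every analysis stage is exercised and validated against what
was planted; all quantitative claims in the test suite and acceptance
script are computed from those synthetic study conditions, and say nothing
about any real dataset.

## Decision-point filtering

Trials are censored at the "decision point": the latest time at which the
animal's speed is below 5 cm/s before its first entry into the outcome
area on that trial. This removes epochs at or approaching the dispenser,
so cue-period activity is not confounded by place. Granularity is tied to
the 25 Hz position sampling. Two edge cases are explicit: if the animal
never enters the area, the whole trial is kept (`"no_entry"`); if it
enters without ever slowing below threshold first, the trial is excluded
from filtered analyses and counted (`"excluded"`). A trial that *starts*
inside the area (outcome windows entered from the preceding cue's dwell)
has no visit of its own — the filter censors approach, not carried-over
occupancy — so such trials are kept whole. This matters for outcome-cue
(Zn) windows, whose dispenser activity is a real signal of interest.

## Binned rates and the cue GLM

Spike counts in 100-ms bins spanning each trial window are converted to Hz
and Z-scored per unit across all decision-point-included bins of the
session. The normalization window is a design choice (the binning and the
filter are fixed; what to normalize over is open): using all included bins
of the session keeps trials comparable within and across days and makes
the trial-averaged response directly interpretable in SD units. Units with
zero rate variance are flagged and excluded from correlation-based
analyses downstream.

Each unit's per-trial average Z rate is regressed on six cue indicators
plus the standardized mean running speed of the trial (OLS; the response
is already a Z-scored rate, so a Poisson link would be wrong). Each trial
presents exactly one cue, so the design uses one indicator per cue and no
intercept — with an intercept the six dummies are rank deficient. A cue
with fewer than two included trials aborts with the cue named. The GLM is
fit pooled across days by default with a `days` argument for per-day fits
(the per-day variant mirrors how an example recording day would be shown;
pooling is the default because the synthetic sessions are stationary).

A unit joins the ensemble of a cue when its weight is positive and exceeds
the cross-unit mean for that cue by 2 SD. Units in more than one ensemble
are retained for summaries but excluded from SWR triplet construction,
which requires non-overlapping representations.

## Performance-modulation GLM

For each 100-ms bin in a ±15 s peristimulus window around auditory-cue
onset (a 30-s span), each unit's Z rate across inference-test trials is
regressed on the trial's correctness (1/0) with standardized speed and cue
set as covariates; the per-bin average weight across units is tested
against zero with a one-sample t-test. The binned design matrix is
factored out (`performance_glm_design()`) so null calibrations can refit
hundreds of label shuffles at negligible cost.

## Representational similarity

Population vectors are per-condition, per-unit means of included Z-rate
bins, averaged within trial first and then across trials with equal
weight. The cross-stage RSM correlates test-stage vectors (auditory cues
at inference, split by correctness, decision-point filtered, optionally
with SWR-containing bins excluded) against training-stage vectors (visual
or outcome cues at conditioning). Rows and columns index different
condition sets, so the matrix is not symmetric. The within-minus-between
statistic is the mean correlation over associated cells (X1–Y1, X2–Y2)
minus the mean over non-associated cells.

Group inference uses two routes: a one-sided Wilcoxon signed-rank test
across recording days (exact for n ≤ 25 without ties), and a permutation
test that relabels the test-stage conditions and recomputes the group mean
each iteration, with the add-one rule p = (1 + #{null ≥ observed}) /
(1 + n_perm) so p is never zero. With only two auditory cues a single
shared permutation across days would give a two-atom null, useless at
α = 0.05; the scheme therefore draws an independent label permutation per
day on each iteration, which is a valid exchangeability argument under the
null and yields a calibrated test (verified at rejection rate 0.03–0.07 on
unstructured data). Correct and incorrect trials are never mixed.

Model-RSM regression vectorizes the RSM, Z-scores the cells, and fits
named model matrices jointly; correlations are Fisher-transformed first by
default (variance stabilization; exposed as a flag, and off by default in
the within-minus-between statistic for the neuron pipeline, where the
transform's effect was verified immaterial on the synthetic conditions).
Collinear models abort with the condition number reported.

## Spike timing

Cross-correlograms and spike-triggered averages (STAs) use 1-ms bins over
±100 ms around each trigger spike, restricted to cue windows so pairs
never straddle trials. Joint probability per bin is the count divided by
the number of *contributing* triggers for that bin: triggers whose bin
would poke outside the cue window are dropped from that bin's normalizer
(truncated windows; this avoids edge bias and is our convention — the
procedure is otherwise silent on edges). The correlogram's change measure
subtracts the mean joint probability over the 50 ms before the trigger.

The STA Z-scores the per-bin rate across the 200 bins of the same STA;
the alternative reference (the target's session rate over the cue windows
with a Poisson-scaled SD) is behind a flag, and the after-minus-before
asymmetry statistic is robust to the choice on synthetic data. Pairs whose
target fires fewer than 20 spikes across all trigger windows are excluded
with an explicit record. A 5-ms moving average is provided for display
only and never feeds statistics. The asymmetry (mean Z after minus before
the trigger) is aggregated across pairs with the BCa bootstrap.

## SWR detection and coactivation

Detection subtracts a reference channel (common-mode removal), band-pass
filters 135–250 Hz, and thresholds the RMS envelope at 7 SD above the
background mean, computed over immobility (< 1.5 cm/s) only. The
procedure fixes only the 7-SD core threshold; the rest are field-standard
conventions exposed in the arguments: edges extended to 2-SD crossings,
minimum duration 20 ms, merge gap 10 ms, 10-ms RMS window. Detection is
scale-invariant by construction (thresholds in SD units). Detected edges
sit where the envelope crosses 2 SD, so they trim the tails of the
synthetic Hann-windowed bursts to roughly two thirds of the planted
duration; analyses that score planted participation therefore run on the
ground-truth event set, which the `swr_set` container carries as a
first-class `source`.

Coactivation of a unit tuple is scored per epoch (early days 1–4 vs late
days 5–8) as p̂ = (n/N)/f̄: the fraction of the epoch's SWRs in which every
member fired, normalized by the mean of the members' session mean rates
over that epoch's days (whole-day rates; the rest-only variant is a flag).
Tuples never coactive in any SWR are excluded, as are tuples with a
zero-rate member. The early-to-late change p̂_diff is summarized per set
with a BCa bootstrap and across the design with a two-way set × day ANOVA
plus Tukey's HSD. Doublet variants score X–Z pairs regardless of Y
activity or only in SWRs with no Y-ensemble spike (same denominator N, so
the "absence" count can never exceed the unconditional one). The X-shuffle
control reassigns which SWRs contain X spikes within each epoch
(participation counts, hence rates, preserved exactly), holding Z fixed.
First-spike order takes each unit's first spike per ripple and tests the
fraction of pairs with median (Z − X) below zero against 0.5 with a
two-sided binomial test; ties are dropped and counted, and set-level tests
are compared at α = 0.025 when both sets are tested.

## The synthetic generator

Spike trains are inhomogeneous Poisson, generated by thinning at rate
baseline × (1 + gain during the preferred cue) + speed coupling, with
multiplicative performance or prospective gains on correct inference
trials. Baseline rates default to lognormal (median 1.5 Hz, sdlog 0.5,
mostly 0.5–5 Hz) — a field convention, not a calibrated value, since
per-unit rate distributions are not specified anywhere. Tuned units are
disjoint across cues by construction. Millisecond structure is planted two
ways: echo spikes at a fixed lag after trigger spikes during auditory
cues, and SWR participation spikes injected at a common uniform time
inside the event with optional per-unit offsets, which makes first-spike
order controllable. The position model is a knot-based path: roaming at
8–13 cm/s between waypoints, immobile rest blocks with sub-0.3 cm/s
jitter, and for visiting trials a staging approach, a sub-threshold dip at
the planted decision point, and a 6.5 cm/s run to the dispenser — so the
planted decision point is recoverable to within one position sample.
Cue durations (10 s auditory, 8 s visual, 10 s outcome), 26 inference
trials/day, 25 Hz tracking, and the 135–250 Hz band match the recorded
task; inter-trial intervals and rest blocks are shortened to desk scale
(the real task uses ≥ 30 s ITIs and longer rest), which inflates trial
density but changes no per-trial statistic. LFP is synthesized at 1 kHz —
sufficient for a 250 Hz band — as pink noise with a shared common-mode
component between detection and reference channels, plus Hann-windowed
190 Hz bursts at a configurable multiple of the ripple-band background
RMS inside each true event.

What the generator does not emulate: refractoriness and bursting,
place-field spatial tuning, theta rhythmicity, behavioral state
transitions beyond mobile/immobile, lick dynamics, and real SWR spike
content (participants are injected, not emergent). Passing tests
demonstrate that the estimators recover what was planted under Poisson
variability at realistic rates and counts — not that they are robust to
every failure mode of real recordings.

## Problem sizes and numerical choices

The test suite and acceptance script fix their simulation scales as
package choices: ensemble recovery on 100 units with 8 planted per cue at
gain 5 and 50 trials per cue (a 100-seed bank in the tests, 40 in the
acceptance script); lag recovery over 60 planted pairs; SWR detection over
five sessions (~400 planted events) at SNR 10; 500 RSA calibration
simulations at n_perm = 1000 with 18 synthetic days; 100 label shuffles
for the performance GLM; 8-day coactivation schedules with 10 triplets per
set at participation 0.02 → 0.10 (set 1) vs flat (set 2). Seeds derive
from a single global seed via a fixed affine map, so every stage is
bit-reproducible and independently re-runnable. Intervals are half-open
[start, end); times are seconds on one session clock; spike times are
quantized to 0.1 ms. Ties in first-spike order are dropped; degenerate
bootstrap distributions (zero variance) return a flagged point-mass CI;
a flat reference-subtracted LFP segment yields no events rather than NaN
thresholds.

## Known limitations

Ensemble thresholds assume enough units (< 10 warns) for a stable
cross-unit SD. The permutation scheme treats days as exchangeable units
and ignores across-day dependence of the same units. The ANOVA on p̂
values follows the original two-way design without residual-normality
checks; a permutation-F alternative would be the robust choice and the
bootstrap CIs are reported alongside for that reason. The
speed covariate enters the cue GLM per trial (not per bin), so fast
within-trial speed fluctuations are not modeled. Detection precision and
recall are measured against planted bursts in stationary pink noise; real
LFP artifacts (chewing, movement onset) are only approximated by the
common-mode component.
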