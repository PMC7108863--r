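---
title: "Simulating and analysing visual-feedback modulation of wrist stretch reflexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing visual-feedback modulation of wrist stretch reflexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package computes

`reflexvf` implements, end to end, the trial-level analysis used to ask
whether the long-latency stretch reflex (LL, the transcortically mediated
EMG response 50–100 ms after a muscle stretch) is tuned by the quality of
*visual* information about the hand — a multimodal contribution to what is
usually treated as a proprioceptive loop. The experimental logic contrasts
manipulations that degrade the hand-state estimate (rotating the cursor,
mirror-reversing it, or switching it off during movement) with a
manipulation that only remaps the target-to-action rule (the anti-reaction
task), leaving hand-state estimation untouched. The signature looked for
is: LL attenuation and endpoint-scatter inflation under the first family,
no LL change under the second, even though the second abolishes the rapid
visuomotor response to target jumps.

Because the original recordings are human data, the package ships a
synthetic cohort generator that reproduces the four experimental designs
and the statistical structure the analysis assumes, so every stage — from
raw traces to bootstrap confidence intervals — is exercisable and testable
in code.

# The synthetic cohort generator

## Kinematics

Each trial is a wrist flexion from −22.5° to a target (22.5° in most
designs; 45° in the graded-elimination design), nominally 750 ms long. The
kinematic shape is a **minimum-jerk profile**; the protocol constrains only
duration and endpoints, and minimum jerk is the standard smooth template
for point-to-point movements. Trial-to-trial variability enters through

* the movement endpoint, drawn from `Normal(target, endpoint_sd(condition))`;
* the movement duration, `Normal(0.75 s, 0.03 s)` (truncated to ±40%), so
  duration screening has honest variance to work with;
* white measurement noise on the recorded angle (`kin_noise_sd`, default
  0.01°, the scale of encoder quantization). This term matters more than
  it looks: double differentiation amplifies it into per-sample
  acceleration variability, which is exactly what makes the successive
  t-test on acceleration ensembles behave like a proper hypothesis test
  instead of latching onto smooth finite-sample mean differences.

Each simulated trial spans 1.4 s at 500 Hz with movement onset at 0.2 s;
this leaves a pre-movement baseline, room for the +300 ms post-perturbation
analysis window, and the 300 ms of quiet needed by the movement-end rule.

## The perturbation and the wrist plant

The mechanical perturbation (MP) is a half-sine torque pulse, 2.0 Nm peak
and 50 ms duration, triggered the first time the angle crosses a
design-specific threshold (3.75° in the rotation experiment, 0° in the
mirror/jump designs, +50.6° of flexion from the start in the elimination
design). Its kinematic consequence is the response of a second-order
rotational plant, inertia `I = 0.005` kg·m² and damping
`b = 0.05` Nm·s/rad, integrated with RK4 at the kinematic rate. The plant
deliberately omits stiffness and reflexive torque feedback — the deflection
therefore does not return to the pre-perturbation path. That is harmless
here: every perturbed-trial measure is an EMG window mean or the
pre-perturbation velocity, and endpoint statistics use unperturbed trials
only. Because the plant is linear and time-invariant the response is
computed once and cached.

## Surface EMG

Raw EMG is modelled as a nonnegative **envelope multiplied by a
unit-variance broadband carrier** (plus additive sensor noise). This is the
simplest construction for which the field's preprocessing — 50 Hz
high-pass, rectification — recovers the envelope up to a multiplicative
constant, and for which isometric normalization cancels that constant: the
1 Nm reference recording is built from the same carrier model. A
deterministic mode (carrier ≡ 1, all noise off) backs the package's
exactness tests, e.g. that halving the LL gain exactly halves the
background-subtracted LL window mean.

The envelope is a sum of:

* a baseline level `bga_mean` (0.05 normalized units) in both muscles;
* a movement-related burst in the agonist (flexor), gain 0.25 times the
  normalized speed profile;
* on perturbed trials, in the stretched muscle: a short-latency Gaussian
  bump (centre 40 ms after MP onset, SD 5 ms, gain 0.35), a long-latency
  bump (centre 75 ms, SD 12 ms, gain 0.55 × the condition multiplier), and
  a voluntary bump (centre 140 ms, SD 25 ms, gain 0.30). The centres and
  widths are chosen so the bumps fall inside the standard scoring windows
  (background −50–0 ms, short-latency 30–50 ms, long-latency 50–100 ms);
* on target-jump trials, a corrective burst in the task-appropriate muscle
  with a **hard onset**: a gamma-shaped rise `(t−t₀)² e^{−(t−t₀)/τ}`
  (τ = 15 ms, peak 2τ after onset, gain 0.6). A Gaussian bump has no true
  onset — its tail is statistically separable arbitrarily early once
  ensembles are large — so a burst whose latency is itself an analysis
  target must start abruptly.

Trial-to-trial burst gains vary with CV 0.2; participants carry log-normal
random effects on overall EMG scale (SD 0.2, cancelled by normalization),
LL gain (SD 0.15) and endpoint variability (SD 0.15).

## Condition effects and their coupling

The per-condition LL gain multipliers encode the effect pattern under
study: rotations (1, 1, 0.8, 0.7, 0.6) across 0–180°; mirror and
cursor-elimination effects additive in the 2 × 2 design (1, 0.85, 0.8,
0.65); a monotone decline over elimination durations (1, 0.9, 0.8, 0.7);
and, in the jump experiment, no Pro/Anti difference but a Mirror
attenuation (1, 1, 1, 0.7). Endpoint SD is linked to the multiplier
through a negative linear map, `sd = 1.5° + 3.75°·(1 − multiplier)`, so the
reflex-gain versus endpoint-variability correlation is recoverable by
construction; the map (and its slope's sign) is configurable.

Task latencies for the corrective response are 120 ms (Pro and Normal),
180 ms (Anti) and 230 ms (Mirror); measurable acceleration divergence lags
EMG onset by an 80 ms electromechanical delay. Participant latency offsets
are drawn uniformly on [0, 25 ms] and re-anchored so the cohort minimum
equals the configured task latency — the cohort-minimum is what the
window rule consumes, so it is a design quantity, not a sample statistic.

## Designs

`experiment_design()` returns the per-block trial composition of each
experiment exactly as published: rotation blocks of 20 trials (5 baseline,
5 perturbed, 5+5 cursor-shift catch trials) × 5 rotations × 5 repetitions;
the 40-trial mirror/hide blocks (8 perturbed standard-target trials per
block) × 6 block pairs; the 80-trial elimination blocks × 6; and the
60-trial jump blocks (12 baseline, 12 perturbed, 18+18 jumps) × 2 per
block type and session. Cursor-shift catch trials are metadata-only by
default (no modelled correction); a flag enables a modelled compensatory
response at 200 ms for reaction-time reconstructions.

# The analysis pipeline

## Signal processing

All filtering is fourth-order Butterworth applied forward and backward
(zero phase). The implementation pads by odd reflection (at least three
filter lengths and three cutoff periods) and initializes each causal pass
at its steady state, so constants pass exactly and edge transients stay at
machine-precision level. Velocity is the first difference scaled by the
sampling rate and then low-passed at 40 Hz — difference first, filter
second — and acceleration repeats the rule on filtered velocity. EMG is
high-passed at 50 Hz and rectified (rEMG); a 100 Hz zero-phase low-pass,
clipped at zero, gives the envelope used for visualization and onset
detection. Window statistics are always computed on rEMG, not the
envelope.

Movement bounds: start is the first sample with |velocity| above 5% of the
signed flexion-direction peak; end is the first post-peak sample below
that threshold that stays below it for ⌈0.3·fs⌉ consecutive samples; the
first and last 50 ms are excluded from the search. On a noiseless
minimum-jerk 45° movement this rule clips the nominal 750 ms duration to
≈ 661 ms and the endpoint to ≈ 22.43° — the tests freeze these closed-form
values. Endpoint SD uses the n−1 denominator and, by default, only
standard-target unperturbed trials.

Analysis windows are half-open `[lo, hi)` so the 50 ms boundary sample is
counted once, in the long-latency window. The isometric reference is the
rectified mean of the 1 Nm hold **without** high-pass filtering: a static
calibration epoch carries no movement artifact, and a constant reference
must normalize to its own amplitude (a high-pass would annihilate it).

## Latency detection and the visuomotor window

Response onsets come from one-tailed successive **Welch** t-tests between
forward- and backward-jump ensembles at every post-event sample, onset
being the first run of at least 10 (acceleration, 500 Hz) or 50 (EMG
envelope, 2000 Hz) consecutive p-values below 0.05, searched from the
event to +400 ms (the correction deadline). Welch rather than pooled
variance because the two ensembles need not have equal trial counts; the
tail direction is an explicit argument derived from task metadata, never
inferred from the data. The visuomotor analysis window is
`[shortest Pro EMG latency − 5 ms, shortest Anti latency − 5 ms]`, which
maps cohort latencies of 120/180 ms onto the canonical 115–175 ms window;
the 5 ms margin is a reconstruction, stated as such. v-EMG window means
are not background-subtracted by default (a flag provides the alternative
reading).

## Screening

Trial screening is single pass, computed on the unmutated condition cell:
perturbed and jump trials are excluded when background activity, the LL
component, or a v-EMG mean deviates from the cell median by more than two
cell SDs (n−1, candidate included); unperturbed trials when duration or
endpoint deviates from the cell median by more than three times the raw
median absolute deviation (no 1.4826 consistency scaling — the rule is
"three times the MAD" literally). Participants whose mean background
activity in any rotation condition leaves ±25% of their own
across-condition average are excluded wholesale (co-contraction scales
reflex amplitudes); this rule is applied in the rotation experiment by
default and is switchable elsewhere. Cells smaller than three trials skip
screening with a warning, and losing more than half a cell triggers a loud
warning.

## Inference

The one-way repeated-measures ANOVA is the classical univariate
decomposition: subject effect removed, condition tested against the
subject-by-condition residual, partial η² = SS_cond/(SS_cond+SS_error).
Published F-statistics in this literature are sometimes labelled with
(k−1, n−1) degrees of freedom; the package computes the standard
(k−1, (k−1)(n−1)) error df for the p-value and reports both labels. No
sphericity correction is applied (matching the reporting convention
emulated). Tukey-HSD post hocs use the studentized range on the RM error
term; two-way designs test each effect against its own subject-by-effect
interaction. Paired t-tests report both Cohen's d variants — `dz`
(mean difference / SD of differences) and `d_av` (mean difference /
average condition SD) — with `d_av` as default, because published d values
of the kind emulated here are inconsistent with `dz = t/√n`.

The reflex-gain versus endpoint-variability correlation is computed per
participant across conditions (Pearson, on the values themselves; a flag
switches to baseline-subtracted changes), and the group statistic is the
plain arithmetic mean of the coefficients — no Fisher-z averaging — with a
percentile bootstrap over participants (B = 1000, seeded) for its
confidence interval; significance means the CI excludes zero.

# Problem sizes and what the tests show

The test-suite's replication study uses the rotation design at n = 18
participants with 4 block repetitions (20 perturbed and 20 unperturbed
trials per condition) over 100 seeded replicates, requiring the LL ANOVA
to be significant with the baseline-involving Tukey pattern
{0° vs ≥ 90°, not 0° vs 45°} and the correlation CI to exclude zero in at
least 90% of replicates. The dissociation study runs nine seeded cohorts
of the jump design at its published size (n = 8, 480 trials each): the
flexor Δv-EMG must separate Pro from Anti in every replicate, while the
LL Pro-vs-Anti contrast is a true null by construction — its p-values are
uniform, so the check is on their median, not on a single draw. One
additional cohort exercises latency detection end to end.

Passing these tests shows that the pipeline recovers known effects at
realistic sizes and that every computational rule matches an independent
oracle; it does not validate the biology. The generator does not model
learning or adaptation across blocks, co-contraction strategies, plant
stiffness or reflexive torque closure, state estimation itself, or real
EMG spectra (the carrier is white; real surface EMG is band-limited and
its bursts are not strictly amplitude-modulated noise). Conclusions about
real recordings rest on the correctness of the rules, which is what is
tested, not on the realism of every generative detail.
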