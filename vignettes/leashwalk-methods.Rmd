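---
title: "Methods: from leash-tension traces to personality-behavior models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leash-tension traces to personality-behavior models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leashwalk)
```

## The measurement problem

When a dog is walked on a leash, the tension in the leash carries a
behavioral signal: who is pulling, how hard, and how often. A leash
tension meter inserted between handle and leash records force (kgf) at
10 Hz over a 0–100 kgf range with 100 g resolution, alongside a
direction channel derived from a 3-axis accelerometer and reduced to a
signed scalar in [-1, 1] (positive = dog-ward pull, negative =
handler-ward). Each recording starts with a protocol: the device is
held vertically for 10 s (a calibration reference) and the handler then
performs three deliberate 3 s pulls that synchronize the force record
with the video. `leashwalk` turns such recordings, together with coded
behavioral observations and handler questionnaires, into walk-level
metrics and association models linking handler personality to walking
behavior.

## Signal preparation

`find_sync_pulses()` locates the three synchronization pulls as maximal
runs with force at or above `min_force` (default 5 kgf) lasting at
least `min_duration` (default 2 s; the protocol asks for 3 s holds, and
the margin tolerates imprecise counting). The walk segment starts a
configurable guard gap (default 1 s) after the last pull. The pull
amplitude is not standardized by the protocol, so `min_force` is a
parameter rather than a constant; anything clearly above one-handed
carrying force and below a realistic pull works, and a recording in
which fewer or more than three runs qualify is rejected with the
candidate list attached for inspection.

The walk segment is then linearly interpolated onto an even
`t0 + k/rate` grid (10 Hz by default; recordings can carry uneven
timestamps), **tarred** by subtracting the trace minimum — which equals
the unloaded baseline — and **smoothed**. The smoothing filter is a
centered moving average with edge truncation, default window 3 samples
(0.3 s at 10 Hz), `window = 1` disabling it. A moving average is the
simplest filter consistent with gradient-based event splitting; the
window is deliberately short so genuine twin peaks inside one burst are
not merged away. We tare before smoothing; the order is configurable by
calling the steps directly, and for a min-subtraction followed by a
linear filter the difference is a constant offset at the edges only.
The median of the 10 s calibration hold is available as a device-offset
diagnostic, but taring by the minimum is authoritative.

## Pull events and walk metrics

The detection threshold is 0.1% of the dog's body-weight force
(`compute_threshold()`): 0.02 kgf for a 20 kg dog. An event starts at
the first sample strictly above the threshold following a sample at or
below it, and ends at the first sample where the filtered tension
either drops strictly below the threshold or the discrete gradient
flips from negative to positive — the signature of a new pull starting
inside the same burst, in which case that sample opens the next event
if it is still above threshold. Three numeric conventions are applied
consistently: comparisons at the threshold extend the event (ties are
not crossings), a zero gradient is not a sign change (the flip must go
strictly negative then strictly positive), and events still open at the
final sample are closed there and flagged truncated. Peaks are read
from the smoothed series the detector ran on, for internal consistency.

Each event is attributed to the **dog**, the **handler**, or **both**
from the direction channel at the sample immediately before onset, with
a dead-band margin (default 0.1) around zero mapping ambiguous values
to "both". An event starting at the very first sample has no prior
sample; its own first sample is used, with a warning.

`summarize_walk()` computes the eight walk outcomes: NT/DT/HT max and
mean (net, dog-attributed, handler-attributed peak tensions, in kgf)
and DPF/HPF (dog and handler pulling frequencies, events per second).
Mean tensions average event peak forces above threshold; a samplewise
trace mean is also reported as an auxiliary diagnostic because "mean
tension throughout the walk" admits both readings. Events attributed to
"both" count toward the net metrics and the total event count but not
toward the dog/handler-specific tensions or frequencies, since the
frequencies are defined per initiator; this choice is configurable in
spirit by lowering the margin to zero, which removes the "both"
category for any noisy direction channel.

## Ethogram summaries and coder agreement

Behavior logs follow the point/state event model: point events are
counted, state events are timed intervals. The shipped catalog has nine
canine behaviors, seven human verbal cues and three human body-language
behaviors. Point behaviors are summarised as events per second, state
behaviors as percent of walk time with overlapping same-behavior
intervals merged first; grouped totals sum the verbal-cue and
body-language member rates.

Agreement between two codings of the same walk is quantified with
Cohen's kappa. Kappa needs categorical sequences, and continuous
records do not provide them directly, so `bin_timeline()` discretizes a
log onto fixed-width bins (default 1 s) and labels each bin with the
most present behavior (covered time for states, count for points),
"none" when nothing is present, ties broken by catalog order. The bin
width is a reported parameter of any kappa value; 1 s matches the
sampling practice of continuous coding without inflating agreement by
overly long bins. When both sequences are constant on the same label
the chance-agreement term degenerates to 1; we return kappa = 1 there,
documenting perfect agreement rather than an undefined value.

## Questionnaire factors and personality profiles

The 13-item exit questionnaire is scored into two mean factors, handler
satisfaction (H) and perception of the dog (D), after reflecting
negatively worded items (`6 - x` on the 5-point scale). The instrument
description fixes the two-factor structure but not the item-level
assignment, so the shipped mapping (`default_factor_specs()`) is an
explicit assumption derived from item wording and is configurable;
both factors' internal consistency can be checked with
`cronbach_alpha()`, which implements the variance decomposition
directly. Personality enters as NEO-FFI domain scores (0–48);
`validate_personality()` rejects out-of-range values and flags scores
at or beyond the observed cohort envelope [3, 48] without rejecting
them, because an unusual profile is information, not an error.

## Association models

Each walk outcome is transformed to meet residual normality — tension
metrics on the log10 scale, behavior rates and time fractions by power
laws with exponents between 0.3 and 10 depending on the outcome — and
modelled with linear mixed models. Volunteer and dog identities enter
as **crossed** random intercepts (the same dog is walked by several
volunteers and vice versa; nesting would misstate that design).
Estimation is by maximum likelihood so BIC is comparable across
fixed-effect sets; fixed-effect p-values are large-sample Wald z tests,
a reasonable choice at several hundred walks and documented as such.

Model building mirrors the screening-then-elimination protocol common
in observational behavior studies: each candidate predictor is first
screened in a single-predictor linear model and kept when p < 0.2; the
five personality scores and the dog's behavioral level are forced into
the model regardless of their screening p. Backward elimination then
repeatedly removes the non-forced predictor with the largest p at or
above 0.05, recording BIC before and after every removal; it stops when
all remaining non-forced predictors are significant. "The model became
consistent" is operationalized as exactly that stopping rule, with the
BIC path reported so a reader can see whether any removal degraded the
model. Collinearity is checked with variance inflation factors computed
from the defining regression (flagged at VIF >= 2), and Shapiro–Wilk
statistics of the final-model residuals are reported as diagnostics
only — they never gate the procedure, replacing visual Q–Q inspection
with a number.

## What the generator emulates — and what it does not

`simulate_walk()` produces traces at the device's nominal rate with a
baseline offset, optional Gaussian sensor noise, optional timestamp
jitter, the calibration/sync protocol, and planted pull bursts from
three parametric templates: triangle, single hump, and a double hump
whose interior valley exercises the gradient-split rule (its ground
truth lists two events). The direction channel switches on 0.3 s before
each burst so attribution reads the correct value at onset. Defaults
reflect the study conditions: ~5 min walks, 20 kg dogs, peaks of a few
kgf — two orders of magnitude above the threshold, as real pulls are.

`simulate_cohort()` reproduces the statistical structure of the study:
370 walks by 74 volunteers with 111 dogs, personality scores drawn from
the observed cohort means and SDs, dogs assigned only to volunteers of
equal or higher training level, outcomes built on the transformed scale
from planted fixed effects plus volunteer and dog random intercepts and
residual noise. The variance components (0.15/0.15/0.35 on the log10
scale) were chosen once so that fixed-effect standard errors land near
the magnitudes the study design implies (~0.003–0.005 for personality
scores); planted effects default to the same order of magnitude
(|beta| ≈ 0.01 on the log10 scale) so recovery studies are realistic
rather than easy.

The generator does not emulate gait dynamics, leash elasticity,
autocorrelated sensor drift, or coder idiosyncrasies; passing recovery
tests therefore demonstrates that the *pipeline* is correct and well
calibrated under the stated noise model, not that detection is robust
to every artifact of field recordings. The optional dropout switch
(deleting a contiguous chunk) exists for robustness exploration only.

## Numerical choices and scale of the shipped checks

Degenerate inputs are handled explicitly rather than incidentally: a
constant outcome short-circuits the mixed fit to its closed form; a
perfectly collinear design aborts naming the aliased columns before
estimation; an undefined alpha (zero total variance) is an error, not a
NaN. All generators are deterministic given a seed, flowing from one
top-level seed in `run_pipeline()`.

The package's verification suite runs detector-vs-oracle equivalence on
200 random traces of ~1000 samples, planted-event recovery on 120
walks, the alpha closed form at n = 100{,}000, and the association
protocol on 400 cohorts of 370 walks — sizes chosen to make Monte-Carlo
error small relative to the properties asserted while keeping a full
run in the minutes range on one core.

## Known limitations

* The item-to-factor mapping of the exit questionnaire is an assumption
  (see above); factor scores computed under the default mapping should
  not be compared across studies without confirming the mapping.
* Wald z p-values are slightly anticonservative with few grouping
  levels; with 74 and 111 levels the effect is small but not zero, and
  the null survivor rate of the elimination protocol reflects it.
* Kappa depends on the bin width; report it alongside the statistic.
* The "both" attribution category depends on the direction dead-band
  margin; at margin 0 every event is forced to dog or handler.
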