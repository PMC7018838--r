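---
title: "Head-free gaze event analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-free gaze event analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazekit)
```

## The problem

When the head is free to move, the velocity signal recorded by an
eye tracker mixes two rotations: the eye in its socket (eye-in-head, EiH)
and the head in the world. A gaze *fixation* may involve vigorous eye
movement (the vestibulo-ocular reflex counter-rotating the eye against the
head at near-unity gain), a gaze *pursuit* may be carried mostly by the
head, and a gaze *shift* (saccade) rapidly relocates the gaze point.
Event classification therefore has to operate on both streams. gazekit
implements the full chain for this setting:

1. **kinematics** -- direction/orientation series to a filtered 6-channel
   velocity signal: absolute EiH and head speed $|\omega_e|, |\omega_h|$
   and signed azimuth/elevation components
   $\omega^{Az}_e, \omega^{Az}_h, \omega^{El}_e, \omega^{El}_h$;
2. **events** -- the FIX/PUR/SAC/NONE taxonomy, run-length event lists,
   and the label-cleaning rules;
3. **agreement metrics** -- sample-level ($\kappa$, precision/recall/F1)
   and event-level (majority vote, event F1 with RTO/RTD, largest-overlap
   event $\kappa$, event error rate, and the window-based ELC metric);
4. **classifiers** -- a windowed-feature Random Forest and forward/
   bidirectional GRU sequence models with leave-one-subject-out (LOSO)
   evaluation;
5. **synthetic data** -- a seeded generator of labelled head-free
   recordings used to validate every other module.

## Velocity extraction

Angular speed uses the two-point central difference on unit direction
vectors, $\omega_v = f_s\,\delta\theta/2$ with
$\delta\theta = \angle(v_{n+1}, v_{n-1})$, computed robustly as
$\mathrm{atan2}(|v_1 \times v_2|, v_1 \cdot v_2)$. The two endpoint
samples use a one-sided difference over a single sampling interval so the
output keeps the input length; a literal replicate-padding of the central
formula would halve the boundary estimate, so the one-sided form is used
instead.

The signed components project the rotation's *sine* (the cross product)
onto the world up-axis (azimuth) and the instantaneous horizontal axis
$\hat z \times v$ (elevation), clockwise positive. Using the sine rather
than the angle is the small-angle approximation: at a 14 degree step the
component is about 1% low, and at the physiological ceiling (900 deg/s at
120 Hz, a 7.5 degree step) the error stays within that regime. It also
guarantees $|\omega^{Az}|, |\omega^{El}| \le |\omega_v|$, since they are
projections of one rotation vector.

Before differentiation, direction components (and head quaternion
components) are low-passed with a zero-phase Kaiser-window FIR
(cutoff 58 Hz, 60 dB stopband, 4 Hz transition band; forward-backward
application squares the magnitude response and cancels group delay).
After differentiation each velocity channel is smoothed with a 1-D
bilateral filter (window 50 ms, $\sigma_t$ = 18 ms,
$\sigma_r$ = 8.75 deg/s): neighbours are weighted by a Gaussian in time
*and* in signal value, so low-amplitude noise is averaged away while a
saccade peak -- hundreds of deg/s above its surroundings -- keeps
essentially all of its amplitude (the package's tests require at least
95% peak retention where a plain Gaussian of the same temporal width
keeps under 90%).

Samples with tracker confidence below 0.3 are masked before any
filtering; filters operate per contiguous unmasked segment and never
interpolate across blinks. Segments shorter than three filter lengths are
reflect-padded; segments under 9 samples pass the anti-alias stage
unfiltered. Head streams sampled on a different clock can be brought onto
the eye timestamps with quaternion slerp (`quat_slerp`) before building
the trace.

The head's absolute speed is measured from the relative quaternion (so
head roll counts), while its signed components come from the rotated
forward vector; torsion therefore never leaks into azimuth/elevation.

## Event representation and cleaning

Events are maximal runs of one non-NONE label; NONE (blinks, low
confidence, unlabelled) separates events and is never scored. Cleaning
applies, in order: (1) merge fixation pairs separated by at most 75 ms
whose mean gaze-in-world directions are within 0.5 degrees (the gap, which
must contain no other event, becomes FIX); (2) drop fixations shorter
than 50 ms; (3) drop saccades longer than 150 ms; (4) drop any event
shorter than 10 ms. All comparisons are strict, merged fixations are
duration-tested after merging, and the ordered pass is iterated to a
fixed point -- a single pass is not idempotent, because dropping an
interior event can create a new mergeable fixation pair. Without gaze
vectors the merge falls back to the temporal criterion alone, with a
warning.

## Agreement metrics

The sample-level machinery excludes any sample either sequence marks
NONE. Group agreement is "each labeller against the rest": every ordered
pair is scored, the two orientations of a pair are averaged (which makes
the reported precision and recall identical -- an assertable property),
then values are averaged per labeller and across labellers. A pooled
majority reference is deliberately not used; it would not give the p = r
symmetry.

Three prior event-level metrics are provided for comparison. Majority
vote scores each reference event by the modal test label inside it, and
cannot penalize short spurious events. The event-F1 family matches the
earliest overlapping same-class test event and reports signed boundary
offsets (RTO, test minus reference, in ms) and their SD (RTD); the
earliest-overlap rule misbehaves when a test event begins near the
reference offset. The largest-overlap event $\kappa$ picks the test event
with the highest intersection-over-union regardless of class (ties to the
earlier onset; reference events overlapping nothing fill an `unmatched`
column). The event error rate is the Levenshtein distance between
event-class strings divided by the reference string length.

## The ELC metric

ELC matches *transition points* rather than events. Every event owns an
onset and an offset. For each reference transition a window is extended
onto the test sequence -- ±25 ms when either adjacent event is a saccade
(gaze-shift boundaries are sharply localized), ±35 ms otherwise, endpoints
inclusive -- and the first-in-time test transition of the same side and
class inside the window is matched; a test transition serves at most one
reference transition, claimed in reference order. An event with both
transitions matched is **matched** (a fixation fragmented by a short
spurious event in the test still matches, via the first fragment's onset
and the last fragment's offset). An unmatched reference event completely
inside a same-class test event is **detached**; everything else is
**unmatched**. Detached events are omitted from all scores by default --
counting them as matches can only inflate per-class F1, which the test
suite asserts as a monotonicity property.

For matched events the package reports $l_2 = \sqrt{\Delta\mathrm{start}^2
+ \Delta\mathrm{end}^2}$ in ms (bounded by the window sizes, hence
$l_2 \le \sqrt{w_{on}^2 + w_{off}^2}$) and the overlap ratio $O_r$
(intersection over union of sample sets, the test-side interval delimited
by the two matched transitions, so it spans fragments).

Timing-offset correction replaces each matched transition pair by the
rounded mean of the two indices (ties toward the reference index; both
sequences move to the same representative index) and rebuilds each
sequence from the corrected event extents. This rebuilding reproduces the
outward/inward relabelling rules -- outward moves extend the event's own
class, inward moves cede samples to the neighbour whose shared boundary
moved with them -- and resolves the case the narrative rules leave open:
when the two sides of a shared boundary matched *different* test
transitions, a gap (NONE) opens between them, mirroring the other
sequence. After correction, re-matching yields zero residual $l_2$ for
all still-matched events whenever corrections do not collide; collisions
on very short events are resolved left-to-right.

The event confusion matrix puts matched reference events on the diagonal
(the matching criterion enforces class equality), unmatched reference
events in their row's `unmatched` column, and charges test events with no
matched transition to the modal reference class beneath them -- a spurious
saccade inside a fixation increments the F/S cell. $\kappa^*$ and
per-class F1 derive from this matrix. ELC is asymmetric; for inter-coder
comparison it is run in both directions and scalar metrics are averaged
(`bidirectional = TRUE`), while classifier output is evaluated
single-direction against the human reference.

## Classifiers

**Random Forest.** Per-sample feature vectors aggregate the six velocity
channels over a window of $2s+1$ samples plus four summaries: the angle
between the mean EiH (head-forward) vectors of the $s$ samples before and
after the sample ($\Delta\theta_e, \Delta\theta_h$) and the windowed SD of
the two absolute speeds ($\sigma_e, \sigma_h$). The feature dimension is
$g = 6(2s+1) + 4$, following the explicit channel enumeration (the
six aggregated channels plus four summaries); boundary windows are
truncated. Tracker confidence enters as a per-sample case weight, not as
a feature. Training rows equal to two decimals with the same label are
collapsed into one row carrying the summed weight (never on test data).
The forest uses 40 trees, a minimum leaf of 30 and $\lfloor\sqrt g\rfloor$
candidate features per split, fitted with `ranger` (chosen because it
supports case weights).

**GRU networks.** The sequence models consume the raw 6-channel velocity
stream: $k=3$ fully connected ReLU layers (width 32 -- the width is not
fixed by the architecture description, 32 is this package's choice),
$k=3$ stacked GRU layers with 24 units per direction (so the
bidirectional variant feeds 48 dimensions to the 3-class output layer and
the forward variant 24), 10% dropout, and a loss combining per-sample
weighted cross-entropy with the generalized Dice loss
($w_c = 1/(\sum_n g_{nc})^2$, empty classes clamped to zero weight).
Optimization is Adam at learning rate $10^{-3}$ decayed linearly to
$10^{-4}$ over the epochs (the decay schedule is unspecified upstream of
this package; linear-to-a-tenth is our reading of "reduced linearly").
Sequences in a batch are zero-padded to the longest; padded, NONE and
masked samples carry zero loss weight. Channels are standardized by
training-pool statistics -- a convergence aid that does not alter the
model class. The forward variant is causal by construction, which the
tests verify by perturbing future inputs. Forward, backward-through-time
and the loss gradient are implemented in RcppArmadillo and validated
against finite differences at $10^{-4}$ relative tolerance.

**LOSO protocol.** For each holdout subject the remaining subjects'
events are split into five folds with balanced fixation and saccade event
counts (whole events, pursuit events assigned whole without balancing);
five models are trained, each on four folds -- for the GRU models the
held-out fold is removed from the loss support while the sequences stay
intact -- and the best model on its validation fold is evaluated on the
holdout. Classifier output is never scored on NONE or low-confidence
samples. The ablation study retrains the same network on reduced input:
`eyes_only` (no head stream) and `absolute_only` (the two unsigned
magnitudes, requiring no eye/head coordinate alignment).

## The synthetic generator

`generate_recording` emulates the statistical structure of natural
head-free recordings: fixations with the head wandering under an
Ornstein-Uhlenbeck velocity law and the eye counter-rotating at the VOR
gain (default exactly 1), residual gaze-in-world tremor targeted at mean
0.55 deg/s and SD 0.32 deg/s *as measured through the velocity pipeline*,
pursuits whose virtual target curves (direction, speed and eye/head split
re-drawn every 400 ms) tracked jointly by eye and head, minimum-jerk
saccades with peak velocities drawn from 120-500 deg/s, and blinks that
drop confidence below the 0.3 threshold. The default event mix
(FIX 45%, SAC 41%, PUR 6%, blink 8% of events) approximates the
composition of labelled naturalistic recordings, with pursuit slightly
upweighted so per-class metrics remain estimable on short simulations;
fixation durations default to 150-800 ms. The scheduler draws event-type
counts proportional to the mix and arranges them with no two equal-label
events adjacent, so event-count proportions converge to the mix (tested
at ±2% on a 10-minute recording). A weak orienting spring re-centres the
head on the gaze direction during fixations, keeping the eye near its
primary position as in natural behaviour (without it, large eye
eccentricities decouple eye-vector speed from head speed and bias the
apparent VOR gain low).

Two internal tremor constants (1.03 on the mean, 1.21 on the SD)
pre-compensate the measured attenuation of the two-point + anti-alias +
bilateral chain in the tremor band; a slow lognormal amplitude envelope
gives the speed distribution its extra dispersion. These were calibrated
once against the pipeline and are not exposed as parameters.

`generate_labeller` emulates imperfect human coders: truncated-Gaussian
boundary jitter, whole-event relabelling by a row-stochastic confusion
matrix, and optional fragmentation of long events by short spurious
saccades.

**What passing tests do and do not show.** The generator produces
cleanly separated dynamics -- saccades are fast, pursuit targets move
within a known band, tremor is stationary. High LOSO kappa on this cohort
demonstrates parameter recovery (the pipeline, features and training loop
are correct), not field performance: real recordings contain optokinetic
nystagmus, head translation, slippage, and pursuit/fixation ambiguity
that no desk-scale simulation reproduces, and published head-free pursuit
detection remains far below fixation/saccade performance.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 10-subject cohort of 12 s
recordings at 120 Hz for the LOSO experiments, with the GRU models
trained for 30 epochs at batch size 1; these sizes were chosen so the
full validation runs comfortably on a single CPU while leaving the
qualitative conclusions (kappa above 0.8, pursuit degradation without
head input) stable across seeds. Filter tests use 5-17 s signals.
Rounding ties in the ELC correction go toward the reference index;
window membership is endpoint-inclusive; zemblys-style overlap ties break
toward the earlier test onset; modal-label ties in majority voting break
in FIX < PUR < SAC order. Degenerate kappa (chance agreement 1) is
defined as 1 for perfect observed agreement and 0 otherwise, with a
warning.

## Known limitations

- Head azimuth/elevation channels ignore pure torsion (roll about the
  line of sight); the absolute head speed does include it.
- The ELC correction's left-to-right conflict resolution can leave small
  residual offsets when corrections collide on events only a few samples
  long.
- The generator does not simulate scene imagery, depth, head translation
  (tVOR geometry) or optokinetic nystagmus; its VOR is purely rotational.
- `clean_events` measures fixation separation as the angle between mean
  gaze-in-world vectors; other separation definitions (e.g. centroid of
  points of regard in scene coordinates) are not implemented.
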