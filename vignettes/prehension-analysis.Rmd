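---
title: "Tracking and analyzing skilled prehension under cortical perturbation"
author: "prehensr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and analyzing skilled prehension under cortical perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prehensr)
```

## The analysis problem

Head-fixed mice can be trained to perform a cued, multi-step prehension
behavior: on an auditory cue they lift a hand off a perch, open it while
reaching, grab a food pellet, supinate, bring the pellet to the mouth, and
chew. The behavior is filmed by two high-speed cameras (500 frames/s,
352 × 260 px, near-perpendicular front and side views), and transient
optogenetic suppression of sensorimotor cortex is applied either at the cue
(probing initiation) or mid-movement (probing execution). The analyses this
package implements answer, on such data:

1. **Where is the hand?** A markerless tracker converts each video frame into
   a 2D hand position with a confidence, and calibrated stereo triangulation
   lifts the paired 2D tracks to 3D trajectories in millimeters.
2. **What did the animal do?** Ethogram statistics over manually annotated
   behavioral epochs: initiation rates in bracketed windows, cumulative
   first-lift histograms, latencies and inter-component intervals, and
   epoch-progression percentages with matched control subsampling.
3. **How does perturbation change the movement?** Distance-to-target time
   courses with the matched-control construction, interquartile divergence
   times, arc-length-aligned nearest-neighbor comparison of control versus
   rebound reaches, and grab end-point error.
4. **What do cortical units do?** Spike-width cell-type classification,
   peristimulus time histograms, and suppression/rebound rate ratios.

Because no public recording accompanies this task, the package ships a
first-class synthetic-data generator that produces trials, stereo videos and
spike trains with the statistical structure the analyses assume. Every
downstream stage is exercised end-to-end against generator ground truth, and
the test suite is largely parameter *recovery*: inject a known latency,
offset, suppression ratio or null and check that the analysis reports it.

## The hand tracker

The tracker is a cascaded pose regression: a cascade of `nStages` (default
100) boosted random-fern stages. Each stage samples a pool of pose-indexed
features — differences of image intensity at two offsets *carried along with
the current pose estimate* — which makes the features equivariant under joint
translation of image and pose. Each of the stage's 50 ferns takes the 5 pool
features most correlated with a random 1D projection of the remaining
displacement to the label; its 32 bins store shrunken mean residuals
(additive shrinkage 10). Offsets are drawn within a 40 px disc; out-of-bounds
samples clamp to the nearest pixel; feature thresholds are drawn uniformly
between the 10% and 90% feature quantiles.

At test time the cascade is run from 50 random initializations drawn
uniformly over the frame (the configuration used for the original videos).
The 50 final estimates are clustered by mean shift (Gaussian kernel,
bandwidth 5 px; modes closer than half a bandwidth merge; ties between
equal-weight modes break toward the lowest `(y, x)`). One mode per frame is
then selected by dynamic programming minimizing
$\sum_t -\log(w_t/K) + \lambda\,\lVert p_t - p_{t-1}\rVert^2$ with
$\lambda = 0.01\,\text{px}^{-2}$; with $\lambda = 0$ this reduces exactly to
the per-frame top mode. A frame is flagged as a potential error when its
selected weight fraction falls below 0.4 or the frame-to-frame jump exceeds
20 px; a second pass re-tracks flagged frames from initializations
concentrated around the position interpolated from unflagged neighbors.
Manual corrections enter as pinned single-candidate frames with confidence 1
and are never flagged.

Design points that were genuinely open and are therefore package
conventions, not reconstructions: the regressor family and its size (random
ferns, depth 5, 50 per stage, 400-candidate pools), the correlation-based
feature selection, the uniform initialization distribution, and the numeric
error-flagging criterion. All are configurable.

## Stereo geometry

Cameras are pinhole models with two-term radial distortion applied in
normalized coordinates before the intrinsics. The world frame is
right-handed, in millimeters, with its origin at the perch. Triangulation
undistorts the two observations (fixed-point inversion of the radial model),
intersects the viewing rays in least squares, and polishes the point with a
few Gauss–Newton steps on the summed squared reprojection error; the
reported residual is the RMS reprojection distance over the two views.
Near-parallel rays (under ~0.06°) raise a degenerate-geometry error, and the
rig constructor refuses optical axes within 1°. Per-animal calibration
refinement adjusts the side camera's extrinsics (six parameters,
Rodrigues-parameterized) to minimize total squared reprojection error, with
the front camera fixed as gauge; a flag releases the intrinsics of both
cameras, off by default to avoid overfitting a single animal's trajectories.

## Ethogram conventions

Frames are 0-based and epoch intervals half-open `[start, end)`; time is kept
in frames internally and reported in ms at the session frame rate (default
500 frames/s). A trial *achieves* an epoch iff an interval with that label
exists; canonical ordering (Lift ≺ HandOpen ≺ Grab ≺ Supinate ≺ AtMouth ≺
Chew) is enforced on first frames only, so overlapping annotations are
permitted. Intervals defined "during the final prehension sequence"
(Grab–Supinate, Supinate–AtMouth, Grab–AtMouth) use the last maximal run of
canonical epochs whose indices are non-decreasing — the definition we adopt
for "final sequence", since a trial interrupted mid-reach can contain an
earlier partial run. Initiation in bracketed windows counts a trial iff a
Lift *starts* inside the half-open window; only a Lift (not a complete
reach) is required, and the window is a parameter.

Progression histograms group laser trials by the epoch ongoing at laser
onset (the last canonical component whose first frame is at or before laser
onset) and score, for each subsequent canonical transition, the percentage
of trials containing the later component after the grouping epoch. The
control comparison is a per-animal seeded subsample, equal in count to the
laser trials and restricted to controls achieving the grouping epoch. For
the distance-to-target analyses, laser trials interrupted during Lift
through Supinate are dropped when a Chew epoch overlaps the laser window
(the behavior was evidently not impeded); AtMouth/Chew interruptions keep
all trials, since a lack of effect is not detectable there.

## Kinematic comparison statistics

Targets (pellet and mouth) are inferred as the per-axis mean — or median,
both estimators are provided since both are defensible and robustness to
end-point outliers differs — of the hand position at the first frame of Grab
and AtMouth across cued control trials. Deviation time courses report the
median and quartiles across trials of the Euclidean distance to the chosen
target, on the video frame grid, relative to laser onset (laser trials) or
to the matched interval start (controls). The matched start transplants, for
each control trial, the offset *t* between the last grouping-epoch start and
laser onset of a uniformly drawn laser trial onto a uniformly drawn epoch
instance of the control trial. The divergence time is the first time point
at or after laser onset from which the two interquartile bands are disjoint
at every subsequent grid point of the horizon; touching bands do not count,
and a momentary re-overlap resets the onset.

Arc-length alignment removes time parameterization: cumulative path length
is normalized to [0, 1] and positions are linearly interpolated at checkpoint
fractions (default Lift start, 1/3, 2/3, Grab). The nearest-neighbor
comparison is a leave-one-out 1-NN on the 3D position at a checkpoint,
reported as balanced accuracy — the mean of true-positive and true-negative
rates, so 0.5 is chance at any group imbalance. Leave-one-out is our choice;
without it a trial would match itself. Rank-sum and Welch contracts wrap the
standard tests (exact rank-sum null for pooled *n* ≤ 20 without ties, normal
approximation with tie correction otherwise; two-sided throughout), and
dispersion comparisons use the Ansari–Bradley test on median-centered
samples. Per-transition tests are reported uncorrected, with an optional
Holm flag, matching how such panels are usually presented.

## Spike-train analysis

Spike width is the trough-to-peak interval of the mean waveform; monotone
waveforms and waveforms whose global peak precedes the trough are rejected.
Classification applies strict inequalities on both sides: widths below
0.35 ms are fast-spiking, above 0.45 ms putative pyramidal, and the closed
interval [0.35, 0.45] ms — including both boundary values — is excluded.
PSTHs pool counts across trials in half-open 100 ms bins (a spike exactly on
an edge belongs to the right bin) and divide by `nTrials × bin` to give Hz.
Suppression and rebound are mean-rate ratios of the laser and post-laser
windows to baseline; a zero baseline yields `NA` with a warning rather than
an infinite ratio. Band-pass filtering and threshold detection are
documented input-provenance requirements: sorted spike times are this
module's input, since sorting was a manual step upstream.

## The synthetic generator: what it emulates

One trial is built in three layers. **Timing:** the cue-to-first-lift
latency is normal (300 ± 80 ms); epoch durations are log-normal with the
configured means and a common coefficient of variation. **Path:** straight
minimum-jerk segments perch → pellet (over Lift + HandOpen), a hold at the
pellet during Grab, pellet → mouth (over Supinate), a hold afterwards, plus
isotropic Gaussian position noise (0.15 mm per axis). **Perturbation:** a
laser window that covers the would-be movement onset blocks initiation; a
laser starting during Lift–Supinate freezes the hand after a latency drawn
uniformly from 72–170 ms (the reported range for a representative animal),
with velocity decaying exponentially with a 10 ms time constant — our
reading of "decay to zero over about 30 ms", i.e. three time constants;
laser during AtMouth/Chew has no kinematic effect, since chewing is
cortex-independent at this level. After laser offset a rebound reach
launches with a probability that increases with laser duration (0.05 at
100 ms up to 0.95 at 4 s) at a latency of 150 ± 40 ms — shorter and less
variable than the cued reaction time, which is the qualitative structure the
timing analyses must recover. Sessions intersperse laser trials at random at
a 20% default fraction. Prolonged-suppression limb retraction to a mid-air
point is implemented but disabled by default; its end point and speed are
conventions with no quantitative anchor.

Default epoch duration means are Lift 80, HandOpen 60, Grab 70, Supinate 80,
AtMouth 150, Chew 800 ms with CV 0.12 — a fast, tightly stereotyped reach of
~200 ms perch-to-pellet, which is the regime the task operates in. The
workspace puts the pellet ~19 mm and the mouth ~15 mm from the perch.

Rendering draws the hand as an isotropic Gaussian blob (σ = 6 px, amplitude
1) at its projected position in each 352 × 260 view over i.i.d. Gaussian
background noise (σ = 0.02). Spike trains are inhomogeneous Poisson with a
piecewise-constant rate: baseline, suppressed by `suppressionFraction`
during the laser, elevated by `reboundGain` for `reboundDurationMs` after
offset.

What the generator deliberately does **not** emulate: mouse anatomy and
appearance (a blob has no paw-like distractors, so tracking difficulty is
optimistic), corrective sub-movements and online feedback, trial-to-trial
path shape variability beyond additive noise (paths differ only in timing
and noise, so arc-length-aligned positions are nearly ideal), licking and
grooming kinematics, and light propagation in tissue. Passing recovery tests
therefore demonstrates the *analyses* are correct and well-calibrated, not
that the tracker would reach the same accuracy on real video.

## Probe configurations used in the tests

Two recovery experiments use dedicated probe settings rather than the
generator defaults, for identifiability rather than realism:

* **Freeze-latency recovery.** A 120 ms latency can only be read off the
  divergence time if the interrupted transport is still in flight 120 ms
  after laser onset. Under the default fast reach the transport is complete
  by then and the divergence instead reflects the departure for the mouth.
  The recovery experiment therefore uses a slow, low-jitter probe reach
  (Lift 150 / HandOpen 150 / Grab 100 / Supinate 250 / AtMouth 200 ms,
  CV 0.02) with the laser placed 20 ms after the trial's own Lift — a
  calibration instrument, in the same spirit as injecting the degenerate
  latency range {120, 120} ms itself. Recovered divergence times are
  128–132 ms across seeds; the positive bias of ~10 ms is the time the
  interquartile bands need to clear each other and is bounded by one grid
  step plus the band-clearing time.
* **Nearest-neighbor chance calibration.** A single-checkpoint balanced
  accuracy at *n* = 50/50 has a standard deviation of ~0.06 (leave-one-out
  decisions are positively correlated), so we summarize the classifier by
  its mean accuracy over the three reach checkpoints (1/3, 2/3, Grab). The
  Lift checkpoint is excluded from the summary because both groups start at
  the perch by construction: it carries no discriminative signal and would
  dilute genuine end-point differences. Per-checkpoint accuracies remain
  available.

## Problem sizes and numerical choices

The test suite and the acceptance script run at these scales, chosen to give
stable statistics at desk scale: tracker training on 200 labeled frames with
a held-out 500-frame stereo video; 1000 randomized instances for the
DP-versus-enumeration oracle; 1000 points for stereo round-trip and noise
calibration; 50 laser + 100 control trials per divergence replicate over
10 seeds (5 in the acceptance script); 50/50 groups over 100 replicates for
the chance calibration; 50 per group over 50 replicates for rebound timing;
40/40 over 100 replicates for the grab-error null; 100 trials for the spike
recovery. Unit tests use a mid-scale tracker fixture (100 frames, 60
stages) with 150 initializations per frame, which stabilizes the top mode
where the full-scale model needs only the default 50.

Remaining numerical conventions: pixel sampling rounds half-up
(`floor(x + 0.5)`) identically in R and C++; poses are clamped to the frame
after every cascade stage; the fixed-point undistortion runs 20 iterations
(exact at zero distortion); Gauss–Newton triangulation polishing runs at
most 8 steps with a 1e-12 Levenberg damping; degenerate rank-sum input (all
pooled values identical) returns p = 1 with a warning; empty feature pools,
empty training sets, missing reference events, and windows outside a PSTH
all raise errors naming the violated precondition.

## Limitations

The generator's idealizations (above) bound what green tests mean for real
data. The cascade's feature selection is a documented stand-in for an
unspecified "different feature-selection method"; the multi-pass smoothing
count and the error-flagging threshold are conventions. Calibration
refinement assumes the front camera defines the world frame; refining both
cameras' extrinsics would require an external gauge. The pipeline's default
configuration is sized for minutes-scale runs; full-scale tracking of long
sessions is compute-bound in the cascade and scales linearly in frames ×
initializations × stages.
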