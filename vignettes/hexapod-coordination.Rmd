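---
title: "Quantifying inter-leg coordination in freely walking hexapods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-leg coordination in freely walking hexapods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexacoord)
```

## The scientific problem

Walking insects coordinate six rhythmically stepping legs without a single
central clock. A long-standing behavioural account describes this
coordination as pairwise coupling between neighbouring leg controllers:
a posterior *sender* leg influences its anterior *receiver*. Two of these
coupling rules matter most for timing. Under **rule 1**, a swinging sender
suppresses the onset of swing in its receiver; under **rule 2**, the
sender's touch-down promotes receiver swing onset shortly afterwards. Both
rules pivot on the sender's touch-down, the moment it takes on load —
which is also why severing one connective of the ventral nerve cord (the
neural channel between adjacent leg controllers) is such an informative
manipulation: it removes neural coupling across the cut while leaving
mechanical coupling through the shared body intact.

`hexacoord` implements the complete measurement chain used to quantify the
effect of such lesions in free walking: marker-based motion capture of the
nine dorsal markers (three thoracic, six femoral), body-centred
protraction/retraction angles, segmentation into step cycles, circular
statistics of inter-leg phase, and a balanced-bootstrap comparison of step
parameters between a lesioned and a sham cohort. Because the original
animal recordings are not publicly deposited, the package also contains a
ground-truthed synthetic walker whose statistical structure matches what
the analysis assumes; it is first-class, tested code, and every stage of
the pipeline is validated against it.

## The synthetic walker

Each leg is a two-phase oscillator. During stance the protraction angle
falls linearly from the touch-down angle (AEP, anterior extreme position)
to the lift-off angle (PEP, posterior extreme position); during swing it
returns along a cosine-eased ramp, which gives the smooth, zero-slope
movement reversals that real protraction traces show. A cycle's period is
drawn per cycle as `period_s + N(0, period_jitter_sd_s)`; per-frame
Gaussian angle noise models marker and digitisation error.

Coupling edges implement the two rules mechanically:

* **rule 2** — at each sender touch-down plus a neural latency
  (default 40 ms), the receiver's remaining stance time is shortened by
  `rule2_strength` times the time remaining. Strength 1 forces the
  receiver to lift off at the latency; strength 0 disables the edge.
* **rule 1** — while an enabled sender is in swing, the receiver's
  lift-off is deferred to the sender's touch-down.

The default topology has ipsilateral posterior-to-anterior edges
(`L2->L1`, `L3->L2`, `R2->R1`, `R3->R2`, both rules) and contralateral
edges between homologous legs with the left leg as sender (`L1->R1`,
`L2->R2`, `L3->R3`, rule 2 only). A lesion switch silences the edges that
cross the cut connective: `T2_right` severs `R2->R1` and `L2->R2`,
`T3_right` severs `R3->R2`. The left/right direction of the contralateral
edges is a modelling convention (the intact side leads), not a biological
claim; it is configurable.

Two properties of this model are worth stating explicitly because the
tests rely on them. First, with no coupling and no jitter every leg is an
exact oscillator, so recovered periods and extreme positions have a
closed-form ground truth. Second, *decoupling only matters in the presence
of period jitter*: with identical deterministic periods, phase locking
persists trivially whether or not edges are severed (after a transient the
deterministic system locks exactly). The lesion signature the package is
designed to detect — a collapse of the mean resultant length R with only
a modest shift of the mean phase — therefore requires jitter, and the
default study condition uses `period_jitter_sd_s = 0.05` s on periods of
0.6–0.7 s.

Default working ranges and periods (front 60..10°, middle 30..−5°, hind
5..−25°, periods 0.6–0.7 s, stance fraction 0.65, forward speed 30 mm/s)
were chosen once to be representative of straight free walking in a stick
insect and are the fixed conditions of all simulation-based tests.

The body translates and yaws with configured velocities; the pose is
integrated by explicit Euler at the 50 Hz frame rate, which is exact for
the constant-velocity profiles the generator supports. Sideward bias is
imposed on the body path (no mechanics are simulated). Markers are placed
from a body plan in which the metathorax root marker is the body-frame
origin; by default each leg's femur is anchored at its segment's thoracic
marker so that the configured angle is exactly the marker-line angle the
analysis later measures.

## From images to angles

`render_frames()` produces 8-bit 480×640 grayscale frames at 50 Hz with a
Gaussian blob per marker, and a gantry stream giving the camera's arena
position per frame. The camera follows the root marker; its follow error
is low-pass filtered over about half a second because a manually driven
gantry errs smoothly, not as white noise.

`detect_markers()` thresholds a frame (default 50/255), labels connected
components (at least 3 pixels) and returns intensity-weighted centroids —
sub-pixel accurate for symmetric blobs. `track_markers()` assigns labels
frame by frame with a greedy nearest-neighbour rule: candidate pairs are
taken in ascending distance, each detection used at most once, and only
within `max_jump_px` (default 20 px, far below the ~45 px inter-marker
spacing but above the ~11 px worst-case per-frame displacement of a
swinging femoral marker). Greedy assignment matches the simplicity of
classical semi-automatic trackers and is a documented limitation where
markers cross. Lost labels get gap flags and are re-acquired from their
last position. `to_arena_coords()` adds back the camera position
(`arena = camera + mm_per_px × (centroid − centre)`, image y flipped to
arena north) and bridges gaps of up to 3 frames (60 ms) by linear
interpolation; longer gaps are an error, not silently smoothed.

`body_frame()` takes the root (posterior metathorax) marker as origin and
the root-to-prothorax chord as the body axis. A two-marker chord is the
simplest deterministic choice; the mesothorax marker is deliberately held
out so it stays available as an independent check. `protraction_angles()`
then measures, per leg, the signed angle between the thoracic-to-femoral
marker line and the body-axis perpendicular on that side: 0° = femur
orthogonal to the body axis, positive = femur points forward, identically
on both sides. `body_velocities()` differences the root position and
heading between subsequent frames (projection on the heading at the
earlier frame), yielding forward (Tx), sideward (Ty, positive left) and
yaw (Rot, positive counter-clockwise) velocities, each smoothed with a
sliding median whose window is 60 ms — 3 samples at 50 Hz — truncated at
the series edges.

## Step cycles and phase

`detect_events()` extracts movement reversals as local extrema of the
angle time course: maxima are AEPs (touch-down proxies), minima PEPs
(lift-off proxies). Two numerical choices matter here. First, the series
is pre-smoothed with a 5-sample quadratic Savitzky–Golay filter: unlike a
moving average or median it reproduces locally quadratic peaks exactly, so
it suppresses angle noise without clipping the reversal extremes. With
2° angle noise this keeps the median AEP/PEP recovery error near 0.5°,
where raw argmax extraction is biased by over 1° (the maximum of noisy
samples near a flat peak is biased upward; a moving average instead clips
the peak from the stance side). Second, candidate extrema are pruned by
repeatedly deleting the adjacent max/min pair with the smallest excursion
until all pairs clear the prominence (default 5°) and separation
(default 0.1 s) thresholds — this enforces strict AEP/PEP alternation and
keeps the more extreme of two same-kind candidates. The defaults sit well
below typical step lengths (15–60°) and periods (0.5–1 s) and are exposed
as arguments. No distinction between step types (e.g. short steps) is
made.

`step_cycles()` assembles one cycle per AEP–PEP–AEP triple; the period is
AEP-to-AEP, matching the phase reference below, and step length is
`aep_deg − pep_deg`. `phase_in_reference()` expresses each receiver
lift-off within the sender's AEP-to-AEP reference cycle as
`360·(t − AEP_k)/(AEP_{k+1} − AEP_k)`; phase 0 means the receiver lifted
off exactly when the sender touched down, the signature timing of rule 2.
The interval is closed on the left, so a lift-off exactly on a reference
touch-down is phase 0 (a tie-break the measurement convention leaves
open). Lift-offs outside all reference cycles are dropped and counted.

Circular statistics are computed on per-animal means: `mean_vector()`
returns the mean direction Φ and mean resultant length R of a phase
sample (R near 1 = tight coupling, near 0 = none; Φ is reported missing
when R = 0), `per_animal_phase_stats()` gives one (Φ, R, n) per animal
plus a pooled 15°-bin histogram for rose plots. Mean directions between
cohorts are compared with the Watson–Williams one-way circular ANOVA
(with the standard 1 + 3/(8κ) correction, κ estimated by Fisher's
approximation; exact ties make the statistic undefined and raise an
error suggesting jittered input), and full phase distributions with the
two-sample Kuiper test, whose statistic `V = max(F1−F2) + max(F2−F1)` is
origin-invariant on the circle; its p value uses the standard asymptotic
series with the small-sample λ correction. Both tests are cross-checked
in the test suite against independently transcribed reference formulas
and a brute-force EDF oracle to 10⁻⁶.

## Cohort comparison

Because each animal contributes many but unequal numbers of steps while
the cohort has only a handful of animals, cohort estimates use a two-step
balanced bootstrap (`bootstrap_median_ci()`): each replicate draws
`ceil(N/k)` values with replacement from each of the k animals and
truncates uniformly at random to the original total N, so every animal
contributes equally in expectation; 10,000 such replicates (tests and
examples use fewer) yield the median of medians and percentile 95% and
99% intervals. Percentile rather than BCa intervals are used — the
simplest estimator consistent with the stated procedure; their realised
coverage for a cohort median is slightly below nominal (~94–95% at
nominal 95%) because the bootstrap distribution of a sample median is
discrete.

`compare_cohorts()` flags significance when CIs are disjoint (closed
intervals: touching counts as overlap, the conservative reading) — 95%
CIs for the p < 0.05 tier, 99% CIs for p < 0.01 — and computes the effect
size as |Δ median| divided by the mean of the two 95% CI *widths*. Whether
that denominator should be the width or the half-width is ambiguous in
the source procedure; width is the default and half-width is available
via `denominator = "halfwidth"`, so absolute effect sizes should be
compared only within one convention. `summarize_lesion_effects()` formats
the familiar effect table: `↑ 1.5` for a 95%-tier increase, `↓↓ 3.8` for
a 99%-tier decrease, blank when not significant.

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure the analysis relies
on — rhythmic alternation, configurable working ranges and periods,
rule-1/rule-2 phase coupling with a lesion switch, between-animal
variability, marker noise, and a moving camera — so passing tests show
that the pipeline recovers known parameters and detects known coupling
changes under realistic noise. It does not simulate mechanics: no ground
reaction forces, no load transfer, no emergent sideward drift, no
femur–tibia or coxa–trochanter joints, no curve walking, and body-pose
changes are imposed rather than produced by the legs. Conclusions about
real animals therefore still require real recordings; what the synthetic
route guarantees is that any failure to see coupling in such recordings
is not an artifact of this analysis chain.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed, and identical
seeds give bit-identical outputs end to end (`run_pipeline()` records all
derived stage seeds in its manifest). The shipped test suite runs the
simulation-based checks at the sizes the properties state: at least 100
cycles per leg for parameter recovery (90 s trials), 10 seeded replicates
for the lesion contrast, 500 replicate cohorts (5 animals × 100 values,
B = 1000) for bootstrap coverage, and full 480×640 rendering for the
tracking round trip, which recovers simulated trajectories with an RMS
error of about 0.01 mm against a 0.125 mm budget (half a pixel).
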