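# hexacoord

Kinematic and statistical analysis of inter-leg coordination in freely
walking hexapods (stick-insect-style marker-based motion capture), for
locomotion researchers who want the full chain — video to effect table —
as tested, reusable R code:

* a **synthetic walker**: six coupled leg oscillators implementing the
  classic coordination rules 1 (a swinging posterior *sender* leg inhibits
  swing onset of its anterior *receiver*) and 2 (sender touch-down promotes
  receiver swing onset shortly after), with a connective-lesion switch
  that silences the coupling edges crossing the cut, per-cycle period
  jitter, angle noise, body translation/yaw, and full ground truth;
* **tracking**: rendering of 8-bit 480×640 frames at 50 Hz with a
  gantry-following camera, threshold/connected-component blob detection
  with sub-pixel centroids, greedy nearest-neighbour label tracking, and
  arena-coordinate reconstruction from the gantry stream;
* **kinematics**: body-centred protraction/retraction angles (0° = femur
  orthogonal to the body axis, positive = forward) and forward/sideward/yaw
  body velocities smoothed with a 60 ms sliding median;
* **step cycles**: AEP/PEP (touch-down/lift-off) extraction from angle
  extrema with Savitzky–Golay pre-smoothing, and per-cycle period, step
  length, stance and swing durations;
* **coordination**: phase of receiver lift-off in the sender's AEP-to-AEP
  reference cycle, per-animal mean phase vectors (Φ, R), pooled 15° rose
  histograms, the Watson–Williams test for mean directions and the
  two-sample Kuiper test for phase distributions;
* **cohort statistics**: two-step balanced bootstrap of cohort medians
  (equal expected contribution per animal despite unbalanced step counts)
  with 95%/99% percentile CIs, CI-overlap significance, effect sizes
  |Δmedian| / mean 95% CI width, and the arrow-formatted effect table.

The statistical core in the field's notation: for phases
φ₁ … φₙ (deg), the mean vector is
(R cos Φ, R sin Φ) = (mean cos φᵢ, mean sin φᵢ); R ∈ [0, 1] measures
coupling strength. A receiver lift-off at time t inside the sender cycle
[AEP_k, AEP_{k+1}) has phase 360·(t − AEP_k)/(AEP_{k+1} − AEP_k), so
Φ = 0 means the receiver lifts off exactly at sender touch-down.

## Worked example

Compare a sham cohort against a cohort with the right connective between
the pro- and mesothoracic ganglia cut (`T2_right`), 5 animals × 2 trials
of 30 s each:

```r
library(hexacoord)

sham_cfg <- walker_config(legs = default_legs(period_jitter_sd_s = 0.05,
                                              angle_noise_sd_deg = 1),
                          edges = default_edges(ipsi_strength = 0.9))
lesion_cfg <- build_walker_config(list(period_jitter_sd_s = 0.05,
                                       angle_noise_sd_deg = 1,
                                       ipsi_strength = 0.9,
                                       lesion = "T2_right"))
pc <- pipeline_config(config_a = sham_cfg, config_b = lesion_cfg,
                      n_animals = 5, trials_per_animal = 2, duration_s = 30,
                      between_animal_sd = list(aep_deg = 3, period_s = 0.03),
                      pairs = list(c("R1", "R2"), c("L1", "L2")),
                      parameters = c("period_s", "length_deg"),
                      B = 2000, seed = 42)
res <- run_pipeline(pc)

res$phases$A$R1_in_R2$per_animal   # sham: per-animal mean phase vectors
#>   animal_id phi_deg     r  n
#> 1        A1    8.15 0.992 86
#> 2        A2    8.03 0.952 87
#> 3        A3   11.48 0.980 93
#> 4        A4    8.32 0.963 91
#> 5        A5   12.87 0.974 89
```

Sham animals lift the right front leg off in a tight band early in the
right middle leg's cycle (per-animal R ≈ 0.95–0.99). After the lesion the
same pair decouples — mean per-animal R collapses from 0.97 to 0.13 while
phases scatter around the circle — and the pooled phase distributions
differ decisively:

```r
res$phase_tests$R1_in_R2$kuiper
#> $V [1] 0.828      $p [1] 5.6e-143
res$estimates$length_deg.R2$A      # sham right middle leg step length
#> <cohort_estimate> length_deg: median 38.29 , 95% CI [38.09, 38.47], ...
res$estimates$length_deg.R2$B      # lesioned
#> <cohort_estimate> length_deg: median 34.81 , 95% CI [34.74, 34.92], ...
res$effect_table
#>              L1     L2       L3   R1      R2      R3
#> period_s   ↑↑ 2   ↑↑ 3     ↑↑ 6 ↓↓ 8    ↑↑ 4  ↑↑ Inf
#> length_deg ↑↑ 8 ↑↑ 3.9 ↓↓ 16.99      ↓↓ 12.6 ↑↑ 2.76
```

Each cell shows the direction of the lesion-induced change, the
significance tier (single arrow: disjoint 95% CIs, p < 0.05; double:
disjoint 99% CIs, p < 0.01; blank: not significant) and the effect size
(|Δmedian| / mean 95% CI width; `Inf` marks a shift against zero-width
CIs, which happens when a frame-quantized median is perfectly stable).

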