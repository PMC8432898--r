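# septune

Information-theoretic characterization of spatially, directionally and
self-motion-tuned neurons from one-photon (miniscope) calcium imaging, with
naive-Bayes position decoding and stability analysis. The package sits
downstream of source extraction and pose estimation: its inputs are extracted
fluorescence traces (cells × frames) and a behavioral pose track, and its
outputs are per-cell tuning verdicts, decoding accuracy, stability metrics,
and anatomical gradients. A seedable synthetic-session generator with stored
ground truth lets every stage be validated against planted truth.

It is written for systems neuroscientists analyzing recordings of freely
moving rodents — for example GABAergic populations of the lateral septum or
hippocampal pyramidal cells — where activity is best treated as binarized
event epochs rather than deconvolved spike rates.

## The analysis in brief

**Binarization.** Raw traces are zero-phase low-pass filtered (2nd-order
Butterworth, 2 Hz), z-scored over the session, and a frame is *active* when
the normalized amplitude exceeds 2 SD while the filtered trace is rising.

**Tuning maps.** Behavioral variables are binned (open-field position
17 × 17 bins, linear-track position 34 bins, head direction 40 × 9°,
velocity 20 bins on [2.5, 30] cm/s, acceleration 20 bins on [−2, 2] cm/s²;
frames below 5 cm/s are excluded from positional and directional maps).
Over valid frames the package estimates occupancy P(Sᵢ), joint P(Sᵢ ∩ A)
and conditional P(A | Sᵢ) as frame-count ratios.

**Mutual information.** Tuning strength is the plug-in mutual information
between binary activity and the binned state,

    MI = Σᵢ Σⱼ P(Sᵢ ∩ Aⱼ) · log₂[ P(Sᵢ ∩ Aⱼ) / (P(Sᵢ) P(Aⱼ)) ],   j ∈ {active, inactive}

scored against 30 bootstrap samples (50% of frames, with replacement) and a
null of circularly time-shifted surrogates, which preserve transient
structure while destroying behavior coupling. A cell is *modulated* when its
MI exceeds the shuffled MI in at least the fraction 1 − α of surrogates;
cells are ranked by mean bootstrap MI minus mean shuffled MI. A per-bin
permutation test (1,000 circular permutations, p < 0.01) marks significant
place-field bins.

**Decoding.** A naive-Bayes decoder with uniform prior reconstructs the
state per frame from the cells active in that frame,

    ŷ = argmax exp[ Σₖ log(1 + P(Aₖ|S) P(S) / P(Aₖ)) − 1 ],

with optional sliding-window averaging of log-posteriors (1.5 s open field,
0.5 s track). Accuracy is reported as mean bin-center error (cm), exact-bin
agreement, and the chance-normalized decoding score
(shuffled error − actual error) / environment length, using bootstrap
samples of 40–100 cells and circularly shuffled training activity as the
control.

**Stability and topography.** Within-session stability is the Pearson
correlation of σ = 3-bin smoothed tuning maps across event-balanced session
halves (> 0.5 = stable). Across days, cells are matched by footprint
centroid distance (< 12 µm) and spatial correlation (> 0.65), and pair map
correlations are compared to a 30-permutation identity-shuffled null.
Proportions of stable tuned cells are regressed on stereotaxic position in
0.2 mm bins along the AP/ML/DV axes.

## Worked example

```r
library(septune)

arena <- arena_spec("open_field", 45, 45)
cells <- c(make_place_cells(8, arena, width_cm = 7, seed = 1),
           make_untuned_cells(2))
ses   <- simulate_session(arena, cells, duration_s = 900, seed = 2)
res   <- run_pipeline(ses, "demo_out", config = list(seed = 3,
                                                     cells_per_sample = 10))

head(res$mi[, c("cell", "mi", "p_value", "significant", "p_active")], 4)
#>   cell     mi p_value significant p_active
#> 6    6 0.0743  0.0323        TRUE   0.0231
#> 8    8 0.0727  0.0323        TRUE   0.0245
#> 7    7 0.0757  0.0323        TRUE   0.0250
#> 1    1 0.0699  0.0323        TRUE   0.0205

aggregate(mean_error_cm ~ shuffled, res$decoding, mean)
#>   shuffled mean_error_cm
#> 1    FALSE         14.74
#> 2     TRUE         24.73
```

The four strongest cells are the planted place cells: each carries ~0.07
bits of spatial information at activity levels P(A) ≈ 0.02, and beats all 30
circular surrogates (reported p = 1/31 with the plus-one correction, the
smallest value 30 shuffles can yield). Decoding the held-out half of the
session from 10-cell bootstrap samples errs by ~15 cm, versus ~25 cm for the
shuffled-tuning control — a decoding score of
(24.73 − 14.74)/45 ≈ 0.222. The untuned controls are not flagged.

Per-cell metrics from the same run (`res$metrics`) include the bursting
index P(active | active at t−1), split-half stability, and the mean
dispersion of active-frame positions around their centroid:

```r
head(res$metrics[, c("cell", "p_active", "bursting_index", "stability",
                     "dispersion_cm")], 3)
#>   cell p_active bursting_index stability dispersion_cm
#> 1    1   0.0207          0.858     0.984          6.43
#> 2    2   0.0197          0.784     0.985         10.19
#> 3    3   0.0270          0.766     0.959         14.50
```

## Session format

`write_session()` / `read_session()` use a plain-text session directory:
`metadata.yaml` (arena, frame rate, cell count), `behavior.csv`
(timestamped pose and kinematics), `traces.csv` (one row per cell), and
optionally `truth_binary.csv` for synthetic sessions. `run_pipeline()`
executes binarize → kinematics → tuning → MI significance → metrics →
decoding and writes one CSV per stage plus a `run_log.yaml` recording all
parameters and seeds.
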