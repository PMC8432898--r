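---
title: "Methods: tuning, significance, decoding and stability in septune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tuning, significance, decoding and stability in septune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septune)
```

# Scope and data model

`septune` analyzes binarized calcium activity from one-photon recordings of
freely moving rodents. It deliberately begins *after* video processing:
motion correction, source extraction and pose estimation are upstream tools,
and the package consumes their outputs — a cells × frames fluorescence
matrix on a common clock with a timestamped pose track (head centroid and
nose tip, in cm). All probability estimates treat the frame as the unit of
observation at a nominal 30 Hz over 15-minute sessions.

Activity is modeled as a per-frame binary state rather than a firing rate.
This matches the slow kinetics of calcium indicators: what a trace supports
reliably is "an activity epoch started here", not a spike count. All
downstream statistics — tuning maps, mutual information, decoding — are
defined on this binary variable.

# Binarization

A raw trace is low-pass filtered with a zero-phase (forward–backward)
2nd-order Butterworth filter, z-scored using the whole-session mean and SD
of the filtered trace, and frame $t$ is active iff

$$z(t) > \theta_z \quad\text{and}\quad f(t) - f(t-1) > 0,$$

i.e. the normalized amplitude exceeds the threshold while the trace rises.
The rising-phase restriction ties active frames to the onset of calcium
influx; the decay tail, which reflects indicator kinetics rather than
spiking, stays inactive.

Parameters: `cutoff_hz = 2` (Hz) — a cutoff of the order of the indicator's
transient bandwidth, low enough to suppress shot noise, high enough to keep
fast-rise onsets; `z_threshold = 2` (SD units). z-scoring is per session:
a single global threshold is only meaningful against a single global scale.
Whole-session normalization assumes slow drift has been handled upstream
(e.g. by the background model of the source extractor). Degenerate inputs
are rejected loudly: a zero-variance ("dead") trace or any NA raises an
error rather than returning an all-zero vector that would silently pass
downstream.

One practical note: a second pass of the filter over an already-filtered
trace still attenuates energy near the cutoff, so binarization is not
bitwise idempotent; re-running on the filtered channel reproduces the same
epochs to within a frame or two of onset jitter, which is what the test
suite checks.

# Kinematics

Velocity is the frame-to-frame displacement rate of the head centroid,
smoothed with a short Gaussian (σ = 33 ms) to suppress tracking jitter. A
second, much wider 30-frame boxcar (`velocity_smooth`) is computed on top
and is the channel used for velocity *binning*; the two smoothings serve
different purposes (artifact removal vs. discontinuity reduction before
discretization) and are applied in sequence.

Acceleration is the per-frame first difference of the boxcar-smoothed
velocity divided by the frame interval, in cm/s². This choice is deliberate:
differencing the lightly smoothed velocity at 30 Hz produces values whose
dynamic range is tens of cm/s², far outside the ±2 cm/s² binning range used
for acceleration tuning, whereas the 1-second-scale smoothed velocity yields
physiologically interpretable accelerations that populate that range.

Head direction is the angle between the vertical (+y) axis and the
head→nose line, measured clockwise and wrapped to $[0, 2\pi)$; the
convention is fixed and documented so that directional tuning is
reproducible regardless of camera axes. Coincident markers propagate the
last valid heading. When behavior and calcium run on different clocks,
positions are linearly interpolated onto the calcium timestamps; heading is
unwrapped → interpolated → rewrapped so interpolation never crosses the
circular discontinuity the long way.

Frames with velocity `< 5` cm/s are excluded from positional and
directional tuning (inclusive `>=` on the running side); velocity and
acceleration tuning instead exclude frames outside their own bin ranges.

# Tuning maps

Each behavioral variable is discretized by a `binning_spec`: open-field
position 17 × 17 bins spanning the arena (bin count fixed, bin size scaled
to the arena side, so a 49 cm arena gets ~2.9 cm bins), linear-track
position 34 bins, head direction 40 circular bins of 9°, velocity 20 bins
on [2.5, 30] cm/s, acceleration 20 bins on [−2, 2] cm/s². Bins are
half-open $[\ell, r)$ with the last bin closed; out-of-range values are
flagged invalid rather than clipped, so no probability mass is smuggled
into edge bins.

Over valid frames the package estimates occupancy $P(S_i)$, joint
$P(S_i \cap A)$, and conditional $P(A \mid S_i)$ as frame-count ratios.
Unvisited bins carry `NA` conditionals and a flag; no downstream statistic
ever reads an undefined conditional. Invariants maintained throughout:
occupancy sums to 1, the joint sums to the active fraction, and all three
maps are invariant to frame order.

Smoothing, where used, is visitation-normalized Gaussian convolution: the
kernel is truncated at 3σ, wrapped for circular variables, and renormalized
over visited bins, so constants are exact fixed points and unvisited bins
stay excluded instead of leaking zeros. On a fully visited circular domain
this also conserves mass exactly; on a bounded open-field grid the edge
renormalization trades strict mass conservation for unbiased values at the
walls — the standard occupancy-aware choice. Two different σ serve two
different jobs: σ = 3 bins wherever maps are *correlated* (split-half
stability, cross-day comparison), because correlation benefits from
variance reduction; σ = 1 bin where a field *peak is localized*, because a
9 cm kernel flattens a 7 cm field and edge renormalization drags the argmax
toward the walls (on planted-truth simulations peak recovery drops from
100% at σ = 1 to ~54% at σ = 3). MI is always computed on raw maps —
smoothing a probability table before a plug-in information estimate biases
it upward.

# Mutual information and significance

Tuning strength is the plug-in MI between binary activity and the binned
state,

$$\mathrm{MI} = \sum_{i=1}^{M}\sum_{j\in\{1,2\}} P(S_i \cap A_j)\,
\log_2\frac{P(S_i \cap A_j)}{P(S_i)\,P(A_j)},$$

with $0\log 0 = 0$. Uncertainty is assessed two ways, both per cell:

- **Bootstrap** (30 samples): frames resampled with replacement at 50% of
  the valid-frame count, giving a sampling distribution of MI.
- **Circular-shuffle null** (30 surrogates by default; 1,000 for
  calibration work): the activity vector is rotated by a uniform shift of
  at least 30 s. Rotation preserves the temporal autocorrelation of
  transients — a surrogate cell still "bursts" — which makes this null
  conservative compared to frame-wise permutation. The minimum shift
  prevents trivially aligned surrogates.

The cell-level verdict uses the shuffle-count ratio exactly as defined:
significant iff $\#\{\mathrm{MI}_\text{shuf} \ge \mathrm{MI}\}/n < \alpha$,
so with 30 surrogates and α = 0.01 the observed MI must beat every
surrogate. The *reported* p-value carries a plus-one correction,
$(r+1)/(n+1)$, so it is never exactly zero; with 30 shuffles its floor is
1/31 ≈ 0.032, which is why the verdict cannot be taken from the corrected
value at α = 0.01. Cells are ranked by mean bootstrap MI minus mean
shuffled MI. MI per binarized event divides MI by the number of 0→1
transitions; with realistic synthetic populations this lands in the
10⁻⁵–10⁻³ bits/event range.

A separate per-bin test (1,000 circular permutations, p < 0.01 per bin,
same verdict convention) marks the bins forming a significant place field.
The package's default "modulated" verdict is the MI-based one; the per-bin
mask is computed and reported regardless, and `population_mi(per_bin =
TRUE)` selects the conjunction. The parametric two-way-ANOVA alternative
for the MI comparison is intentionally not implemented; the nonparametric
route is fully specified and is the one used for ranking.

On linear tracks, MI is additionally split by traversal direction
(left/right run labels), each direction tested against its own null and the
difference tested by bootstrap; cells class as left-selective,
right-selective, bidirectional, or untuned.

Type-I behavior is verified by simulation: 200 untuned Bernoulli cells on a
simulated 15-minute open-field session, 1,000 permutations each, flag at
most 2.5% (the suite observes ~1%, consistent with the 10/1001 nominal
level of the count rule).

# Bayesian decoding

The decoder is naive Bayes over binarized activity with a uniform prior
across bins visited during training. Training estimates each cell's tuning
row $P(A_k \mid S)$ and marginal $P(A_k)$ from the training frames only
(locomotion frames, 50% of the session in alternating 10 s blocks —
interleaving avoids confounding the split with slow drift; a contiguous
split is available). Per test frame the decoder accumulates, over the cells
*active in that frame*,

$$\hat y = \arg\max \exp\Big[\sum_{k} \log\big(1 + P(A_k|S)\,P(S)/P(A_k)\big) - 1\Big],$$

normalized to a posterior over bins. Inactive cells are skipped: with
sparse binary activity the informative event is activity itself, and the
$1+\cdot$ inside the logarithm keeps never-active-in-bin cells from
annihilating the product. Ties at the argmax break to the lowest bin index,
deterministically. Frames with no active cell fall back to the prior and
are *flagged*: they carry no evidence, and evaluation excludes them by
default — scoring a constant tie-break bin as a "decode" would
systematically distort chance-level error. Temporal filtering (sliding mean
of log-posteriors over a centered odd window; 1.5 s open field, 0.5 s
track) re-admits such frames whenever their window held evidence.

Evaluation: error is the distance between decoded and actual *bin centers*
(absolute difference in 1D, Euclidean in 2D), agreement the fraction of
exact-bin hits, and the decoding score $(\bar e_\text{shuffled} -
\bar e_\text{actual})/L$ with $L$ the track length or arena side — a
dimensionless quantity invariant to units. Bootstrap decoding draws 40–100
cells with replacement from the pool passing $P(A) > 0.001$, 30 samples;
the chance control replaces each cell's *training* activity with one
circular surrogate before estimating tuning, leaving test activity intact.

Calibration facts the suite verifies: a noiseless population of 34
indicator cells tiling a 34-bin track decodes with zero error and full
agreement; shuffled-tuning decoding on a uniformly occupied 100 cm track
converges to the $L/3$ closed form for the expected distance of two
independent uniforms (within 10%); the score of shuffle against shuffle is
centred on 0 within ±0.02; and the median error decreases monotonically as
bootstrap samples grow from 8 to 100 cells.

# Stability, cross-session tracking, topography

**Split-half stability.** The session splits at the frame where the
cumulative count of binarized *events* (0→1 transitions) reaches half the
session total — event-balancing, not time-halving, so both halves hold the
same amount of activity even when rate drifts. Active-frame counts would
overweight long transients, hence the transition-count definition. Maps per
half are smoothed (σ = 3) and Pearson-correlated over bins visited in both
halves (pairwise-complete; a zero-filled variant is available by argument);
r > 0.5 is stable. Halves with fewer than 3 common bins, or sessions with
fewer than 2 events, raise errors rather than returning a correlation of
convenience.

**Dispersion.** The mean Euclidean distance of active-frame positions from
their centroid — a formula reconstructed from a schematic rather than
printed, and flagged as such: it is translation/rotation invariant,
increases with field width, and treats multi-field cells as dispersed,
which is the intended reading.

**Cross-session matching.** Candidate pairs need centroid distance < 12 µm
and footprint correlation > 0.65; among candidates a greedy
mutual-nearest assignment (closest first) yields a one-to-one matching.
This replaces a full probabilistic registration model with the two printed
thresholds; nonrigid image alignment is accepted as an upstream step
(identity for synthetic data). Pair tuning-map correlations are compared
against a null built by permuting day-B identities among matched pairs (30
permutations, derangement not enforced); pairs with r > 0.3 count as
stable.

**Topography.** Cells inherit their implant lens center (stereotaxic mm)
plus the in-plane offset (µm → mm); DV is the lens-center DV since the
imaging plane is single. Per animal and per 0.2 mm bin along the chosen
axis, the proportion of flagged cells (default flag: significantly
modulated *and* split-half stability > 0.5) is regressed on bin center by
OLS; bins with fewer than 5 recorded cells for an animal are dropped to
avoid degenerate 0/1 proportions. Constant proportions return slope 0,
R² = 0 rather than an undefined fit.

# The synthetic-session generator

The generator exists so each stage has a recoverable truth; it emulates the
study conditions, not calcium biophysics.

- **Trajectory.** Open field: reflected Ornstein–Uhlenbeck speed process
  (mean 10 cm/s, SD 3, relaxation 1 s — the mid-range of mouse foraging
  speeds under the 0–30 cm/s binning) with diffusing heading
  (1.6 rad/√s) and wall reflection; 45 × 45 cm, 30 Hz, 15 min. Linear
  track: alternating end-to-end runs with ~1.5 s end pauses and a
  per-frame run-direction label, so direction-split analyses have truth.
  The nose marker sits 1.5 cm ahead of the head along the heading.
- **Activity.** Per-frame independent Bernoulli draws at rate
  $p_b + (p_f - p_b) f(\text{state})$ with $f$ a normalized Gaussian place
  field (width = 2σ in cm), von Mises direction tuning, or logistic
  velocity/acceleration tuning; untuned controls use $f = 0$. Composition
  is additive-then-clipped so the exact per-frame rate is stored and
  binomial checks are exact. Defaults $p_f = 0.15$, $p_b = 0.005$ put
  session-wide P(A) near 0.01–0.02, bracketing the activity levels of the
  recorded populations the package targets.
- **Remapping**, where planted, means the day-2 field center is redrawn at
  least 15 cm from the day-1 center: an independently redrawn field that
  happens to land on the old one is genuinely stable, and including such
  cells in a "remapped" truth set would make the planted fraction
  unrecoverable by any estimator.
- **Calcium.** Each 0→1 transition injects a double-exponential transient
  (rise 50 ms, decay 500 ms, peak 1.0 — fast-indicator-like), transients
  sum linearly, Gaussian noise (SD 0.05) is added, and true onset frames
  are returned.

What it does *not* emulate — and therefore what green tests do not certify
on real data: indicator saturation and bleaching, signal contamination
between neighboring cells, tracking dropouts and pose-estimation error,
theta-timescale temporal structure within activity epochs, and nonrigid
field-of-view deformation across days (cross-day alignment is identity for
synthetic footprints). Conclusions about estimator calibration, decoding
geometry and recovery transfer; absolute error magnitudes on real data will
differ.

# Numerical conventions and problem sizes

- Permutation p-values are reported with the plus-one correction
  ($p \in (0,1]$, never 0); verdicts use the raw count ratio (see above).
- Posterior rows renormalize after every operation; log-posteriors are
  floored at `1e-300` before logs to avoid `-Inf` arithmetic.
- Circular shifts are uniform on $[\text{min\_shift}, T-\text{min\_shift}]$
  with min 30 s; rotation is exact (integer index arithmetic).
- All stochastic functions take explicit integer seeds; identical seeds
  give bit-identical outputs, and `run_pipeline` writes every parameter and
  seed to its run log.
- The test suite runs sessions of 120–900 s at 30 Hz; calibration blocks
  use 200 null cells × 1,000 permutations, recovery blocks 50 place cells,
  stability blocks 100 seeded runs per condition, cross-day blocks 80
  pairs, gradient blocks 50 cohorts of 8 × 100 cells. These sizes give
  binomial standard errors comfortably inside the asserted margins while
  keeping the whole suite in the low minutes on one core.

# Known limitations

- The MI estimator is the plug-in estimator; it is positively biased at low
  occupancy and no bias correction is applied, because verdicts compare
  against surrogates computed with the identical estimator (the bias
  cancels in the comparison, not in the absolute value).
- The decoder assumes conditional independence across cells; correlated
  noise between cells (shared neuropil, co-bursting) will make posteriors
  overconfident without changing the argmax much.
- Cross-session matching is threshold-greedy; in dense fields of view a
  probabilistic model would resolve ambiguous pairs better.
- Head-direction decoding is supported through agreement on direction bins,
  but no dedicated circular error metric is provided.
- The acceleration convention (difference of the 1 s-smoothed velocity) is
  one defensible reading of an under-specified step; users comparing
  against pipelines that difference raw velocity should rescale their bin
  ranges accordingly.
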