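---
title: "Methods: spatial coding and remapping analysis for entorhinal VR recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial coding and remapping analysis for entorhinal VR recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecmap)
```

## Scope

`mecmap` analyzes single-unit recordings from the medial entorhinal cortex
(MEC) of head-fixed mice running on a 400 cm circular virtual-reality (VR)
track. The pipeline covers: behavior preprocessing; per-cell spatial tuning
metrics and dark-running distance tuning with spike-time shuffle nulls;
speed tuning and its stability; functional cell typing (fast-spiking
interneurons, ± speed cells, spatial cells, grid cells, non-grid spatial
cells, conjunctive subtypes); cross-trial similarity and context-remapping
statistics; factorized k-means clustering of trial-by-trial population
spatial maps with model selection and shuffle controls; circular-linear
position decoding; and LFP band power with speed-restricted averaging.
Every stage is testable without recorded data through a seeded synthetic
session generator with ground truth.

Spike sorting, hardware synchronization, mixed-effects/logistic regression
over sessions, and all transcriptomics are out of scope: the package
produces the per-cell and per-session tables such models consume.

## Behavior preprocessing

VR frames arrive at slightly irregular intervals and are resampled to a
uniform 50 Hz grid by linear interpolation. Because the track is circular
(a seamless teleport at 400 cm), positions are first unwrapped to
cumulative distance — trial transitions are recognized as position drops
steeper than −100 cm between consecutive frames — so interpolation never
crosses a teleport; out-of-range raw positions (< 0 or > 400 cm) thereby
land in the neighboring trial's coordinates. Linear interpolation is used
throughout; the resampling target rate (50 Hz) and the track length are
parameters.

Running speed is the frame-to-frame position difference times the frame
rate. Speeds ≤ 5 cm/s or > 150 cm/s are treated as tracking artifacts,
removed, refilled by linear interpolation, and the trace is smoothed with a
Gaussian filter of SD 0.2 samples (reflect padding: a temporal trace has no
circular continuity). All spike-train analyses exclude stationary frames
(speed < 2 cm/s); lick/reward analyses keep them.

Task performance is the fraction of eligible reward zones in which the
animal licked before the automatic delivery point (the zone center).
Reward-triggered licking and slowing profiles average position-binned
(2.5 cm) lick counts and speed from 25 cm before the zone start to the zone
end (75 cm, 30 bins); their magnitudes are the topographic prominence of
the absolute maximum of the mean lick trace and of the inverted mean speed
trace. Contrast sensitivity is estimated by fitting
`y = 1 / (1 + exp(-(x - center)/scale))` to the fraction requested across
opacity bins (bin 0.1), initialized at `center = 0.1`, `scale = 0.002`.
That initialization sits on a near-step sigmoid where least-squares
gradients vanish, so the fit runs a derivative-free simplex pass from the
prescribed start before the Levenberg–Marquardt polish; degenerate inputs
(no response variance) are flagged rather than fitted.

## Spatial tuning metrics

Spatial firing rates are spike counts divided by occupancy in 2 cm bins
(half-open `[left, right)` bins, the package-wide convention), per trial or
trial-averaged. Bins a trial never occupied are set missing and linearly
interpolated before smoothing, avoiding spurious zeros. When smoothed
(SD 4 cm for tuning curves, 5 cm for population tensors), the Gaussian
filter wraps around the track: a trial's spatial vector is circular, and
wrapping preserves the trial mean rate exactly.

* **Coherence** — Pearson correlation between each bin's rate and the mean
  of its 8 nearest bins (computed on the unsmoothed trial-averaged vector);
  ~1 means locally smooth, i.e., strongly spatial firing. The 8 nearest
  bins form a 9-bin window clamped at the track ends.
* **Sparsity** — `sum(P_i R_i^2) / R^2` with `R = sum(P_i R_i)`; 1 for
  uniform firing, `1/P_i` for a single active bin.
* **Information** — `sum(P_i R_i log2(R_i / R))` in bits/s, with
  `0·log 0 = 0`.

Both sparsity and information are undefined (NA) for silent cells.

## Distance tuning, shuffle nulls, and grid scale

Distance tuning is assessed in darkness, where only self-motion cues
remain: the smoothed by-trial rate vectors of the dark trials are
concatenated into one linearized distance series and autocorrelated at lags
up to 800 cm (2 cm steps). The autocorrelation is Pearson-normalized
(mean-removed, variance-normalized, lag 0 = 1) so that the peak criteria
are scale-free. Peak detection reports height, prominence, and width at
half-prominence with the conventions of standard signal-processing
libraries; a qualifying peak needs width > 10 cm, height > 0.1, prominence
> 0.15.

The null model circularly shifts spike times by offsets drawn uniformly
from [20 s, session end], preserving count and interval structure. A cell
is distance-tuned when it has a qualifying peak and the maximal peak's
prominence is **greater than or equal to** the 99th percentile of the
shuffle autocorrelation heights at that lag (100 shuffles; percentiles use
linear interpolation between order statistics — with n = 100 the 99th
percentile sits between the two largest values, so the interpolation rule
materially defines the threshold). Grid scale is the lag of the **first**
(not largest) peak passing relaxed criteria (width > 8 cm, height > 0.05,
prominence > 0.05). Unit depth is the probe insertion depth minus the
median spike distance from the tip.

## Speed tuning

Instantaneous rate is the Gaussian-smoothed frame spike-count series
divided by the frame duration. The smoothing SD is specified as 40 cm of
track and converted to time as `40 / mean running speed` (exposed as
`kernel_sd_cm`, with a direct `kernel_sd_s` override): the distance-unit
kernel inherited from prior work is interpreted as "the time to cover
40 cm at this session's pace". The speed score is the Pearson correlation
of rate with speed over running frames (slope/intercept by least squares).
Stability variants are spike-weighted averages `sum(n_i p_i)/n` of scores
computed within five 80 cm track sections or within single trials; strata
with no spikes or undefined scores drop out. Note that a purely
multiplicative per-trial rate jitter cannot reduce per-trial scores
(Pearson correlation is scale-invariant), but it does decorrelate rate
from speed at the session level; the generator-based tests therefore track
degradation through the session speed score.

## Functional cell typing

Quality control removes units with SNR < 1, rate < 0.1 Hz, negative
repolarization slope, > 3200 µm from the probe tip, halfwidth > 0.30 ms,
or ≤ 350 spikes; sessions with < 10 surviving cells are flagged. Putative
fast-spiking interneurons have waveform duration < 0.35 ms **or** mean rate
> 40 Hz; the rest are putative excitatory cells.

Typing decisions follow the quoted threshold semantics literally: speed
cells require both |speed score| and |speed stability| to **strictly
exceed** the 99th percentiles of their absolute shuffle distributions;
spatial cells require coherence and sparsity to strictly exceed theirs
(computed on Block A trials in the two-context task, keeping
context-driven firing changes out of the metric); distance tuning uses
greater-or-equal. Grid cells are excitatory, distance-tuned, with dark
mean rate > 0.05 Hz, overall rate ≥ 0.3 Hz, and a trial-averaged firing
noise ratio (SEM/mean per context) ≤ 0.45 — exclusion fires if **either**
context exceeds it, the stricter reading of the artifact filter. NGS cells
are spatial cells that are not distance-tuned. Sessions without dark
trials cannot type grid/NGS cells and are flagged.

## Cross-trial similarity and remapping statistics

The population tensor stacks smoothed (SD 5 cm) per-trial rate maps of all
cells and min-max rescales each cell to [0, 1] (silent cells stay zero),
preventing high-rate cells from dominating population analyses. Dark and
gain trials are excluded; alternation trials can be stably sorted by
context (chronological order within context — this choice affects which
trials are "neighbors" in stability windows and is exposed as an option);
tensors can be restricted to the front or back track half.

Cross-trial matrices are Pearson correlations of per-trial spatial vectors
(the normalized zero-lag cross-correlation after mean subtraction —
mathematically the same thing, stated here because the normalization is
otherwise ambiguous). Zero-variance trials give missing entries, which are
excluded (not imputed) from all group means. Stability is the mean
correlation with the 5 nearest trials (window truncated at phase edges);
within-map stability averages this within clustered maps having ≥ 2
trials. Context specificity ratios compare matched to mismatched group
similarity (block phase: `mean(AxA, BxB)/mean(AxB)`; alternation:
`mean(AxA', BxB')/mean(AxB', BxA')`); both equal 1 when context-matched
firing is no more similar than mismatched, and are flagged degenerate when
the mismatched mean is not positive (e.g., fully orthogonal maps, whose
mean-centered correlation is negative). Rate remapping is the percent
change of the peak of the trial-averaged normalized vector across blocks;
global remapping is 1 − cosine similarity between the block-mean vectors.
Network-wide similarity correlates flattened bins × cells trial vectors
(requiring > 10 spatial cells in RF or ≥ 10 grid cells in SM);
remapping coordination correlates a unit's matrix with the network matrix
built from the remaining units, over upper-triangle entries. Gain
responses compare within-baseline to baseline × post-gain similarity with
trial-count-matched pre sets.

## Factorized k-means spatial maps

The population tensor is modeled as
`X_hat[i,j,k] = sum_r U[i,r] V[r,j,k]` with one-hot rows of `U` — k-means
clustering of trials in flattened bins × cells space, where each centroid
slice is a spatial map. Optimization is Lloyd iteration with
k-means++-style seeding; each fit takes the best of `restarts` runs by
reconstruction error (the acceptance rule for restarts, where the source
procedure names none). Empty clusters are refilled with the worst-fit
trial. Under speckled holdout, centroid updates use only observed entries
and assignments minimize the mean squared deviation over a trial's
observed entries — stated explicitly because masked fitting changes
results.

Model selection sweeps k ∈ 2..4 with 10 repetitions per k (fresh restarts
each; nothing else is resampled) and picks the k maximizing the mean
silhouette score of trial assignments, with Euclidean distance on
flattened trial vectors (the silhouette metric is otherwise unspecified;
Euclidean matches the k-means objective). Whether the session supports any
multi-map structure is decided separately: 10% of tensor entries are
censored in a speckled pattern, the masked model's uncentered test R² is
averaged over 10 replicates, and compared against the same procedure on a
rotation-shuffled tensor (random orthogonal matrix applied across trials —
norm- and feature-covariance-preserving, cluster-structure-destroying)
with a one-sided paired Wilcoxon signed-rank test at α = 0.05; failure to
reject flags a one-map session, in which case k = 1 is used. A
rank-matched truncated SVD (EM imputation over the same masks) provides
the discreteness comparison: comparable test R² of the more constrained
k-means model indicates genuinely discrete maps.

Map labels are canonicalized (SM: map 1 has the most Block A trials, then
map 2 the most Block B among the rest; for k = 4, map 3 is the remaining
map with more trials before the midpoint of the context-sorted
alternation phase; ties go to the lowest raw label. RF: maps ordered by
mean running speed, slowest first). Context identities assign map 1 → A,
map 2 → B, and extra maps to the block they resemble more in mean network
similarity (ties → A, with a warning). Remaps are label changes between
consecutive chronological trials; remap frequency divides the count by
the phase's trial count; context alignment is the fraction of trials
whose map identity matches the VR context (chance 0.5 under independent
binary assignment).

## Circular-linear decoding

Track position maps to an angle `y = position/400 · 2π`. The decoder
predicts `y_hat = atan2(sum_n b1_n s_nt, sum_n b2_n s_nt)` from population
spike counts with one coefficient pair per neuron. Coefficients are
initialized by ridge least squares of `(sin y, cos y)` on counts and
refined by BFGS maximization of the mean cosine of the angular error with
ridge 1e-6, tolerance 1e-6, and at most 500 iterations (the cited source's
EM updates live in an external reference; this objective-equivalent
optimizer is deterministic given the data, and the pure least-squares fit
remains available as `refine = FALSE`, cross-checked on synthetic data).
Time bins with all-zero counts have undefined predictions and are excluded
from scoring. The decoder score is `mean(cos(y - y_hat))`: 1 for perfect
prediction, 0 in expectation for random circular guesses. Evaluation fits
on a random 90% of running time bins and scores the held-out 10%, over 10
repetitions, against a control in which each neuron's count series is
independently circularly shifted in time (chance performance). Because
single 20 ms frames are too sparse to decode, counts are aggregated into
200 ms bins (`bin_decoding_data()`, 10 frames), with circular-mean angles.
Optional down-sampling matches training sets drawn from the same session
by greedy per-stratum subsampling over position-bin × speed-quartile
strata.

## LFP band power

The analysis channel is the one with the highest theta power among the 200
channels closest to the probe tip that recorded at least one good cell.
Band power (theta 6–12 Hz, slow gamma 20–50 Hz, fast gamma 50–110 Hz) is
integrated from a multitaper spectrogram with 0.5 s windows (2 Hz power
traces) using 5 sine tapers (time–bandwidth ≈ 3; taper family and count
are exposed because they set the spectral concentration: at 0.5 s windows
the half-bandwidth is ~6 Hz, so narrow-band lines leak slightly outside
the 6–12 Hz theta band at the default). Session spectra use Welch's
method (2 s Hann segments, 50% overlap — the segment length is not fixed
by the source and is a documented default). Power traces are upsampled to
50 Hz with cubic spline interpolation (R has no quadratic-spline
interpolator; on smooth 2 Hz traces the difference is negligible) and
averaged over frames with speed in [20, 40] cm/s inclusive, controlling
for running-speed differences between groups.

## The synthetic generator

`synth_config()` encodes the study conditions as defaults: 400 cm track at
50 Hz; SM sessions with 20 dark trials, 60-trial blocks of contexts A and
B, 80 pseudorandomly alternated trials whose last 20 run at VR gain 0.7
(gain trials are flagged and excluded from population tensors, matching
the analyses); RF sessions with ~200 invariant-context trials. The context
of each alternation trial is a seeded uniform draw over {A, B}, mirroring
the task engine's per-teleport random draw rather than a balanced shuffle.
Running speed is a smoothed positive autoregressive process clipped to
(2, 150) cm/s (mean 40, innovation SD 10 cm/s — typical head-fixed running
— chosen once so that stationary filtering and speed-artifact cleaning
have realistic work to do). Licking is simulated so that a configurable
fraction of reward zones (default 0.8) is requested before the automatic
delivery point.

Spikes are drawn per 20 ms frame from an inhomogeneous Poisson process
(counts `rpois(λ·dt)`, times uniform within the frame). Archetypes: grid
cells with von Mises bump trains — anchored to track position (landmarks)
in the light, to cumulative distance (path integration) in darkness, with
scale drawn from {40, 60, 80, 100} cm; non-grid spatial cells with two
Gaussian place fields (flat in darkness); ± speed cells, linear in speed;
fast-spiking interneurons at ~45 Hz with weak speed modulation (satisfying
the IN waveform/rate signature in the metadata); and untuned cells at 3 Hz.
Context-B maps are phase-shifted copies of context-A maps (global
remapping), with the shift drawn per unit. The population map label per
trial follows either the context (switching with `remap_probability` at
context switches; probability 1 reproduces context-locked remapping) or an
independent per-trial toggle (`remap_mode = "random"`), which decouples
maps from context for chance-alignment controls. Controllable noise:
per-trial log-normal rate jitter (`rate_noise`, default 0.1) and a
per-trial random walk of field positions (`drift_sd`, default 0 cm) —
drift is the "tuning noise" axis used in the noise-sensitivity tests,
since it degrades both trial-averaged coherence and decodability, whereas
multiplicative jitter leaves spatial shapes intact.

What the generator does **not** emulate: 2-D open-field firing,
theta-phase dynamics, head-direction/border/object-vector cells,
electrode drift, sorting artifacts, bursting/refractory spike statistics,
or behaviorally correlated lick/speed artifacts. Passing tests therefore
demonstrate correctness of the estimators and decision rules under the
assumed generative structure, not robustness to every failure mode of
recorded data.

## Test problem sizes

The suites run at sizes chosen to keep each property decisive yet quick:
recovery tests use sessions of ~10–40 trials and 1–22 cells; the typing
calibration uses 500 untuned Poisson cells on a shared 15-trial session
with 100-shuffle nulls per statistic; model-selection recovery uses 100
seeded 24-trial tensors; alignment recovery uses 76-trial SM sessions
with 16 grid cells (10 restarts, 3 repetitions — the full 100-restart,
10-repetition setting remains the function default). Seeds are fixed in
code; every stochastic routine takes an explicit seed.

## Known limitations

* Grid cells are one-dimensional distance/position-periodic processes; no
  2-D gridness is computed.
* The decoder represents only first-harmonic structure per neuron pair;
  strongly periodic populations without spatial cells decode poorly (and
  the noise-sensitivity tests therefore use spatial-cell populations).
* The Wilcoxon one-map test needs ≥ 5 CV replicates to be meaningfully
  powered; fewer replicates are flagged.
* `q99` from 100 shuffles has sampling noise of a few percentile points;
  classifications near the threshold are correspondingly uncertain.
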