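---
title: "Methods: quantifying ketamine's disruption of entorhinal and hippocampal spatial coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ketamine's disruption of entorhinal and hippocampal spatial coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketamap)
```

## The scientific problem

Sub-anesthetic ketamine produces dissociation and spatial-memory
impairments. The medial entorhinal cortex (MEC) and hippocampus contain
the brain's spatial map — grid cells, other spatially stable cells, and
place cells — so a natural question is what ketamine does to that map at
the level of single cells, cell pairs, whole populations and behavior.
`ketamap` implements an analysis pipeline for recordings designed around
that question: head-fixed mice running a 400 cm looped virtual-reality
(VR) track while MEC spiking is recorded, with a saline ("control")
injection after trial 50 and a ketamine injection after trial 100; and
freely moving mice whose CA1 population is imaged with a miniscope over
four daily open-field sessions (baseline, baseline, ketamine,
post-baseline).

The package is organised as the experiment is: a behavior module, a
single-cell spatial-coding module, a monosynaptic-connectivity module, a
population-state (decoherence) module, a remapping module, a position
decoder, an LFP band-power module, a hippocampal calcium module, and a
synthetic-session generator that produces all of these inputs with known
ground truth.

## Synthetic sessions are the test bed

No recorded data ships with the package. Every analysis stage is instead
validated against `simulate_vr_session()`, `simulate_connected_pairs()`,
`simulate_openfield_calcium()` and `simulate_lfp()`, whose defaults
encode the study conditions:

* 300 trials on a 400 cm track — baseline trials 1–50, control 51–100,
  ketamine 101–290, visual gain-change 291–300 — behavior sampled at
  50 Hz;
* excitatory cells with 1–3 Gaussian spatial fields (SD 8–20 cm, peaks
  3–10 Hz over a 0.5 Hz floor) and ~10% high-rate (18–30 Hz)
  interneurons;
* running at 30 ± 5 cm/s with 2× slowing in the reward zone before
  ketamine, abolished slowing and a 0.8× overall speed after;
* licks concentrated near the reward tower before ketamine and uniform
  after;
* a ketamine effect modeled as a transient *decoherence state*: starting
  4 min after the injection and lasting 18.6 min (the mean duration
  reported for the recorded sessions), each cell's tuning is flattened
  to its spatial mean and multiplied by a rate gain (default 1.5);
  afterwards field centers are circularly shifted ("remapping");
* spiking is inhomogeneous Poisson given tuning and position, suppressed
  below 2 cm/s so the analysis-side speed filter is exercised.

The generator deliberately omits several features of real data: no
theta-phase spike timing, no slow drift or probe instability, no
behavioral states other than running, no sorting artifacts, and
decoherence onset/offset are sharp rather than pharmacokinetically
graded. Passing tests therefore certify the *analysis logic* — binning,
filtering, nulls, detection gates, estimators — under controlled
conditions, not performance on raw recordings.

Two generator calibrations were genuinely open and are worth recording.
First, inhibitory connections are simulated by *thinning* the
postsynaptic train in the 1–5 ms window (excitatory ones by spike
insertion at 1–3 ms); thinning was chosen because the expected
cross-correlogram deficit is then analytically equal to the efficacy,
which gives the transmission-probability estimator an exact oracle.
Second, the calcium generator's default peak event rate (2.5 Hz over a
~0.05 Hz floor, fields of SD 4 cm by default) was set so that place-cell
mean event rates sit comfortably above the 0.1 Hz classification floor
— consistent with that floor being roughly the 5th percentile of the
recorded rate distribution. At lower peak rates half the simulated place
cells straddle the floor and the classifier's behavior reflects the
floor, not spatial tuning.

## Behavior

`preprocess_position()` resamples the variable VR frame rate to 50 Hz by
linear interpolation (after unwrapping teleports so interpolation never
crosses the seam), wraps positions into [0, 400), marks trial boundaries
where the per-step position difference is below −100 cm, and estimates
speed as the forward difference divided by the frame interval, first
sample copied from the second, smoothed with a Gaussian kernel.

The speed-smoothing width is stated ambiguously in the source methods
(0.2 time bins in one place, σ = 0.2 s in another); the package adopts
**0.2 s** and exposes it (`speed_smooth_sd`), since 0.2 time bins = 4 ms
would be indistinguishable from no smoothing.

`lick_accuracy()` scores a lick as accurate within 50 cm of the reward
tower at 400 cm using *circular* distance, so licks just after the
teleport (e.g. at 30 cm) count as near-reward; whether the original
analysis wrapped at the seam is unstated, and the circular choice is the
conservative one on a seamless track. Trials without licks score 0.

## Single-cell spatial coding

`compute_rate_map()` bins each trial into 2 cm bins and divides spike
counts by dwell time, with all periods below 2 cm/s removed from both
numerator and denominator *before* binning (the speed filter applies to
spikes and occupancy alike). Never-occupied bins are `NA`, not 0 Hz.

Three per-cell metrics follow:

* **Spatial information** (bits/s, `spatial_information()`): the Skaggs
  rate `I = Σᵢ pᵢ λᵢ log₂(λᵢ/λ̄)`; zero-rate bins contribute zero, and
  occupancy-0 bins are excluded rather than imputed.
* **Stability** (`stability_score()`): trial curves smoothed with a
  circular Gaussian (SD 2 cm), max-normalised, Pearson-correlated with
  both neighbors and averaged (one neighbor at the ends).
  "Normalisation" is read as per-trial max-normalisation; Pearson
  correlation is scale-invariant, so this choice is inert and documented
  only for reproducibility.
* **Crest factor** (`crest_factor()`): peak over RMS of the tuning curve
  — 1 for flat curves, √N for a single active bin; scale-invariant.

`classify_cells()` applies the study's thresholds: interneurons have
mean rate > 15 Hz; spatial cells are excitatory with baseline stability
> 0.2; putative grid cells additionally require mean baseline spatial
information > 3 bits/s and decorrelation (r < 0.2) between tuning on the
0.5× visual-gain trials and the last normal trials — the gain
manipulation dissociates path integration from visual landmarks, to
which grid cells are preferentially sensitive.

`field_width()` averages a 50-trial block into a tuning curve, rotates
each trial row circularly (uniform offset, minimum 5 bins — the source
says only "spatially shuffled", and independent per-trial rotation is
the variant that actually perturbs the block average) 1000 times, takes
the 80th percentile of shuffled peak heights as the detection threshold,
and reports the maximum width at half the detected peak's height above
zero.

## Monosynaptic connectivity

`detect_monosynaptic_pairs()` builds 1 ms cross-correlograms and flags a
pair excitatory/inhibitory when any bin in the 5 ms after a presynaptic
spike exceeds/falls below the pointwise 99% CI of 1000 temporal shuffles
of the postsynaptic train. Two unstated choices, both documented and
measured rather than assumed:

* the shuffle permutes the follower's inter-spike intervals — the
  strongest rate- and ISI-marginal-preserving null that needs no extra
  parameters (a jitter scale, for instance);
* the CI is pointwise per bin, as worded, not family-wise; the implied
  null flag rate (≈ 2 × (1 − 0.995⁵) ≈ 5% before count discreteness) is
  *measured* on 200 simulated independent pairs in the acceptance suite.

`transmission_probability()` normalises each 10 s window's correlogram
by the presynaptic spike count and subtracts the −5..−1 ms mass from the
+1..+5 ms mass, cancelling follower rate changes that are independent of
the reference cell; on the generative models above its expectation
equals the configured efficacy, which the tests verify for efficacies
0.1–0.9.

## The decoherence state

`temporal_rate_matrix()` bins spikes (0.02 s at full resolution) and
smooths each cell's rate with a 0.2 s Gaussian (the smoothing width is
unstated in the source; 0.2 s is the package default and configurable).
`embed_and_cluster()` embeds the time bins with UMAP (n_neighbors 15,
2 components, Euclidean metric, min_dist 0.3) and clusters the
embedding with DBSCAN. Two parameterisations were open:

* the source names both DBSCAN and HDBSCAN; DBSCAN is implemented (in
  package, grid-accelerated for 2D) as the parameterised variant, with
  ε defaulting to the knee of the 50-NN distance curve and
  min_samples = 50; the resolved values are recorded in the result;
* clustering is described once as operating in a "three-dimensional
  embedding space" while the printed parameter list says
  n_components = 2; both are exposed, with 2 as the default per the
  printed parameters.

`identify_decoherence_period()` takes the first cluster whose contiguous
span (gaps ≤ 5 s merged) exceeds 1 min and starts 2–15 min after the
ketamine injection; when nothing qualifies it returns `NULL`, mirroring
sessions without a detectable state.

For long sessions the pipeline defaults to 0.2 s bins ("desk scale") so
that a full 300-trial session embeds in about a minute; the acceptance
suite uses 0.5 s bins on 30–120-trial sessions. On those synthetic
sessions the recovered interval overlaps the injected 10-min state with
Jaccard ≥ 0.9, and the detector stays silent on null sessions in ≥ 90%
of seeds.

## Population structure and remapping

`cellpair_correlations()` computes Pearson correlations between the
smoothed temporally binned rates of all pairs of spatially stable cells,
separately per epoch (baseline 1–50, control 51–100, acute ketamine
101–150, late ketamine 251–290, gain change 291–300; epoch membership of
a time bin follows its trial). Pairs qualify when their baseline
correlation is significant at p < 0.05. The session statistic ⍴
correlates the vector of pair-correlations between two epochs: it stays
near 1 when the co-firing structure is preserved (including under
tuning flattening with preserved co-fluctuations, and under the gain
change) and collapses only when per-cell fluctuations decouple — the
attractor-network signature the analysis targets.

`trial_similarity_matrix()` concatenates all cells' trial × position
maps into a population matrix and correlates trials pairwise
(pairwise-complete over occupied bins). `baseline_template_correlation()`
correlates each trial against each cell's mean baseline tuning. The
source notation is per-cell (corr(bᵢ, Aᵢ[aⱼᵀ])), so the per-cell
correlation averaged over cells is the default, with the concatenated
population vector as an option; within the baseline epoch the template
is recomputed leave-one-trial-out so baseline scores are not inflated.
Because single-trial maps are Poisson-noisy, per-trial template
correlations are modest (~0.3) even pre-drug; remapping appears as the
*sustained drop* of that score after the decoherence state, quantified
by `remap_difference()` (mean of 25 trials before the injection minus 25
after).

## Position decoding

`fit_position_decoder()` z-scores each cell on baseline statistics
(frozen thereafter — test-time rate surges legitimately push population
vectors off the encoding manifold, they are not renormalised away) and
averages the z-scored population vector within each 2 cm bin, defining a
200-point encoding trajectory. Decoding (`decode_position()`) assigns
each test vector the trajectory point of minimum Euclidean distance
(ties to the lowest bin index, deterministically); this trajectory
readout is the default because it is the step the source methods use to
produce decoded positions. An L2 multinomial-logistic readout (inverse
strength C = 0.03, ridge path via glmnet) is available as
`mode = "logistic_argmax"`. The "trained 50 times dropping 1" phrase is
read as a leave-one-trial-out jackknife (`baseline_decoder_rmse()`);
drop-one-cell is the noted alternative.

`circular_rmse()` uses the shortest way around the loop, so errors are
bounded by 200 cm and the chance level under uniform occupancy is
400/(2√3) ≈ 115.5 cm — both verified by closed form in the tests.

## LFP band power

`band_power()` computes a multitaper spectrogram on non-overlapping 1 s
windows (DPSS tapers, NW = 2, 3 tapers — the taper parameters are
unstated in the source and these are the conventional defaults for a
1 s window), integrates 5–11 Hz (theta) or 50–110 Hz (fast gamma), and
z-scores to the baseline epoch's mean and SD. The DPSS sequences are
computed from the standard symmetric tridiagonal eigenproblem
(shift-invert above the Gershgorin bound), cached per window length.
`velocity_matched_resample()` re-draws, for each baseline second, the
paired-epoch second with the closest mean running speed (absolute
difference, ties to the first index), removing power differences that
merely track speed. `welch_psd()` and `select_channel()` (highest theta
power) cover QC and channel selection.

## Hippocampal calcium analysis

`binarize_events()` thresholds each deconvolved trace at 3 × its SD
(computed over the whole trace, zeros included, as specified — so the
threshold scales with the trace). `rate_map_2d()` bins events per second
into 1.75 cm square bins of the 36 cm circular arena (speed < 2 cm/s
excluded, out-of-arena bins masked) and smooths with a 2D Gaussian of
SD 2 bins. Information scores use the *raw* map with a 0.1 s occupancy
floor — whether the original used smoothed or raw maps is unstated, and
raw maps keep the shuffle null exact — while spatial correlations use
the smoothed maps.

`place_cell_test()` compares the cell's information against the 95th
percentile of 1000 circular time-shifts of its event train (minimum
shift 20 s, so the shift actually breaks position coupling) and
additionally requires a mean event rate ≥ 0.1 Hz.
`position_matched_downsample()` equalises spatial sampling between two
sessions bin by bin (the session with more frames randomly drops frames
and their events), recomputes mean/peak rate, information and the
between-session spatial correlation on each of 50 draws, and averages —
always pairwise, never across more than two sessions at once.

## Orchestration and cohort statistics

`run_pipeline()` runs every stage on a session container (skipping LFP
with a notice when absent), writes per-stage CSVs and a JSON summary,
and is deterministic given its seed. `aggregate_sessions()` produces
across-session means ± SEM per epoch metric and two-sided Wilcoxon
matched-pairs signed-rank tests between epochs with Šidák correction,
sessions being the pairing unit; degenerate comparisons (identical
values) are reported as `NA` rather than invented.

Connectivity inside the pipeline is capped (`conn_max_cells`, default
12, 200 shuffles) because all-pairs detection with a 1000-fold shuffle
null is quadratic in cell count; the standalone
`detect_monosynaptic_pairs()` has no such cap.

## Numerical conventions and degenerate inputs

* Positions live in half-open [0, 400); bin k covers [2k, 2k+2); ties
  and ambiguities resolve toward the lower index everywhere.
* Gaussian smoothing is FIR, truncated at 4 SD, renormalised at edges,
  circular for spatial tuning curves, and `NA`-aware (missing bins are
  renormalised out, never treated as zeros).
* All-zero tuning curves make the crest factor undefined (an error, not
  a number); zero-variance trials yield `NA` stability and are excluded
  from means; cells without baseline variance are excluded from the
  decoder and recorded.
* Every stochastic routine takes an explicit seed; one master seed
  derives per-component streams, and identical seeds reproduce sessions
  bit for bit.

## Problem sizes

The test and acceptance runs use deliberately scaled synthetic problems,
chosen as the smallest sizes at which each statistical property is
well-powered: 30–120-trial VR sessions with 10–30 cells for recovery
tests, the full default 300-trial/40-cell session for the end-to-end
acceptance run, 100–200 independent pairs for null calibration of the
connectivity detector, 10-minute calcium sessions with 12–15 cells, and
0.5 s embedding bins for sessions analysed in the test suite.

## Known limitations

* The decoherence detector's boundaries are quantised to the embedding
  bin width, and its ε heuristic assumes the embedding separates states
  by a margin; heavily drifting recordings may need a manual ε.
* ⍴ comparisons require ≥ 2 significantly correlated baseline pairs and
  are reported only for sessions with enough stable cells, as specified.
* The generator's decoherence is a step change; onset-latency estimates
  from real, pharmacokinetically graded data will be softer than the
  synthetic recovery suggests.
* Deposit-based benchmarks against the recorded dataset require a
  download and are outside the offline test surface.
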