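---
title: "Source-level high-gamma EEG mapping: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-level high-gamma EEG mapping: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgmap)
```

## The problem

High-gamma (HG, 70–150 Hz) activity is a focal, fast signature of engaged
cortical populations, classically measured with invasive electrodes because
scalp EEG attenuates it badly and muscle activity overlaps its whole
spectral range. `hgmap` implements a pipeline for recovering HG activity
non-invasively: cue-locked EEG trials are decomposed with complex Morlet
wavelets, projected onto a cortical source space with an LCMV beamformer,
summarized as baseline-normalized amplitude Z maps, and tested with a
maximum-statistic permutation test that controls the family-wise error over
time, frequency and space jointly. A companion module quantifies the
spatial agreement between the EEG HG map and an fMRI activation map on the
same cortical mesh, with a resampling significance test.

Because the recordings the method targets are not redistributable, the
package ships a synthetic-session generator with full ground truth, and
every statistical claim in the test suite is made against that generator.

## The model chain

**Forward model.** A leadfield $G$ (channels × sources) gives the scalp
potential per unit dipole moment. The simulated leadfield places sources on
a sphere-like triangle mesh (radius 70 mm, ±2 mm seeded jitter) inside a
sensor shell (95 mm, Fibonacci lattice) and evaluates the
infinite-homogeneous-medium current-dipole potential
$V = \mathbf{p}\cdot(\mathbf{r}-\mathbf{r}_0)\,/\,(4\pi\sigma|\mathbf{r}-\mathbf{r}_0|^3)$
with the dipole oriented along the outward vertex normal. This preserves
the spatial structure that matters at desk scale (nearby sources project
similarly; amplitude falls with distance); realistic boundary-element
leadfields can be supplied through the same `leadfield()` constructor.
Orientation is fixed, matching the scalar beamformer: one weight row per
source.

**Beamformer.** With broadband channel covariance $C$ pooled over whole
retained trials (per-trial means removed), the LCMV weight row for source
$v$ with leadfield column $l_v$ is
$w_v = C_r^{-1} l_v / (l_v^\top C_r^{-1} l_v)$, where
$C_r = C + \lambda\,\overline{\mathrm{diag}(C)}\,I$. The unit-gain
constraint $w_v^\top l_v = 1$ is enforced to $10^{-6}$ and tested. Whether
the covariance should come from baseline only or the whole trial is an
open choice; whole-trial pooling is the default because it is the more
stable estimate at 20–100 trials, and the window is a visible argument of
`broadband_covariance()`.

**Time–frequency.** Complex Morlet kernels with
$\sigma_t = n_\mathrm{cycles}/(2\pi f)$, truncated at $\pm 4\sigma_t$,
amplitude-normalized so a unit passband tone yields unit coefficient
magnitude. Defaults: `n_cycles = 7` for the 70–100 Hz grid in 1 Hz steps
(spectral SD $f/7 \approx 11$ Hz — the compromise between the 1 Hz grid
and the 0.3–1.0 s effect window), 5 for the 15–35 Hz beta band. Samples
within one kernel half-width of a trial edge are carried in a validity
mask and the baseline/signal windows are required to be fully valid —
edge-contaminated samples are never silently zeroed.

**Amplitude maps and Z-scoring.** Source coefficients are $j_i = T d_i$
per trial; the map is the plain sum $a(t,f) = \sum_i |j_i(t,f)|$ (the
power twin $p = \sum_i |j_i|^2$ is kept alongside). Amplitudes rather than
powers reduce outlier sensitivity; the sum is kept literally as written —
no $1/N$ — because the baseline Z-score
$z = (a - \mu_b)/\sigma_b$ cancels any positive scale. $\mu_b, \sigma_b$
are the mean and $(n-1)$-denominator SD of $a$ over the baseline window
$[-1, 0)$ s. Zero-SD locations are marked invalid and reported, never
silently dropped.

## Inference

**Maximum-statistic permutation test.** Under the null hypothesis the
baseline second and the signal second $[0, 1)$ s are exchangeable within a
trial. Each permutation swaps the two segments in a uniformly random
$\lfloor N/2 \rfloor$-trial subset and recomputes the Z map and its
maximum over signal times, the 70–100 Hz grid, and all sources. Taking the
maximum jointly over all three axes means the add-one p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + B)$ needs no further
multiple-comparison correction. Swapping is performed on source-domain
coefficient magnitudes: because the average is over $|j_i|$ and both the
wavelet and the beamformer are linear and time-local outside the swap
windows, this equals swapping the raw segments before averaging, at
roughly $B$-fold lower cost. The swap is an involution and conserves the
per-trial multiset of segment values — both are asserted in the tests.

The test is also robust to single outlier trials: an outlier's inflated
signal segment enters roughly half of the permutations' signal windows, so
the null maxima rise together with the observed maximum. Quantitatively,
the observed statistic is exchangeable with the non-swapping half of the
permutations, making p approximately uniform on $(0, 1/2]$ for an extreme
outlier — large on average, though not guaranteed above any fixed level;
the property test asserts the derived expectation (about 90% of p-values
above 0.05) minus three binomial standard errors.

**Per-vertex p-values.** For cluster extraction each vertex's own maximum
Z over the signal window is compared against the *global* null histogram.
This is one interpretation of per-vertex significance under the joint
test — conservative for non-peak vertices — and is stated as such in the
documentation.

**Peak frequency.** The frequency readout uses the relative
amplitude-change (ERS ratio) spectrum at the peak vertex: mean
signal-window amplitude over mean baseline amplitude per frequency,
`peak_frequency()`. The alternative — the frequency of the maximum Z —
inherits the sampling error of the per-frequency baseline SD, and with a
1-s baseline the Morlet envelope autocorrelation leaves only ~10 effective
degrees of freedom, a session-level error that does not average out with
trials (measured: ~2.4 Hz SD at both 25 and 100 trials per hand). The
ratio spectrum involves only baseline means and recovers the simulated
burst center exactly in the recovery study below. The Z map remains the
localization and significance statistic.

**EMG/EOG monitoring.** Transient muscle or ocular bursts are handled by
the permutation test itself (they are as likely to land in baseline as in
signal), but *task-locked* contamination would pass it. The monitor
computes the 70–100 Hz Hilbert envelope of each EMG/EOG channel
(`hg_envelope()`: zero-phase Butterworth band-pass, then analytic-signal
magnitude) and subjects the trial-summed envelope to the same
maximum-statistic segment-swap test, one channel at a time
(`permutation_null()` accepts plain magnitude arrays for exactly this).
A significant EMG/EOG envelope increase in the signal window marks the
condition as contaminated. How such envelopes should enter the source
analysis is ambiguous in the source literature; per-channel p-values are
this package's stated interpretation.

**EEG–fMRI proximity.** Supra-threshold vertices (fMRI: $Z > 2.3$; EEG:
permutation $p \le 0.1$) are grouped into contiguous clusters under mesh
edge adjacency. Each cluster is summarized by its centroid and mean
spherical radius; a cluster pair's distance is the centroid separation
minus both radii, floored at zero on overlap. Each fMRI cluster takes its
nearest EEG cluster; if fMRI clusters outnumber EEG clusters only the
smallest distances are kept, and the compound measure is their median.
Distances are 3-D Euclidean, not geodesic — a deliberate simplification,
adequate because the measure is dominated by gross mismatches of several
centimeters. Significance: fMRI clusters are relocated to random mesh
positions as connected patches of identical vertex count (breadth-first
growth with uniformly random frontier picks — count and size are fixed,
shape is free, and BFS patches are the simplest connected choice), 1000
resamples by default, add-one p with ties counting against rejection.
Resample placement does not exclude the original location; with meshes of
hundreds of vertices the self-overlap probability is negligible and
excluding it would bias the null away from exchangeability.

**Group maps.** Vertex-wise means across subjects on a shared mesh. The
mean of $n$ independent standard-normal Z maps has SD $1/\sqrt{n}$, so the
group threshold equivalent to a single-subject threshold $z_1$ is
$z_1/\sqrt{n}$: for $z_1 = 2.3$ and $n = 10$, `equivalent_group_threshold()`
returns 0.727 (0.72 at two printed decimals), and $\Phi(2.3) = 0.989$,
i.e. a 99% one-sided confidence level to the nearest percent.

## The synthetic-session generator

`sim_config()` defaults mirror the study protocol: 100 trials per hand, 54
channels at 1200 Hz, 5-s trials on $[-2, 3)$ s around the cue. Each trial
contains:

* a **high-gamma burst** at the hand's contralateral source vertex:
  narrowband Gaussian noise (order-2 zero-phase Butterworth band-pass,
  default 6 Hz wide) under a Hann envelope on $[0.3, 1.0)$ s, center drawn
  per source as an integer in 70–96 Hz. `hg_snr` sets the in-band
  amplitude ratio of the projected burst to the channel noise; the study
  does not quantify scalp-level HG SNR, so this is a free parameter with
  default 1.
* a **beta rhythm** (15–35 Hz) at the active source, attenuated by
  `beta_erd_depth` (default 0.3) after the cue with a 0.2-s cosine ramp —
  the classic event-related desynchronization.
* **1/f channel noise**, generated in the frequency domain and spatially
  mixed by a smooth sensor-distance kernel (40 mm Gaussian, 30% identity),
  so the covariance is realistic but well-conditioned.
* optional **broadband artifacts** (20–300 Hz, 0.4 s, 8× channel SD, on a
  quarter of channels) in an `artifact_rate` fraction of trials, recorded
  in the ground truth; and **EMG/EOG channels** with optional task-locked
  HG contamination (`emg_task_snr`, default 0).

One master seed drives everything; per-trial substreams are derived
deterministically, so sessions are pure functions of `(config, seed)`.

What the generator does *not* emulate: realistic head-tissue conductivity
(BEM), electrode-placement error and coregistration error, non-stationary
background rhythms, eye-movement topographies, or spatially extended
patch sources. Passing tests therefore demonstrate the statistical
machinery — calibration, localization at a given SNR, robustness — on a
favorable but structurally faithful forward model, not performance on real
recordings.

Matched fMRI maps (`simulate_fmri_map()`) are Gaussian blobs (8 mm spatial
SD, peak Z = 4) at the true source vertices plus well-separated distractor
blobs (Z = 3.5) and optional vertex noise, so thresholding at $Z > 2.3$
yields exactly one cluster per blob in the noiseless case.

## Numerical and problem-size choices

* **Decimation.** Wavelet amplitude envelopes at `n_cycles = 7` are
  band-limited near $f/n_\mathrm{cycles} \approx 10$–14 Hz, so `hg_fit()`
  stores them on a decimated grid (largest divisor of `fs` keeping at
  least 50 Hz by default; the validation studies below use a 25 Hz grid).
  `morlet_transform()` itself does not decimate unless asked.
* **Windowed analysis.** `hg_fit()` restricts the transform to
  $[-1, 1)$ s plus kernel margins by default; memory then scales with
  sources × frequencies × window samples, independent of trial length.
* **Regularization.** `reg_lambda = 0.05` of the mean covariance diagonal;
  the source literature offers no single value, and the unit-gain
  invariant is checked after regularization.
* **Ties.** The maximum statistic breaks ties by lowest (vertex,
  frequency, time) index; add-one p-values make $p = 0$ impossible and
  count null ties against rejection.
* **Degenerate inputs.** Zero baseline SD marks the location invalid with
  a message; an empty cluster side yields an NA proximity with a reason
  (mirroring a subject/condition with no significant activity); cues too
  close to the recording edge are dropped and reported.

The statistical validation in `tests/testthat/test-acceptance.R` uses
these problem sizes, chosen so each study carries real evidence while the
whole suite stays desk-scale: type-I calibration on 200 null sessions
(20 trials × 20 channels × ~50 sources at 400 Hz, 199 permutations);
source recovery on 20 sessions at `hg_snr = 2` (25 trials/hand, 24
channels, ~80 sources); proximity specificity on 20 overlapping subjects
(single-vertex EEG cluster inside the true fMRI cluster, two distractors,
999 resamples — a pointlike EEG cluster keeps the chance of accidental
overlap under random relocation near 1% on a ~400-vertex sphere) and null
calibration on 200 random-placement subjects (99 resamples). At
400 Hz the 70–100 Hz grid, the 100–150 Hz artifact band and the simulated
20–180 Hz artifact bursts all sit below Nyquist.

## Worked example

```{r example, eval = FALSE}
fwd <- make_mesh_and_leadfield(n_vertices = 80, n_channels = 24, seed = 1)
cfg <- sim_config(n_trials_per_hand = 25, n_channels = 24, fs = 400,
                  hg_snr = 2, artifact_rate = 0.05, seed = 2)
ses <- simulate_session(cfg, fwd$mesh, fwd$leadfield)

flagged <- detect_artifact_trials(ses$trials)
fit <- hg_fit(flagged$trials[flagged$trials$labels == "right"],
              fwd$leadfield)
print(fit)
test <- hg_perm_test(fit, n_perm = 999, seed = 3)
print(test)
peak_frequency(fit)

# EEG clusters at p <= 0.1 vs the matched fMRI map of the same condition
pv <- vertex_pvalues(fit, test)
eeg_cl <- extract_clusters(pv, fwd$mesh, 0.1, mode = "p")
fmri <- simulate_fmri_map(fwd$mesh, ses$truth$source_vertex_ids[["right"]],
                          extra_clusters = 2, seed = 4)
fmri_cl <- extract_clusters(fmri, fwd$mesh, 2.3, mode = "z")
resample_significance(fmri_cl, eeg_cl, fwd$mesh, n_resamples = 999, seed = 5)
```

Note the compound measure deliberately penalizes unmatched activity: when
distractor fMRI clusters outnumber the EEG clusters, their distances enter
the kept set and inflate the median, so widespread fMRI activity with a
focal EEG map yields a large compound and weak specificity even when the
primary pair overlaps.

## Known limitations

* The scalar beamformer assumes the forward orientation is right; a
  max-power orientation search is not implemented.
* Per-vertex p-values reuse the global maximum null, which is conservative
  away from the peak; a vertex-wise null would need per-vertex histograms.
* The proximity null relocates fMRI clusters with shape drawn from BFS
  patches, not from the empirical shape distribution of thresholded maps.
* Group averaging assumes maps already live on a shared mesh; no surface
  registration is provided.
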