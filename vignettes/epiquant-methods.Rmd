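---
title: "Methods: event detection, image quantification and gated statistics in epiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event detection, image quantification and gated statistics in epiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiquant)
```

epiquant packages the quantification steps used to characterise
epileptiform activity and excitation/inhibition imbalance in larval
zebrafish models of Dravet syndrome: detection of seizure-associated
calcium transients and ictal-like local field potential (LFP) events,
cross-modal event matching, synaptic puncta densitometry, 3-D cell
counting and colocalization, and the normality-gated two-group statistics
used to compare experimental groups. Every analysis has a matching
synthetic-data generator that plants known ground truth, so the whole
pipeline can be validated end-to-end without access to raw recordings.

## Calcium trace processing

A recording is a ROI-mean fluorescence series on a uniform grid,
canonically 2 Hz for 1 h. Processing follows three steps.

**Normalisation.** `compute_dff()` computes
$\Delta F/F_0 = (F - \bar F)/\bar F$ with $\bar F$ the grand mean over
all frames. The result is dimensionless and zero-mean, which is the scale
on which the 0.04 event threshold is defined. The normalising constant is
the mean of *all* frames, so recordings with many events have a slightly
inflated $F_0$; this shifts the baseline down by the mean event mass and
is subsequently absorbed by the drift correction.

**Drift correction.** `correct_drift()` removes photobleaching and slow
drift by subtracting, at every sample, the mean of the *sub-median*
values inside a sliding window centred on that sample (default 20 s,
truncated at the trace edges; a constant window, where no value falls
strictly below the median, uses the median itself so constant traces pass
unchanged). Using only the lower half of the window makes the baseline
estimate nearly insensitive to positive-going transients. Two properties
of this estimator matter in practice:

* On pure noise the sub-median mean sits about $0.8\sigma$ *below* the
  noise mean, so the corrected trace is biased upward by roughly
  $0.8\sigma$. The event detector compensates with a minimum-duration
  rule (below).
* The window must be long relative to the events riding on the baseline.
  When an event occupies more than about half the window, event samples
  contaminate the sub-median mean and the event is partially flattened.
  With the default 20 s window the events should last at most ~8 s;
  analyses of longer events (e.g. the coupled-recording studies below,
  with transients up to ~15 s) use `window_s = 60`. The window is a
  plain argument everywhere.

**Event detection.** `detect_calcium_events()` takes maximal runs of
samples with $\Delta F/F_0 > 0.04$. Two deterministic curation rules
replace the manual review applied in the original workflow: runs
separated by at most `merge_gap_s` (default 1 s) are merged, and merged
runs lasting `min_dur_s` (default 1 s, i.e. under three frames at 2 Hz)
or less are discarded. The duration floor exists because
seizure-associated transients last seconds, while the upward bias of the
sub-median baseline makes isolated one-frame threshold crossings far more
likely than the nominal 4-sigma rate; without it, noise blips of a single
frame dominate the false-positive budget. Onsets are the first
supra-threshold sample, offsets the first sub-threshold sample after the
run (half-open windows); boundary-clipped events are kept and flagged.

## LFP processing

`bandpass_lfp()` applies the acquisition band (0.1 Hz high-pass, 1 kHz
low-pass) as cascaded zero-phase Butterworth stages (order 1 and 4): a
single band-pass design with a $10^4$-fold cutoff ratio is numerically
fragile. The trace is demeaned explicitly first, because a 0.1 Hz
high-pass cannot settle on the DC level within short records.

`detect_lfp_events()` implements the ictal-event rule: a downward
deflection below $-0.3$ mV (signed threshold on the baseline-centred
signal, since events are explicitly downward) lasting strictly more than
100 ms. Because ictal-like discharges are multi-spike bursts whose
envelope re-crosses the threshold between spikes, sub-threshold gaps of
at most 50 ms are bridged before the duration rule is applied; a burst
therefore counts as one event. Duration is measured between the
threshold crossings — the rule supplies only one threshold, so that
threshold defines both onset and offset.

## Cross-modal coupling

`match_events()` pairs calcium and LFP events greedily by ascending
absolute onset offset within a tolerance (default 2 s: one calcium frame
is 0.5 s and seizure events last tens of seconds), one-to-one, ties
broken by earlier calcium onset. `duration_correlation()` fits ordinary
least squares of calcium duration on LFP duration and reports
$R^2 = 1 - SS_{res}/SS_{tot}$; degenerate inputs (fewer than two pairs,
zero LFP-duration variance) raise explicit errors rather than returning
NaN. OLS was chosen because the published analysis reports a simple
duration-duration correlation without naming a regression type.

## Synthetic recordings

`sim_config()` fixes the acquisition regime (2 Hz calcium; LFP at a
configurable rate, 10 kHz by default as a desk-scale stand-in for the
hardware's 10 µs sampling) and every generator parameter. All generators
are bit-reproducible given a seed.

Waveforms are not parameterised in the source experiments, so shapes
were chosen once to stress the detectors' onset/offset logic and are
documented here as placeholders for real waveform statistics:

* **Calcium transients**: instantaneous rise, exponential decay, scaled
  so that the width *above the 0.04 threshold* equals the requested
  duration (default 6 ± 2 s, seizure-scale yet short relative to the
  20 s drift window). Peak amplitude defaults to 0.1 dF/F0.
* **LFP bursts**: a rectified 80 Hz oscillation (the multi-spike
  character) under a negative flat-top envelope with raised-cosine ramps,
  plateau at −0.5 mV, width at the −0.3 mV crossing equal to the
  requested duration. A flat-top rather than Gaussian envelope keeps the
  threshold crossing steep, so recording noise cannot fragment the burst
  edge into spurious sub-events.
* **Ground truth windows** are defined as the supra-threshold runs of the
  *noiseless* signal (envelope, for LFP) under the same run/merge rules
  the detectors use, so truth and detection share one event definition
  and noiseless recovery is exact by construction.
* **Event placement** draws onsets uniformly over all admissible
  configurations with a minimum spacing (sorted uniforms in the slack
  interval plus the enforced gaps). This construction always terminates
  and, unlike naive accept-reject over the full interval, does not
  collapse at dense packings; infeasible requests fail immediately with
  an explicit message.

In `simulate_coupled_recording()` each seizure appears in both
modalities: the LFP duration $D$ is uniform around its mean, the calcium
duration is $\alpha D + \beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma_j)$ (defaults $\alpha = 1$,
$\beta = 2$ s — the calcium transient outlasts the discharge), and the
calcium onset tracks the LFP onset up to a 0.2 s jitter. Because $D$ is
uniform with half-width $j$, the expected coefficient of determination is
the variance ratio
$R^2 = \alpha^2 j^2/3 \,/\, (\alpha^2 j^2/3 + \sigma_j^2)$, inverted by
`coupling_jitter_for_r2()`.

The coupled-recording validation studies run the full pipeline
(normalise, drift-correct at 60 s, detect in both modalities, match,
fit) under conditions chosen so the closed-form oracle applies: large
transients (0.5 dF/F0, which keeps the decay steep where it crosses
0.04), low trace noise (0.002), a wide LFP duration spread (6 ± 4 s) and
LFP sampled at 250 Hz. These keep duration-measurement error small
against the planted jitter; the residual quantisation of calcium
durations at 0.5 s frames shifts recovered $R^2$ down by roughly 0.01-
0.02 at high targets, visible in the acceptance output. Because the
$R^2$ estimator itself has a sampling spread of about
$2r(1-r^2)/\sqrt{n}$ (≈ 0.05 at $r^2 = 0.5$, $n = 200$), the studies
pool 16 recordings of 50 events (≈ 800 pairs), putting the estimator
noise well inside the ±0.05 acceptance window.

## Puncta quantification

`segment_puncta()` thresholds a 2-D section (Otsu by default — the
original macro applies an unnamed threshold, so a reproducible automatic
default with a fixed-threshold escape hatch was chosen; a constant image
under Otsu is an error directing the user to the fixed mode) and labels
foreground with **8-connectivity**, so diagonally touching pixels join
one punctum. The common 2-D labeller in EBImage is 4-connected, so
labelling is done in-package over the 8-neighbour adjacency graph.

`filter_puncta()` keeps components whose physical area
(pixel count × `pixel_size_um`², default 0.063 µm pixels) lies in
0.018-3.14 µm², **inclusive** on both ends (the source describes the band
as "between"; inclusivity is a documented choice). A single pixel at the
default pitch is 0.003969 µm² and always falls below the band.
`puncta_density()` divides the kept count by the ROI area, and
`synaptic_ratio()` forms the excitatory/inhibitory (PSD-95/gephyrin-like)
density ratio.

`simulate_puncta_image()` plants non-overlapping spots in three area
bands (compact 1-4 px clusters below the band, discs inside it, large
discs above it) by rejection sampling with a hard 10,000-retry cap and a
2-pixel Chebyshev margin so 8-connected components never merge; truth
areas are exact rasterised pixel counts. On noiseless images the pipeline
is exact: segmentation recovers precisely the planted foreground, so the
in-range count equals the planted count for every seed.

## Cell counting, classification, colocalization

`detect_cells()` performs scale-matched blob detection for ~7 µm somata:
Gaussian smoothing at $\sigma = d/(2\sqrt3)$ per axis converted to voxels
with the per-axis pitch (z-anisotropy honoured throughout), local maxima
within a half-diameter neighbourhood, a response threshold *relative to
the response maximum* (default 0.5, making counts invariant to global
gain), and greedy suppression of candidates closer than half a diameter
in physical distance, in order of descending response — near-touching
somata therefore resolve deterministically. Default voxel pitch is
0.8 × 0.8 × 2.0 µm, the regime of whole-tectum counting acquisitions
(~2 µm optical sections at 20x); the 0.063 µm pitch of the 40x puncta
imaging would be needlessly fine for 7 µm objects, and pitch is a
parameter everywhere.

`classify_cells()` normalises each detection's per-channel sphere-mean
intensity by the channel's volume-wide maximum and assigns the role of
the brightest channel if it clears a 0.3 floor, else `unclassified`.
`count_dying_cells()` is the same detector on a single marker channel
(acridine orange / activated caspase-3). `colocalize()` replaces the
original manual assessment with an explicit rule: greedy one-to-one
nearest-neighbour pairing within 3.5 µm (one cell radius), reporting
pair counts keyed by partner class. `quantify_movement()` counts, per
consecutive frame pair, pixels whose absolute intensity change exceeds a
threshold ("acting units"), summed over the recording.

## Gated statistics

`dagostino_pearson()` implements the omnibus $K^2$ test (the skewness
transform of D'Agostino 1970 plus the kurtosis transform of
Anscombe-Glynn 1983, $K^2 \sim \chi^2_2$), since no installed R package
provides it. `compare_groups()` applies the published decision rule:
both groups are gated at $\alpha = 0.05$; failure of either routes to a
two-sided Mann-Whitney test (exact for small tie-free samples, normal
approximation with tie correction otherwise); double-pass routes to
Student's or Welch's t-test according to a two-sided F-ratio test at
$\alpha = 0.05$ — the published rule says only "depending on the
variance difference", so the F-test operationalises it. Samples below
the omnibus test's validity floor ($n < 8$) are sent to the
non-parametric branch with a warning. Summaries are mean ± SEM
($sd/\sqrt n$). No multiple-testing correction is applied, matching the
original analysis; callers comparing many endpoints should track the
number of comparisons.

## Reproducible runs

`run_pipeline()` executes a named task from a config list or YAML file
and writes a JSON summary serialised at fixed precision plus CSV tables,
stamped with an MD5 hash of the analysis-relevant config (output paths
excluded) and the package version; identical config and inputs reproduce
byte-identical summaries. The installed `inst/cli/epiquant.R` script is a
thin command-line mapper onto `run_pipeline()` with `--config`, `--seed`
and `--out`.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, duration_s = 1200, n_events = 12)
sim <- simulate_calcium_trace(cfg)
dff <- correct_drift(compute_dff(sim$trace))
events <- detect_calcium_events(dff)
event_rate(events, 1200)
detection_performance(events, sim$truth$calcium_windows)
```

## Problem sizes used in validation

The shipped validation studies use: 200 planted calcium events (five
1-h recordings of 40 events) and 100 LFP bursts (four 60-s recordings)
for detector recovery; 1000-sample traces for the drift-correction
oracle; ~800 matched pairs per coupling target; 256² puncta images with
(10, 20, 5) planted spots; 100 × 100 × 20-voxel three-channel volumes
with 10 + 15 + 5 cells; and 2000 replicates for the type-I calibration
of the gated statistics.

## What the synthetic data does and does not show

The generators emulate the statistical structure the analyses assume —
threshold-crossing events on drifting noisy baselines, coupled durations,
spot size distributions straddling the area filter, spherical somata in
anisotropic volumes — with known truth. They do not model biophysics
(no calcium indicator kinetics or neuron models), optics beyond
hard-edged spots (no PSF, no deconvolution artefacts), motion artefacts,
electrode drift, or the waveform statistics of real seizures, which the
source experiments do not publish. Passing the planted-truth studies
therefore demonstrates that the quantification rules are implemented
correctly and are internally consistent, not that they are optimal for
any particular real recording.

## Known limitations

* The sub-median drift estimator flattens events long relative to its
  window; choose `window_s` at least ~5× the typical event duration.
* Event durations at 2 Hz are quantised to 0.5 s; duration-based
  statistics on short events carry that floor.
* Blob detection assumes roughly spherical, similar-sized somata;
  strongly elongated or touching cells beyond half-diameter separation
  merge deterministically but are not split.
* The Otsu default assumes a bimodal intensity histogram; sections with
  very sparse signal may need a fixed threshold.
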