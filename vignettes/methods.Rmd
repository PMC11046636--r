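---
title: "Reading conceptual geometry from spontaneous gaze: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading conceptual geometry from spontaneous gaze: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazegeom)
```

## The analysis problem

During a verbal fluency task — freely generating numbers, color names, or
animal names at a metronome pace in the dark — the eyes keep moving even
though there is nothing to look at.  The hypothesis this package
operationalizes is that those spontaneous movements are a behavioral
readout of the *representational geometry* of the conceptual space being
searched: a one-dimensional left-to-right mental number line for numbers,
a two-dimensional ring (the color wheel) for colors, and, for
high-dimensional domains such as animals, whatever low-dimensional
projection the task makes salient (in practice, lexical frequency).

The core analysis is correlational and runs per subject:

1. extract the median gaze position in the 500 ms window before each word
   onset (the median is robust to the outliers that raw gaze data carry);
2. difference consecutive trials into a gaze displacement series
   (signed horizontal `dx`, signed vertical `dy`, and their Euclidean
   combination `d2`);
3. build the matched conceptual change series under a distance model
   (signed numeric difference, distance in a subject-specific MDS space,
   embedding cosine distance, cluster jumps, PC1 or frequency
   differences);
4. rank-correlate the two series (Spearman's rho), Fisher-transform
   (`z = atanh(rho)`), and test the per-subject `z` values against zero at
   the group level with a t test and a default JZS Bayes factor.

The companion analyses recover geometry from *absolute* positions
(per-concept mean fixations, the position-on-value regression, RSA between
fixation-distance and concept-distance matrices, group-level MDS from
gaze) and decode concepts from single trials (balanced leave-one-trial-out
LDA with permutation nulls).

## The synthetic session generator

Because per-subject eye-tracking data cannot ship with a package, every
stage is exercised against a seeded generator whose ground truth is known.
A session embeds a latent geometry into gaze:

* word onsets are spaced `1 / pace_hz` seconds apart (default 0.75 Hz, the
  metronome pace of the emulated task; blocks of 90 words ≈ 2 min);
* in the 500 ms pre-onset window, gaze samples scatter around
  `affine(coupling · latent coordinate)`.  The scatter has two parts: a
  *trial-level* fixation offset with SD `noise_sd` (px), shared by all
  samples of the window, plus small within-window sample jitter
  (SD `noise_sd / 4`).  This split matters: real fixation scatter is
  strongly autocorrelated within a window, so the per-trial *median*
  inherits the trial-level SD rather than averaging it away.  Effect sizes
  quoted as "coupling = 2 × noise_sd" therefore operate on the scale of
  the trial medians that the analysis actually consumes;
* between windows the gaze follows a bounded random walk
  (step SD `drift_sd` px/sample, clipped to the screen), re-anchored at
  the end of each window — a deliberately minimal stand-in for free
  viewing;
* dropouts (blinks, out-of-range gaze) are contiguous invalid runs from a
  two-state Markov process with a target invalid fraction and mean run
  length (default 100 ms), mirroring how trackers lose signal in runs
  rather than in isolated samples.

Latent coordinates are the integers 1..12 for numbers and 12 equally
spaced points on the unit circle for colors.  The color frame is only
defined up to isometry, so per-subject rotations/reflections are applied
through the affine map.  For animals, frequency values are drawn
log-uniformly (Zipf-like) and the embedded effect couples the horizontal
gaze target to the *unsigned between-trial frequency difference*,
normalized by the largest pairwise difference — the transition-magnitude
code that the frequency-space analysis is designed to detect.

Synthetic similarity judgments rate each unordered color pair in both
orders per repetition as `clip(round(9 − 8·d/d_max + ε), 1, 9)` with
`ε ~ N(0, noise_sd)`.  Noiseless judgments are integer-quantized yet still
recover the ring exactly under classical MDS, because the rating matrix
stays circulant and its leading Fourier pair is the fundamental harmonic.

What the generator does *not* emulate: saccade kinematics (main-sequence
dynamics), pupil size, calibration drift, head movement, serial
dependencies in word choice (words are sampled uniformly, immediate
repeats allowed; a `no_repeat` flag exists but is off by default), and any
semantic clustering strategy.  Passing tests therefore show that the
pipeline recovers geometry *when it is present in the stated form*; they
do not show that human gaze contains it.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `window_ms` | ms | 500 | pre-onset window of the emulated protocol |
| `min_samples` | samples | 10 | 10 ms of data at 1 kHz; below this a median is too unstable to keep |
| `pace_hz` | words/s | 0.75 | metronome pace of the task |
| `sample_rate_hz` | Hz | 1000 | tracker rate of the emulated setup |
| `noise_sd` | px | 40 | trial-level fixation scatter of a compliant subject |
| `coupling` | px/unit | 10 | conservative embedded effect; cohort-level analyses state their own values |
| `n_perm` | — | 1000 | permutation count of the decoding null |
| Cauchy scale | — | √2/2 | the default prior width of standard Bayes-factor software |

## Statistical and numerical choices

* **Spearman by default.**  Pixel displacements are heavy-tailed and the
  hypothesis is monotone, not linear; a Pearson option exists for
  sensitivity checks.  Group inference runs on Fisher-z values, whose
  sampling distribution is closer to normal than raw rho.
* **2D pairing.**  The unsigned 2D displacement `d2` cannot coherently
  pair with a signed conceptual change, so the `euclid_2d` mode pairs it
  with the unsigned change; `sign_only` is refused on that axis.  The
  transition-frequency control pairs counts with `|dx|`/`|dy|` (or `d2`),
  since counts carry no direction either.
* **Transition adjacency.**  A displacement pair is formed only between
  trials adjacent in utterance order; if either member is invalid the pair
  is dropped rather than bridged — bridging would fabricate long
  displacements across lost windows.
* **Dissimilarity convention.**  Ratings map to dissimilarities as
  `10 − mean similarity` (mean over repetitions and presentation orders),
  the same inversion used for external similarity matrices, keeping every
  similarity source on one convention.
* **Classical MDS.**  Torgerson double-centering with negative eigenvalues
  clipped to zero (the standard treatment of non-Euclidean noise) and
  zero-padding with a warning when fewer positive eigenvalues than
  requested dimensions exist.  The implementation is cross-checked against
  `stats::cmdscale` in the tests.
* **Group-level gaze MDS.**  Subject matrices are scaled to unit mean
  off-diagonal entry before entrywise averaging.  Averaging *coordinates*
  instead would be invalid without first aligning subject-specific frames,
  which differ by arbitrary rotation/reflection; averaging normalized
  distances sidesteps the alignment problem.
* **Procrustes disparity.**  MDS output is defined only up to similarity
  transforms, so recovery is scored by symmetric Procrustes (translation,
  uniform scale, rotation/reflection), giving a disparity in [0, 1];
  the computation is delegated to `vegan::procrustes`.
* **LDA.**  Pooled within-class covariance with a ridge of
  `1e-6 · trace/d`, equal priors, and a documented tie-break toward the
  lexicographically smaller label.  Every LOOCV fold re-balances the
  training set by downsampling the majority class without replacement;
  permutations reshuffle labels and re-balance afresh, so the null
  carries the full variability of the procedure.
* **Permutation p.**  `count / n_perm` exactly as defined by the
  emulated protocol; an optional `(count+1)/(n_perm+1)` estimator avoids
  exact-zero p-values and is slightly conservative under ties.
* **JZS Bayes factor.**  The Cauchy prior is integrated through its
  inverse-gamma(1/2, r²/2) variance-mixture with adaptive quadrature on
  the likelihood *ratio* (numerically stabler than integrating the raw
  marginal), two-sided, scale √2/2.  The tests check it against a direct
  Monte Carlo draw from the mixing density and against monotonicity in
  |t|.
* **Degenerate inputs** error early and descriptively: constant vectors
  in correlations, collinear controls in partial correlations,
  single-class training sets, zero-variance group tests, all-coincident
  Procrustes targets.

## Problem sizes in the test suite

Cohort-level properties are exercised at sizes chosen to make the
statistics meaningful while keeping the suite quick to run: sessions are
simulated on a 100 Hz grid (50 Hz for the dense-sampling subjects), so a
500 ms window still rests on dozens of samples; line-recovery operating
characteristics use 100 cohorts of 30 subjects at 45 trials each, for
each of the coupled (`coupling = 2·noise_sd`) and null (`coupling = 0`)
conditions; ring recovery uses 20 subjects with subject-specific frames;
decoding calibration uses a 120-trial subject with 1000 permutations; and
the accuracy-versus-distance property uses five dense subjects with 24
blocks of 90 trials each.  All simulated statistics in the vignette and
README are produced by the shipped code.

## Known limitations

* The generator's free-viewing walk is not an oculomotor model; analyses
  that depended on between-window dynamics would need a better one.
* The paper-faithful permutation estimator can return p = 0; use the
  add-one estimator when downstream code takes logs.
* The published Bayes factors this package is checked against were
  produced by JASP from raw data; recomputing them from the *printed*
  (rounded) t statistics reproduces them only approximately, which is the
  expected behavior of the standard JZS computation, not a defect of
  either implementation.
* Ingest mode consumes segmented event tables; audio segmentation and
  tracker-native (EDF) parsing are out of scope.

## A worked micro-example

```{r example, eval = FALSE}
geo <- make_geometry("number")
cfg <- session_config("number", n_trials = 90, coupling = 60,
                      noise_sd = 30, seed = 1)
sim <- simulate_subject_trials(cfg, geo)
disp <- displacement_series(sim$trials)
chg <- signed_number_change(sim$trials$word, block = sim$trials$block,
                            trial = sim$trials$trial)
condition_correlation(disp, chg, axis = "x_signed", mode = "combined")
```
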