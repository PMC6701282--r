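---
title: "Multiband fALFF interaction analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband fALFF interaction analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(falffband)
```

## The question the pipeline answers

After stroke, roughly one in three survivors develops clinically
relevant depressive symptoms. This package implements a resting-state
fMRI analysis chain for asking whether the *amplitude* of spontaneous
low-frequency BOLD fluctuations in a brain region is differentially
coupled to the depressive-symptom score in high- versus low-symptom
survivors — an interaction, not a group-mean difference.

Subjects are split at a MADRS-SIGMA total of strictly greater than 8
(`assign_group()`; a score of exactly 8 is "low"). The spectral measure
is the fractional amplitude of low-frequency fluctuations (fALFF): per
voxel, the sum of spectral amplitudes inside a band divided by the sum
over all positive-frequency bins up to Nyquist. Three bands are
analysed: broadband (0.01–0.08 Hz), slow-5 (0.01–0.027 Hz) and slow-4
(0.027–0.07 Hz), as half-open `[lo, hi)` intervals so that the
0.027 Hz boundary belongs to slow-4 and no bin is counted twice.

## Cleaning chain

`clean_run()` applies, in order:

1. **Despiking.** A transparent operator: a running-median trend
   (window 7 volumes) is subtracted, and points deviating by more than
   `clip_k = 4` robust standard deviations (MAD × 1.4826) are clipped
   back to the trend ± threshold. Common fMRI toolchains despike with
   opaque, tool-specific algorithms; this one is deterministic and
   testable while serving the same purpose. The vectorised
   implementation reproduces the scalar operator bit for bit (the
   running median matches `stats::runmed(..., endrule = "median")`
   exactly, including the Tukey end rule).
2. **Joint nuisance regression.** One OLS fit per voxel against 37
   columns: intercept, linear trend, the Friston-24 motion expansion
   (6 parameters, their one-volume lags, and both sets squared), five
   aCompCor components each from the eroded WM and CSF masks, and the
   global signal. Fitting jointly avoids the order-dependence of
   sequential partial regression. Collinear columns (e.g. all-zero
   motion in synthetic nulls) are dropped with a warning. Tissue masks
   are thresholded at 0.99 when probabilistic, have lesion voxels
   removed, and are eroded twice with the full 26-neighbour 3×3×3
   element before component extraction.
3. **Smoothing.** Separable truncated-Gaussian smoothing, FWHM 6 mm,
   sigma = FWHM / (2√(2 ln 2)) / voxel size, zero-padded boundaries,
   per volume. Mask-confined renormalisation is deliberately off: it
   changes edge-voxel spectra.

Slice timing, realignment and spatial normalisation are *not*
implemented: data are expected already aligned on a common grid (the
synthetic generator produces them that way). Motion scrubbing is
deliberately absent — censoring introduces gaps that corrupt spectra.
Global-signal regression is a flag (default on) so both conventions are
reproducible.

## Spectral core

`amplitude_spectrum()` removes a least-squares line, Fourier-transforms,
and returns `|FFT|` at bins `k/(t·TR)`, `k = 1..⌊t/2⌋` (DC excluded,
Nyquist included in the denominator). The amplitude-versus-power
constant cancels in the band ratio, and fALFF is invariant to positive
rescaling of the series. A constant series yields 0 with a
`degenerate` flag rather than an error. No taper is applied by default
(a Hann taper is available behind a flag). Note one consequence of the
linear detrend: a pure sinusoid whose phase is not orthogonal to a
straight line over the window acquires a small broadband residue; exact
spectral concentration holds for window-symmetric phases.

The stated denominator "entire spectrum" is implemented as *all
positive-frequency bins up to Nyquist* — at TR = 3 s the Nyquist
frequency is 0.167 Hz, so any larger printed bound cannot be taken
literally.

Per-subject maps are z-standardised over the brain mask
(`zscore_map()`): subtract the global mean, divide by the global SD.
This makes maps comparable across subjects and decouples amplitude
scale from residual motion, at a price analysed below.

## Second-level model and inference

`build_design()` produces columns `[1, group, score, group × score]`
with low = 0, high = 1 and the raw (uncentred) score, plus optional
mean-centred covariates (age, sex, NIHSS). The interaction t-statistic
is identical under score centring; only main-effect columns change.
With n = 63 and four columns the residual df is 59, which together
with `r_squared(t, df) = t²/(t² + df)` reproduces the published
per-cluster effect sizes exactly at two decimals. (The published
formula prints a radical over the numerator; the values in the source
table are consistent only with the ratio form implemented here.)
`t_to_z()` is the tail-symmetric, log-space Student-to-normal
quantile map.

Clusters are formed at the one-sided upper-tail threshold
`p < 0.001` under 18-neighbour connectivity (6 and 26 available).
Familywise error over cluster extent is controlled by **Freedman–Lane
permutation** (`cluster_fwe()`): the reduced model (design without the
interaction column) is fitted once; each permuted dataset is its fitted
values plus row-permuted residuals, refitted under the full model; the
maximum suprathreshold extent per permutation forms the null, and each
observed cluster gets `p = (1 + #{max ≥ k}) / (1 + n_perm)`.
Freedman–Lane is the standard scheme when nuisance terms (here the
group and score main effects) must be respected; naive label shuffling
is not exchangeable under this model. The original analysis used
parametric random-field cluster correction; permutation gives exact
control at the same thresholds without smoothness estimation, and the
calibration experiment below verifies it empirically.

## The synthetic cohort

`generate_cohort()` builds a complete study: a cohort table (38 low /
25 high by default; MADRS drawn from rounded truncated normals with
low ≈ 2.29 (2.31) on [0, 8] and high ≈ 14.88 (6.67) on [9, 60]; age,
sex, NIHSS, history and medication flags at the reference rates), and
per subject a 4D BOLD run with masks, motion file and lesion.

The signal model, per in-brain voxel:

* baseline 1000;
* 1/f-coloured noise (exponent 1, SD 8) in grey-matter-like voxels;
  WM/CSF voxels instead carry matched-power white noise plus three
  shared very-low-frequency (< 0.01 Hz) physiological waveforms,
  strongly weighted there and weakly brain-wide — the structure
  aCompCor is designed to estimate and remove. This is deliberate:
  with pure 1/f noise in the tissue compartments, the estimated
  components become noisy mixtures of low-frequency Fourier modes that
  randomly delete slow-5 content from the whole brain;
* white measurement noise (SD 4) everywhere;
* motion-coupled drift (random per-voxel weights on the first
  translation parameter); motion itself is a slow two-mode drift plus
  5% white jitter, scaled to SD 0.15 mm / 0.002 rad per column;
* a stable background band topography: two fixed smooth amplitude
  fields (one per subband, peak amplitude 24) scale band-limited
  oscillations whose spectral mass sits exactly on the FFT bin centres.
  Their phases form travelling waves (wavelength 12 voxels): locally
  coherent, so smoothing preserves the topography deterministically,
  yet globally incoherent, so the global-signal regressor carries
  almost none of it. The wave pattern is a fixed property of the
  synthetic anatomy, shared by all subjects;
* in a spherical effect region (radius 5 voxels, grey matter only,
  carved out of the tissue compartments), a phase-coherent band-limited
  oscillation of RMS amplitude `a0 + beta × MADRS` in the high group
  and `a0` otherwise, with defaults `a0 = 4`, `beta = 1/3` so the
  amplitude doubles across the high group's observed score range
  (roughly 9–30, the range over which it varies at all);
* a spherical lesion (radius 2–4 voxels) attenuating signal and adding
  noise, placed by rejection so the twice-eroded tissue masks always
  retain enough voxels for aCompCor. Lesion voxels are excluded from
  the WM/CSF masks.

Everything is deterministic given the spec (including its seed);
regenerating from a written manifest reproduces every file
bit-identically. The default test grid is 24³ so a full cohort runs in
minutes; the emulated acquisition grid (72×72×44, 3 mm, TR 3 s, 140
volumes) is available by setting `grid_shape`.

What the generator does **not** emulate: haemodynamic response shapes,
cardiac/respiratory waveforms (only their low-frequency aliases),
EPI distortion, slice-timing structure, realistic lesion anatomy, or
anatomically realistic tissue geometry (the compartments are boxes
precisely so that 26-neighbour erosion leaves predictable cores).
Passing tests therefore validate the *computational* chain, not
fidelity to any particular scanner.

## Validation experiments and a known test-scale limitation

`null_calibration()` generates independent null cohorts
(`beta_interaction = 0`), maps them (generation → fALFF → z-score) and
runs the full permutation inference; the fraction of cohorts with any
significant cluster should match the nominal alpha. The default
experiment uses 200 cohorts of 12 + 8 subjects at 64 volumes with 500
permutations each — 64 volumes is the generator's minimum and the null
does not depend on spectral resolution; the nuisance-cleaning stage is
skipped because it is a deterministic per-subject transform that cannot
break exchangeability under the null, and the quantity under test is
the inference stage.

`band_recovery()` runs the full chain — generation with the slow-5
effect, despiking, nuisance regression (GSR off, see below), smoothing,
fALFF in both subbands, z-scoring, permutation inference — and reports
how often each subband analysis finds a significant cluster overlapping
the true region. GSR is off in this experiment because at test scale
the coherent effect region is ~9% of the brain, so the global-mean
regressor is dominated by the effect waveform and removes it almost
exactly — a small-volume artefact of GSR that cannot arise at
acquisition scale, where such a region is well under 1% of the brain.

**Limitation.** At the 24³ test scale, cluster-level recovery of an
amplitude-type interaction is sharply bounded, for reasons worth
stating because they are scientific, not implementation, facts:

1. *Self-normalisation.* The per-subject global z-scoring divides each
   map by a SD that the subject's own effect inflates (the region is
   ~9% of in-mask voxels). The achievable z-height of the region
   saturates around 1.5–1.8 irrespective of injected amplitude, so the
   score slope available to the interaction test is a fraction of a
   z-unit across the whole score range.
2. *Regression chasing.* OLS nuisance regression of a strong
   band-limited signal against ~35 broadband regressors removes part of
   the band content and redistributes the fitted energy across the rest
   of the spectrum, inflating the fALFF denominator proportionally to
   the signal; cleaned fALFF therefore plateaus with amplitude.
3. *Ratio noise.* The fALFF denominator is an amplitude sum over ~63
   bins whose relative fluctuation (~6–7%) is not reduced by spatial
   smoothing, because numerator and denominator scale together. The
   per-voxel between-subject SD of z-scored fALFF is bounded below
   around 0.2.

Together these cap the attainable per-voxel interaction t near 1 with
20 subjects, while cluster-forming at p < 0.001 needs t > 3.7. At
acquisition scale (tens of thousands of in-brain voxels, effect regions
well under 1%) bounds 1 and 2 relax by an order of magnitude, which is
why the method is viable on real data. `band_recovery()` reports the
desk-scale rates honestly rather than assuming them away; expect the
slow-5 rate to be far below what the same effect would yield at
acquisition scale, and the slow-4 rate to be near zero (the injected
slow-5 power enters the slow-4 denominator, pushing its interaction
slope negative — the one-sided positive contrast is blind to it, which
is itself the band-specificity property).

## Numerical choices

* Degenerate inputs: constant series → zero spectrum, flagged, not an
  error; zero global SD in z-scoring → error; empty eroded mask →
  error naming the remedy; `n_perm = 0` → all corrected p = 1 with a
  warning.
* Collinearity: QR-pivot selection of a maximal independent column set,
  dropped columns reported by label.
* `t_to_z` is evaluated in log space so |t| up to 50 and beyond maps to
  finite z.
* Monte-Carlo p-values use the add-one estimator `(1 + b)/(1 + m)`,
  which cannot return 0; contingency resampling fixes both margins
  (`r2dtable`).
* Cluster connectivity defaults to 18-neighbour, the convention of the
  major neuroimaging packages; 6 and 26 are available.
* Seeds: every stochastic stage takes an explicit integer seed and
  records it in its provenance output; per-subject generator seeds are
  derived from the spec seed by a fixed affine map.

## Problem sizes used by the test-suite

Module tests run on 24³ grids with 64–140 volumes and cohorts of 2–16
subjects. The calibration experiment uses 200 cohorts × 500
permutations; the recovery experiment 20 replicates × 199 permutations
at 140 volumes; the end-to-end determinism check two full pipeline runs
at 8 subjects, 64 volumes, 30 permutations. These sizes were chosen so
the whole suite completes in under half an hour on one CPU while
keeping every experiment at full statistical strength where it matters
(the permutation counts and cohort counts of the calibration).
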