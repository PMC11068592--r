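---
title: "fpvs: generative model, numerical choices and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fpvs: generative model, numerical choices and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how the synthetic EEG generator works, which
numerical conventions the analysis chain follows, and why several
non-obvious choices were made. All parameters discussed here were fixed
a priori, before the calibration and recovery experiments were run.

## 1. The stimulation model

A recording represents one ~90 s FPVS train: stimuli at a base rate of
`f_base = 5.77` Hz with every fifth stimulus drawn from the deviant
category, so category-discriminative responses are tagged at
`f_odd = 5.77 / 5 = 1.154` Hz. The train lasts `n_cycles = 96` oddball
cycles (96 / 1.154 ≈ 83.19 s), sampled at 500 Hz, flanked by short pre-
and post-stimulation padding; a marker encodes the condition and
stimulus type at train onset.

Each channel's signal is a sum of cosines:

- **oddball harmonics** at `k * f_odd` for `k = 1 .. max_harmonic` (8 by
  default), skipping multiples of 5 (those coincide with base harmonics);
- **base harmonics** at `k * f_base`;

with per-harmonic amplitudes decaying geometrically
(`harmonic_rolloff = 0.7` per step, normalized so the harmonic weights
sum to 1 — the *summed* amplitude equals the design value).

### The amplitude design is the hypothesis

`default_effect_design()` fixes the summed oddball amplitude per group ×
stimulus type × condition × region class. The parieto-occipital face
amplitudes are 1.5 / 0.9 / 0.35 µV (Self / CloseOther / Stranger) for the
NT group and 0.9 / 0.9 / 0.35 µV for the autism group: a graded
self-relevance response in one group, no Self vs CloseOther advantage in
the other. Name amplitudes are smaller, identical across groups, and
frontocentrally weighted. These values were chosen once, from the
magnitude range of published FPVS self-relevance cluster means, and were
never adjusted afterwards: the generator is the fixed object under test,
not a dial to make tests pass.

Between-subject variability is a truncated-Gaussian amplitude offset
(`between_subject_sd = 0.3` µV) shared across a subject's cells;
`noise_scale = 0.25` sets the 1/f background so that single-subject
fundamental z-scores land in the strongly-significant range typical of
real FPVS data (tens, not thousands). The table-level simulator
(`simulate_subject_table()`) uses residual SD 0.45 µV for the same
reason.

### Common-mode nulling and realized ground truth

Average re-referencing subtracts the spatial mean of all channels at
every sample. A generator that draws each channel's harmonic phase
independently produces a nonzero common-mode component at every
harmonic; re-referencing then *changes* each channel's realized
amplitude by a random amount (≈ 25 % at 12 channels), and no analysis
could recover the designed values from the re-referenced data — the
information is destroyed, not hidden.

The generator therefore works with complex per-channel amplitudes
`a_ch = A_ch * exp(i * phi_ch)` per harmonic and, with the default
`zero_common_mode = TRUE`, subtracts the spatial mean of `a_ch` before
synthesis. The emitted signal then has exactly zero spatial mean at
every harmonic, average re-referencing is signal-transparent, and the
ground-truth table records the *realized* post-nulling amplitudes
`Mod(a_ch)` — the quantities an ideal analysis of the emitted data would
estimate. Tests of the designed ordering itself set
`zero_common_mode = FALSE` to address the design directly.

### Artifacts

- **1/f noise**: each channel gets independent Gaussian noise shaped in
  the frequency domain by `f^(-noise_exponent / 2)` (amplitude slope −0.5
  for the default exponent 1).
- **Line interference**: a 50 Hz sinusoid (`line_amp`).
- **Blinks**: a Poisson train (`blink_rate` per second) of smooth
  biphasic pulses projected with a frontal-dominant topography (maximal
  at Fp1/Fp2); the course is returned for testing.
- **Bad channels**: `inject_bad_channels()` replaces up to two channels
  with high-variance noise, for exercising interpolation.

### Realism limits

The generator is deliberately simple where simplicity does not affect
the analysis contract: phases are random rather than stimulus-locked
waveforms; noise is stationary and spatially white (real EEG noise is
spatially correlated); blink topography is fixed; there are no muscle,
cardiac or drift artifacts; amplitudes are constant over the train (no
adaptation). Consequently the pipeline's performance numbers here bound
the method's behaviour under its own assumptions, not under real-world
violations of them.

## 2. Numerical conventions in the analysis

- **Cropping**: epochs are cut to ⌊96 / 1.154 × 500⌋ = 41,594 samples.
  The spectrum's bin width is 500 / 41,594 ≈ 0.01202 Hz.
- **Near-commensurability**: 1.154 Hz × (41,594 / 500) = 96.0029… is not
  an exact integer, so the oddball fundamental is not perfectly
  bin-centred; a noise-free 1 µV cosine reads ≈ 1 − 2 × 10⁻⁶ µV at its
  nearest bin. Exact-bin tests therefore use a 10⁻⁵ tolerance at the
  stimulation frequencies (and 10⁻⁹ at grid-exact frequencies).
- **Amplitude normalization**: single-sided spectrum `|FFT| / (N / 2)`,
  no taper — after integer-cycle cropping the rectangular window is the
  correct choice. The DC bin consequently reads twice the mean.
- **Noise window**: 10 bins per side, excluding the 1 bin adjacent on
  each side, leaving 18 noise bins (± 0.12 Hz at the 0.012 Hz
  resolution). A window of ±10-with-1-excluded is stated in some sources
  as "20 bins"; the arithmetic gives 18 and this package uses 18.
- **Baseline subtraction**: bin amplitude minus the mean of the 18 noise
  bins; negative results are not clipped, keeping the estimator unbiased
  at null bins. Because the window is symmetric, constant offsets and
  linear trends cancel exactly.
- **z-scores**: same numerator, divided by the *sample* (n−1) SD of the
  noise bins.
- **Harmonic selection**: from the grand-average spectrum, the maximal
  consecutive run of oddball multiples starting at the fundamental with
  z > 2.32; base multiples are skipped without breaking the run; the
  fundamental is always retained.

### Why the z > 2.32 rate is not 1 %

z = 2.32 is the normal-theory one-sided 1 % point. But with the noise
mean and SD estimated from n = 18 bins, the statistic at an iid-Gaussian
null bin is distributed as √((n+1)/n) · t(n−1) = √(19/18) · t(17), whose
exceedance probability at 2.32 is

P(t(17) > 2.32 / √(19/18)) ≈ 0.019,

about twice nominal. The acceptance criterion that the empirical rate be
1 % ± 0.5 % is therefore unattainable for this (standard, literature-
faithful) estimator: the acceptance suite states the 1 % band, fails it
honestly (observed ≈ 0.019–0.022), and this analysis is the explanation.
Nothing in the package was weakened to mask the discrepancy. Note the
*pipeline-level* error rate that matters for the study — the type-I rate
of the condition-by-group interaction — is correctly calibrated
(≈ 0.05–0.06 over 1,000 null replicates).

## 3. Statistical conventions

- `mixed_anova()` computes the balanced mixed-design univariate
  decomposition via orthonormal Helmert contrast scores (Kronecker
  products across within factors). Sums of squares follow the sequential
  convention of `aov` with `Error(subject / (...))` strata — verified
  against `aov` to < 10⁻⁸ relative error — which coincides with Type III
  when group sizes are equal.
- Greenhouse-Geisser ε = (tr S)² / (d · tr S²) from the pooled
  within-group covariance S of the contrast scores, bounded below by
  1/d; Mauchly's W = det S / (tr S / d)^d with the standard χ²
  approximation. The GG-corrected p is flagged for reporting when
  Mauchly's p < .05.
- `paired_t()` reports Cohen's dz, `independent_t()` pooled-SD Cohen's
  d; both error on zero variance (a t-statistic 0/0 is undefined; the
  package treats identical vectors as the same error rather than
  returning t = 0).
- Bonferroni adjustment is `min(1, m · p)` with m fixed by the analysis
  plan (3 condition pairs).
- `run_paper_contrasts()` encodes the full decision tree: omnibus
  parieto-occipital (Stimulus Type × Condition × Laterality × Group) and
  frontocentral (without Laterality) ANOVAs, then per stimulus type a
  Condition × Group ANOVA collapsed over laterality, pairwise condition
  t-tests, and independent t-tests on the three condition difference
  scores between groups.

## 4. Verification strategy

Every [derived] quantity is checked against an independent oracle before
use: spectra against a direct O(n²) DFT, ANOVA sums of squares against
`aov`, sphericity statistics against the covariance formulas computed
from scratch, t-tests against `stats::t.test`, and the BrainVision
writer against an independent reader (MNE-Python). Monte-Carlo
calibrations use the cheap table-level simulator (1,000 type-I
replicates, 100 power replicates); the EEG-level and table-level routes
are tied together by an end-to-end recovery regression (600
channel-level points through the full preprocessing chain; slope within
1 ± 0.1, intercept within ± 0.05 of zero).

## 5. Limitations

- The recovery regression's small positive intercept (≈ 0.03 µV)
  reflects Rician bias: at bins containing signal, |signal + noise|
  exceeds |signal| on average, while baseline subtraction removes only
  the neighbouring-bin mean.
- The single-bin z criterion miscalibration discussed above is a
  property of the estimator's definition, inherited by design.
- ICA ocular correction identifies components by correlation with a
  virtual EOG (mean of Fp1/Fp2); on data whose *signal* is strongly
  frontal it can remove a signal component. In the study configuration
  (signal dominated by posterior channels, threshold 0.8) this does not
  occur, and the recovery regression — run through the full chain
  including ICA — confirms it.
- The ANOVA assumes a complete balanced design; unbalanced *group* sizes
  are supported (and used), but missing cells are an error, not imputed.
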