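---
title: "Resting-state EEG biomarkers of smoking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG biomarkers of smoking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

resteeg implements a resting-state EEG (rsEEG) biomarker analysis for
three-group smoking cohorts — never-smokers, long-term abstinent
past-smokers, and current chronic smokers — together with a synthetic
cohort generator that lets every stage of the pipeline be validated by
parameter recovery. This vignette describes the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish.

## The analysis pipeline

Each subject contributes two multichannel recordings (31 channels by
default, 500 Hz in the motivating study design): three minutes eyes-closed
(EC) and three minutes eyes-open (EO). The pipeline mirrors the standard
rsEEG workflow:

1. **Band-pass filter, 1–50 Hz.** A zero-phase Butterworth band-pass
   (high-pass section of order 4, low-pass of order 8). Zero-phase
   filtering applies the squared magnitude of the filter; we realize it by
   multiplying the spectrum by that response after reflective padding,
   which is numerically identical to forward–backward filtering away from
   the edges and removes the edge transients. The low-pass order was
   chosen so that a mains-frequency (60 Hz) tone retains less than 10% of
   its RMS amplitude; one octave beyond either band edge, power is down by
   more than 20 dB.
2. **Common average reference (CAR).** Each sample has the instantaneous
   channel mean subtracted; the operation is idempotent and requires at
   least two channels.
3. **Two-second epochs.** Consecutive, non-overlapping; a trailing partial
   segment is dropped. Two seconds gives 0.5 Hz spectral resolution, so
   the band edges at 1, 4, 8, 13, 30 and 50 Hz fall exactly on bins.
4. **Artifact screening, two quantitative criteria.**
   (a) any epoch containing a sample whose absolute value exceeds
   75 µV on any channel is rejected (we read the threshold as absolute
   amplitude, not peak-to-peak — the stricter reading — and apply it per
   epoch, which also yields a subject-level screen when every epoch
   fails); (b) a subject × condition whose total 1–50 Hz power (summed
   over bands, averaged over channels) deviates more than 3 SD from its
   group mean for that condition is excluded *from that condition only*.
   Manual artifact screening and ICA-based correction are deliberately
   out of scope: they involve analyst judgment that cannot be reproduced
   or tested, while the two quantitative rules can be validated against
   planted artifacts.
5. **Spectral features.** Per retained epoch, the FFT periodogram of each
   channel (mean-corrected, no taper, normalized so the bin sum equals
   the signal variance). Absolute band powers are bin sums over the five
   canonical bands — delta [1, 4), theta [4, 8), alpha [8, 13),
   beta [13, 30), gamma [30, 50) Hz — averaged over retained epochs;
   relative powers divide by the total 1–50 Hz power. Band intervals are
   half-open so that an on-edge bin (for example 4.0 Hz) belongs to
   exactly one band and the five bands tile the analysis range.
6. **Reactivity.** Per band and channel,
   `(EC power − EO power) / EC power`, using the epoch-averaged absolute
   band power by default (a relative-power variant is available via
   `reactivity_source = "relative"`; both preserve the sign of a genuine
   EC alpha enhancement). Subjects excluded in exactly one condition
   contribute power features for the other but no reactivity.
7. **Coherence.** Magnitude-squared coherence
   `C(f) = |Pxy(f)|² / (Pxx(f) Pyy(f))` for all channel pairs, estimated
   by Welch averaging of mean-corrected, Hann-tapered periodograms over
   the same retained two-second epochs used for power (no overlap). Band
   coherence is the unweighted bin mean; the per-subject scalar summary is
   the mean of the strictly lower triangle of the coherence matrix
   (465 pairs for 31 channels, diagonal excluded). Coherence is computed
   on CAR-referenced data for consistency with the power pipeline; CAR is
   known to inflate coherence, so `car = FALSE` is available.
8. **Statistics.** Per channel (or channel pair), a Kruskal–Wallis
   omnibus test on mid-ranks with tie correction; Benjamini–Hochberg FDR
   within one family — one feature × band × condition, i.e. 31 channels
   or 465 pairs, matching a per-family correction "across channels";
   Tukey HSD post-hoc comparisons only where the omnibus survives FDR at
   α = 0.05 (a rank-based Dunn z-test is available via
   `posthoc = "dunn"` for users who prefer a post hoc consistent with the
   rank-based omnibus). Feature–covariate association uses Pearson
   correlation on pairwise-complete observations with nonparametric
   bootstrap inference (B = 10,000 paired resamples by default;
   percentile CI; two-sided p defined as twice the smaller sign-crossing
   fraction of the resampled correlations, floored at 2/B).
   Summary-statistic tests (`t_test_from_summary`, `anova_from_summary`)
   recompute pooled t and one-way F directly from printed group means,
   SDs and sizes, which is how published demographic tables are verified
   (`validate_table1()`).

## The synthetic cohort generator

The generator exists because the downstream features depend only on the
second-order spectral structure of the signal. Each channel is a sum of

* five independent band-limited Gaussian components, one per band, scaled
  to a configured RMS amplitude (µV) per group;
* a 1/f-type background (power density ∝ f^−exponent across 1–50 Hz,
  default exponent 1, RMS 3 µV);
* for alpha only: a mixture
  `sqrt(s) · polarity · shared + sqrt(1 − s) · private` of one shared
  source and a channel-private source, both band-limited to 8–13 Hz,
  where `s = alpha_shared_fraction` controls inter-channel coherence and
  `polarity ∈ {−1, +1}` per channel. The polarity matters: with equal
  loadings the CAR step would subtract the shared source exactly; random
  polarities emulate the sign-varying topography of a real alpha dipole
  and leave the planted coherence visible after re-referencing.

Band-limiting applies the zero-phase (squared-magnitude) response of an
8th-order Butterworth band filter spectrally. The order was chosen so
that the realized in-band share of each component exceeds 93%; each
component is then normalized to unit *in-band* RMS, so the configured
amplitude is the realized band RMS by construction. A 4th-order edge
would leave about 18% of the alpha component outside its band and break
that contract. The smooth edges still let a strong alpha rhythm
contribute a small shoulder to the measured beta band, much as real
spectra do — a known, intentional imperfection.

The eyes-closed condition multiplies the alpha amplitude by
`alpha_ec_gain ≥ 1`. Per-subject log-normal amplitude jitter (default
sdlog 0.15, a typical inter-subject spread for band amplitudes) is drawn
once per subject and shared between conditions, so reactivity in
unaffected bands is zero in expectation.

Covariates are drawn per group to match configured means, SDs and bounds
(defaults follow the demographic profile of a matched male cohort in its
fifties, with the smoking measures present only in the two smoker
groups and missingness rates matching typical self-report completeness).
For each planted feature–covariate correlation, the standardized
covariate is a linear blend of the standardized realized feature(s) and
independent noise. Because both the covariates and the features carry
group-mean structure, the blend weights are solved numerically so that
the realized *pooled* correlation across the applicable groups equals the
target; bound clipping and integer rounding afterwards attenuate it
somewhat (the tests allow ±0.25 around the target at n ≈ 48, about twice
the sampling SD of a correlation at that size).

**Default effects ("paper-like" preset).** Theta RMS 5.0/4.2/3.8 µV for
never/past/smoker (a persistent theta deficit in both smoker groups);
alpha RMS 6.0/6.0/7.5 µV, EC gain 1.3/1.3/1.6 and shared fraction
0.15/0.20/0.45 (alpha power, reactivity and coherence elevated in current
smokers only); delta/beta/gamma equal across groups. These are stylized,
deliberately stronger than a real cohort's effects, so that recovery is a
sharp test of the pipeline rather than of sample size. `null_preset()`
removes all group differences and planted correlations.

**What the generator does not emulate:** volume conduction and realistic
source mixing (coherence comes from a single shared source per band),
non-Gaussian and non-stationary dynamics, blink/muscle artifact
waveforms (only amplitude spikes for testing rejection), channel-specific
noise topographies. Passing recovery tests therefore shows that the
pipeline detects second-order spectral effects of the planted kind; it
says nothing about robustness to artifacts or to the spatial structure of
real EEG, and the real study's channel-level significance maps are not
reproducible from synthetic data.

## Numerical choices and degenerate inputs

* The per-epoch PSD uses no taper: with bin-aligned band edges this makes
  Parseval exact and places a bin-frequency sinusoid's power in a single
  bin, both of which are contract-tested. The Welch coherence estimator
  uses a Hann taper (standard for cross-spectra); the taper cancels in
  the coherence ratio's normalization.
* A montage of 31 standard 10-10 labels is the default; the pipeline is
  agnostic to the montage length.
* All-identical samples give Kruskal–Wallis H = 0, p = 1 (not an error);
  zero within-group variance makes Tukey HSD abort with a labeled error;
  `reactivity` requires positive EC power; coherence needs at least two
  segments (one segment gives identically 1); the SD-outlier screen needs
  at least three subjects per group and condition, and because its z-score
  uses the inclusive group SD it is bounded by `(n-1)/sqrt(n)` — the 3 SD
  rule can only ever fire in groups of a dozen or more subjects.
* Mann–Whitney U reports min(U₁, U₂) with an exact p (no ties,
  n₁·n₂ ≤ 400) or the tie-corrected normal approximation.
* The bootstrap p-value is floored at 2/B and the whole resampling is a
  deterministic function of the seed.
* Errors are classed conditions (`resteeg_error_invalid_input`,
  `resteeg_error_unknown_label`, `resteeg_error_degenerate`,
  `resteeg_error_io`) so callers can handle them precisely.

## Problem sizes used in the test suite

The packaged validation runs the full pipeline at the study's group sizes
(33/28/20) but with shorter recordings (16 s per condition) at 128 Hz —
8 two-second epochs per condition — which keeps a 30-cohort recovery
study to a few minutes while leaving every planted effect comfortably
detectable. Estimator calibrations use 10,000 null replicates
(Kruskal–Wallis type-I error), 1,000 simulations with B = 10,000
(bootstrap null rejection), and 40 independent white-noise pairs with
L = 90 Welch segments (MSC bias, expectation ≈ 1/L ≈ 0.011). The
`scripts/acceptance.R` entry point re-runs the same computations from a
command-line seed.

## Known limitations

* Relative band powers are compositional: a genuine alpha increase
  mechanically depresses the other relative powers, so a strong planted
  alpha effect produces secondary group differences in other bands'
  relative power. This is a property of the feature definition, not a
  bug, and it is visible in the synthetic recovery runs.
* CAR inflates coherence and partially cancels spatially uniform
  sources; conclusions about absolute coherence levels should use
  `car = FALSE` and a non-CAR reference strategy.
* The EDF writer quantizes to 16 bits (per-channel relative error about
  1/65535 of the data range); the internal fixture format round-trips
  exactly.
* Education and income are modeled as rounded Gaussians on their ordinal
  scales; the chi-squared education comparison therefore has no synthetic
  ground truth beyond its degrees of freedom.
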