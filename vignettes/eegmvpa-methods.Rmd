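---
title: "Methods: time-resolved EEG decoding, RSA and Bayes-factor inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved EEG decoding, RSA and Bayes-factor inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmvpa)
```

## The analysis problem

`eegmvpa` implements a time-resolved multivariate analysis pipeline for
rapid-serial-presentation EEG studies of face perception.  The scientific
question it serves is *when*, after stimulus onset, different facial
attributes (emotional valence, perceived sex) become decodable from
whole-scalp activity, and whether the representational geometry of the
neural response tracks behavioural rating structure.  The pipeline has
five analysis layers:

1. **Behaviour** — 9-point ratings from independent rater groups are
   averaged per stimulus; the extremes (k lowest / k highest) define the
   decoding classes, and absolute differences of mean ratings define a
   behavioural representational dissimilarity matrix (RDM).
2. **Decoding** — per subject and per timepoint, linear discriminant
   analysis (LDA) classifiers on the channel vector, under
   leave-one-block-out cross-validation: all-pairs image decoding (image
   specificity) and exemplar-generalising class decoding.
3. **RSA** — per-timepoint neural RDMs (cross-validated pairwise decoding
   accuracies, or correlation distance) Spearman-correlated with the
   behavioural RDM, with a leave-one-participant-out lower-bound noise
   ceiling.
4. **Inference** — Jeffreys–Zellner–Siow (JZS) Bayes factors with interval
   nulls at every timepoint, a contiguity rule for decisions, and
   onset/peak latency estimation with bootstrap confidence intervals.
5. **Controls** — low-level image statistics (luminance, contrast, radial
   spatial-frequency bands) compared between the decoding classes.

Every layer is exercised against a synthetic-data generator with known
ground truth, so the package's correctness claims are parameter-recovery
claims, not claims about any particular recorded dataset.

## The synthetic-data generator

### What it emulates

The generator reproduces the structural features of the emulated study
design that the analyses depend on:

* **Catalogue** — 900 stimuli, 840 human faces and 60 non-face
  (pareidolia) images; each stimulus carries latent valence and
  masculinity values drawn from a bivariate standard normal with
  correlation `latent_correlation` (default −0.1, slightly negative:
  masculine-looking faces rated marginally more negative).
* **Ratings** — each rater scores a random subset (default 300 of 900) on
  a 1–9 scale.  A rating is `5 + 2·latent + noise`, clipped to [1, 9] and
  rounded half-away-from-zero; the affine map puts the scale midpoint at
  the latent mean and spans the scale at ±2 SD.  Subsets are
  rejection-resampled until every stimulus is rated.  The default rater
  noise SD of 1.0 rating unit was chosen so that the split-half
  reliability of the behavioural RDM is ≈ 0.9, the level of agreement
  real rating experiments of this kind report; it was fixed once, from
  the split-half statistic alone.
* **Schedule** — 150-trial sequences, six sequences per block, every
  block a permutation of all 900 stimuli, 12 blocks (10,800 trials):
  exactly the balanced structure leave-one-block-out cross-validation
  requires.
* **Epochs** — trials × channels × timepoints at 256 Hz on an
  onset-aligned grid (−100…1000 ms ⇒ 282 samples).  Each trial is
  spatially mixed Gaussian noise plus two deterministic components that
  start at stimulus onset: a per-stimulus fixed channel pattern under a
  generic evoked envelope (image identity), and one unit-norm pattern per
  attribute scaled by the stimulus' standardised latent value and by that
  attribute's temporal envelope.  Pre-stimulus samples are pure noise.
* **Images** — square grayscale PNGs whose class-wise mean intensity,
  texture SD and low-frequency sinusoidal content are configurable, so
  the image-statistics controls have known group differences to detect.

The attribute signal scales *continuously* with the latent value rather
than with a binary class label.  One mechanism then grounds both analyses:
class decoding sees separable extremes, and RSA sees neural dissimilarity
proportional to rating gaps.

The temporal envelope is zero before `onset_ms`, rises as a half-Gaussian
(SD = one third of the onset-to-peak interval) to 1 at `peak_ms`, holds a
plateau (default 40 ms), then decays exponentially (default τ = 80 ms).
This family makes onset and peak distinct, orderable, and recoverable —
the two latencies the inference layer estimates.  Defaults place the
valence effect at 80→120 ms and the sex effect at 110→160 ms, preserving
the valence-before-sex ordering the pipeline is designed to resolve.

Noise is white in time but spatially correlated through a seeded random
mixing matrix (`I + α·G/√p`, default α = 0.5); spatially white noise
would make whole-scalp LDA unrealistically easy.

### What it does not emulate

No eye movements, blinks, alpha rhythm, 1/f spectral structure, temporal
autocorrelation of noise, electrode drift, or the fixation-dot target
task.  Passing tests therefore demonstrate that the *analysis code*
recovers known ground truth under realistic dimensionality and SNR — not
that any specific neural claim holds for recorded EEG.

## Preprocessing

The chain is fixed in this order: zero-phase Butterworth band-pass
(0.1–100 Hz; high-pass order 2, low-pass order 4, forward–backward so the
passband is phase-neutral), probability-based noisy-channel detection,
inverse-distance-weighted interpolation of flagged channels, average
re-reference, polyphase resampling to 256 Hz, epoching, per-epoch linear
detrend, crop to −100…1000 ms.

The channel-rejection criterion scores each channel by the mean negative
log-likelihood of its samples under a kernel density estimate of the
pooled amplitude distribution, z-scores those deviances across channels,
and flags z > 5.  This is a from-scratch reading of "probability-based"
rejection; the exact toolbox computation it stands in for is not public
in equation form.  Note the attainable maximum z grows like √(number of
channels), so the 5-SD default is meaningful for 64-channel montages but
conservative for very small ones.  A temporary hardware-reference step is
omitted: simulated data have no reference channel.  No notch filter is
applied.  Zero-phase IIR filtering was chosen over FIR to keep edge
transients short relative to the epoch padding; filter family and order
are config-exposed because reasonable toolboxes differ here.

## Decoding

LDA uses the 64-channel vector at a single timepoint as features (no
temporal stacking) and a pooled within-class covariance shrunk toward a
scaled identity with the analytic Ledoit–Wolf intensity.  Shrinkage is
essential: exemplar-holdout folds can have fewer trials than channels, and
plain LDA would be singular.  The discriminant returns class posteriors;
the larger posterior is the prediction; fold accuracies are averaged (not
pooled) across folds, and subject timecourses are averaged unweighted into
the group timecourse.

Class decoding iterates over exemplar pairs: the i-th low and i-th high
exemplar (after a seeded shuffle of each class) are held out together
with one block — training on k−1 exemplars per class in 11 blocks,
testing on the held-out exemplars in the held-out block, i.e. k × 12
folds per timepoint at full scale (200 × 12 = 2,400).  The pairing rule
is a package choice; only the iteration count is externally constrained.

The same inner loop (in C++ via RcppArmadillo) serves pairwise decoding;
a pure-R implementation of the identical estimator is kept public
(`lda_fit`) and the two routes are held equal in the test suite.
Full-scale pairwise decoding (404,550 pairs × 282 timepoints × 40
subjects) is cluster-scale by construction; the package's own validation
runs use reduced catalogues (8–48 stimuli, 4–8 subjects) chosen to finish
in minutes on one CPU while keeping the full 12-block structure.

## RSA and noise ceiling

The default neural dissimilarity is the cross-validated pairwise decoding
accuracy, which lets the RSA reuse the pairwise analysis unchanged;
correlation distance (1 − Pearson r between per-condition mean patterns)
is provided as a cheaper alternative and both are tagged in the output.
Neural–behavioural correspondence is Spearman's rho on condensed RDMs,
computed per subject and averaged.  The subset analysis restricts both
RDMs to the human-face conditions (840 of 900 at full scale) before
correlating.

The noise ceiling (lower bound) rank-transforms each subject's RDM,
correlates it with the mean rank-transformed RDM of the remaining
subjects, and averages across subjects — an estimate of the best
correlation any model of the group data could achieve.

## Bayes-factor inference

Evidence at each timepoint is a JZS Bayes factor: Cauchy prior with scale
0.707 on the standardised effect size, centred on the null value (0.5 for
accuracies, 0 for correlations).  Interval nulls follow the
truncated-prior construction: the null marginal likelihood integrates the
noncentral-t density against the Cauchy prior truncated to the null
interval ([0, 0.5] one-sided; [−0.5, 0.5] two-sided), the alternative
against the prior truncated to the complementary region (upper tail for
one-sided tests).  A degenerate interval [d, d] reduces to the point-null
JZS t test.  Integration uses adaptive quadrature (`stats::integrate`,
absolute tolerance 10⁻¹⁴, relative 10⁻⁸); the test suite pins the
implementation to an independent fixed-grid Simpson oracle to four
significant figures.  Zero-variance samples return BF = ∞ when the mean
differs from the null value, and fall back to t = 0 otherwise.

Decisions require contiguity: BF > 10 (or < 1/10) must hold for at least
`min_consecutive` (default 2) neighbouring samples; isolated extremes stay
inconclusive.  The onset latency is the first post-stimulus sample whose
decision favours the alternative on the group-level series; the peak is
the post-stimulus argmax of the group mean.  Confidence intervals come
from a percentile bootstrap over subjects (default 1,000 resamples,
seeded) with onset and peak re-derived per resample; resamples with no
reliable sample contribute no onset.  Group-level onset estimation and
the bootstrap design are package choices where conventions genuinely
diverge; both are config-exposed.  With very few subjects a bootstrap
resample can consist of one subject repeated, which yields zero variance
and BF = ∞; intervals are therefore only meaningful for realistic subject
counts (≥ 8).

## Image-statistics controls

Luminance is the mean pixel intensity, contrast the population SD.
Spectral content: 2-D DFT amplitude spectrum (amplitude, not power, by
default; a flag switches), DC excluded because it *is* the luminance,
components binned by rounded integer radial frequency, the per-radius
means forming the radial profile; radii at or below the median radius are
the low band, the rest the high band, and each band's profile mean is
reported.  No windowing is applied before the DFT.  Group comparisons use
the pooled-variance Student t (two-tailed, df = n₁ + n₂ − 2, matching the
printed df = 398 for 200-vs-200 designs), with explicit zero-variance
limits.

## Numerical and degenerate-input choices

* Extreme-group selection breaks rating ties by ascending stimulus id —
  determinism over elegance.
* Spearman p-values use the t approximation with average-rank ties.
* Odd rater counts in the split-half drop one rater at random per
  iteration; stimuli unrated in either half are excluded pairwise.
* The epoch grid is onset-aligned: sample k sits at k·(1000/rate) ms, so
  −100…1000 ms at 256 Hz has 282 samples and the grid spacing is
  3.90625 ms.
* The epoch container stores 32-bit floats (C order) with a JSON sidecar;
  size and event-count mismatches fail before any array is built.
* All randomness is seeded; stage seeds derive from the master seed by
  fixed offsets so one stage's draws never perturb another's.  Identical
  configuration + seed reproduces outputs bit-identically (the pipeline
  manifest records md5 checksums).

## Validation problem sizes

The packaged validation suite runs, per analysis: onset recovery with 8
subjects, 48 stimuli (k = 12 extremes), 24 channels, 12 blocks at 256 Hz
over −100…300 ms; null calibration with 20 seeded 4-subject, 8-stimulus
runs; RSA recovery with 6 subjects and 30 stimuli; and a signal-free
4-subject, 20-stimulus pairwise run for chance-level calibration.  These
sizes are the package's chosen trade-off between Monte-Carlo stability
and a test suite that completes in minutes on a laptop core.

## Known limitations

* Noise is temporally white; decoding onsets on real EEG (autocorrelated
  noise, filtering-induced smearing) can be biased in ways the generator
  does not probe.
* The EEGLAB-style probability criterion and the spherical-spline
  interpolation of production toolboxes are approximated by a KDE
  deviance scan and inverse-distance weighting respectively.
* The exemplar pairing rule, bootstrap CI construction and contiguity
  count are conventions fixed by this package where the field's
  descriptions underdetermine them; all are parameters.
* `correlate_attributes` assumes both attributes were rated over the same
  stimulus set.
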