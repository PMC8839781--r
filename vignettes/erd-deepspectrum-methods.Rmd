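---
title: "Methods: ERD/ERS mapping and deep-spectrum group comparison for tinnitus therapy EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERD/ERS mapping and deep-spectrum group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Auditory discrimination therapy (ADT) is a sound-based tinnitus treatment
built on the oddball paradigm: the patient attends to standard versus
deviant pulses, which is intended to redirect attention away from the
tinnitus percept. Whether the therapy works is usually judged with
questionnaires; `erdeep` implements an *objective* evaluation route based
on EEG recorded while subjects identify familiar sounds in everyday
soundscapes and press a key on each recognition.

The pipeline has four stages:

1. **EEG analysis / preprocessing** — band-pass filtering, bad-channel
   screening, large-amplitude burst rejection.
2. **ERD/ERS mapping** — keypress-locked epochs on the midline frontal
   channel Fz are transformed with a complex Gaussian continuous wavelet
   transform (CWT) and baseline-corrected, giving event-related
   (de)synchronization maps and per-epoch scalogram images.
3. **Deep feature extraction** — each scalogram image is summarized by a
   1280-dimensional *deep spectrum* vector: the global average pool of
   the final feature block of a MobileNet-V2-style convolutional
   backbone.
4. **Comparison analysis** — groups (tinnitus/control) and sessions
   (before/after the 8-week treatment) are compared with
   Lilliefors-screened Student's t-test matrices, a
   difference-in-differences (DID) treatment-effect estimator, and
   centroid/Euclidean-distance summaries.

# Signal model and preprocessing

Recordings are 16-channel, 256 Hz, 10–20 montage, referenced at Cz. The
preprocessing filter is a zero-phase Butterworth band-pass, 0.1–30 Hz,
order 6. Numerically the filter is designed from the closed-form analog
prototype and kept factored as cascaded second-order sections (biquads):
at a 0.1 Hz cutoff the normalized corner frequency is about $8\times
10^{-4}$, where the expanded transfer-function polynomial is so
ill-conditioned that its poles leave the unit circle in double
precision. Each biquad is applied forward and backward (squared
magnitude response, zero phase) with odd reflective padding and
steady-state initial conditions per section, which suppresses the
multi-second edge transients the sub-hertz highpass would otherwise
exhibit. The analytic gain used in the tests is
$|H(f)|^2 = \frac{1}{1+(f/30)^{12}}\cdot\frac{1}{1+(0.1/f)^{12}}$.

Channel screening applies three criteria: a channel is rejected when it
is flat for more than 5 s, when its high-frequency noise exceeds 4
robust standard deviations, or when its best correlation with the other
channels falls below 0.8. "High-frequency noise" is operationalized as
the standard deviation of the channel's 15–30 Hz component, z-scored
robustly (median/MAD) across channels; the band and the all-channels
correlation neighborhood are configuration hooks, since montage
geometry is not shipped.

Burst rejection is a windowed large-amplitude rejector: 0.5 s windows,
a per-channel calibration SD taken over the quietest quartile of
windows, and masking of any window whose RMS *strictly exceeds* 20
times the calibration SD. This is a deliberate simplification of full
artifact subspace reconstruction: it shares the calibration idea and
the 20-SD threshold but rejects whole windows instead of reconstructing
subspaces. Independent-component-based artifact classification is out
of scope (it requires a pretrained third-party classifier); the
pipeline accepts pre-cleaned input instead.

# ERD/ERS maps

Epochs span $[-0.5, +1.0)$ s around each keypress, half-open in samples
(`round(onset*fs) - 128` to `+ 256` at 256 Hz, exactly 384 samples).
Events whose window leaves the recording or touches a burst mask are
dropped and counted, mirroring the subject exclusions of event-poor
recordings.

The analysis wavelet is the $p$-th derivative of the complex Gaussian
$f(x) = C_p e^{-ix} e^{-x^2}$, with $C_p$ fixed by unit $L^2$ norm of
the derivative. The derivative is computed exactly via the polynomial
recurrence $q_{k+1} = q_k' - (i + 2x)\,q_k$, and the normalization is
integrated numerically (trapezoid, grid $[-8, 8]$, $2^{14}$ points; the
Gaussian tail is below $10^{-27}$ at $|x| = 8$). The derivative order is
not dictated by the protocol; the default $p = 4$ balances time and
frequency localization and is configurable over 1–8.

Scales map to frequencies through the wavelet's center frequency,
computed numerically as the location of its spectral peak (the wavelet
is anti-analytic, so the peak is found on the full signed frequency
axis and its magnitude used). CWT kernels are $L^1$-normalized so that
a sinusoid of fixed amplitude produces the same response magnitude at
every scale; this makes the frequency of maximum response coincide with
the stimulus frequency on the analysis grid. Epoch edges are handled by
symmetric reflective padding up to one wavelet support: symmetric
(rather than odd) reflection avoids injecting a DC pedestal that the
large low-frequency kernels would otherwise integrate. No
cone-of-influence masking is applied; maps span the full epoch.

The default frequency grid is 60 log-spaced frequencies in
$[0.5, 30]$ Hz, with a linear option reaching 0.1 Hz. At 1.5 s epochs,
frequencies below roughly 0.7 Hz have wavelet supports longer than the
epoch and are under-resolved; they are kept and documented rather than
silently truncated.

Per-epoch complex coefficient matrices are collapsed by
`average_and_rectify()`. The default `average_then_abs` averages the
complex coefficients across epochs and then rectifies — the literal
reading of the processing description, emphasizing phase-locked
activity. The alternative `abs_then_average` (rectify per epoch, then
average) measures induced power and is the appropriate choice for
non-phase-locked ERS; the two coincide for identical epochs and for a
single epoch. The ordering of averaging, rectification and baseline
correction is genuinely ambiguous in the source protocol; both
orderings are provided and neither is asserted as canonical. The
pipeline default corrects after averaging.

Baseline correction subtracts, per frequency, the mean power over
$[-400, -100]$ ms: $BC(t,f) = P(t,f) - \bar R(f)$. Window endpoints are
converted to samples by rounding and both endpoint samples are included
($-102$ to $-26$ at 256 Hz, 77 samples). Correcting twice is an error.

Scalograms are rendered deterministically at 1200×900 (native figure
size) and resized to 160×160 for the backbone. The colormap (viridis)
is a fixed package choice — the study's colormap is unstated — and it
does affect downstream features, so it is recorded in each image's
metadata sidecar.

# Deep spectrum features

Images are rescaled from $[0,255]$ to $[-1,1]$ via $v/127.5-1$ and
resized bilinearly to 160×160×3. The backbone is a
MobileNet-V2-style depthwise-separable network with output stride 32
and final width 1280: a strided 3×3 stem, inverted-residual blocks
(1×1 expansion ×6, 3×3 depthwise, 1×1 projection, residual where
shapes permit, ReLU6), and a 1×1 head to 1280 channels. At 160×160
input the feature block is 5×5×1280; global average pooling gives the
1280-vector $x^u$ per image. Channel widths (16-24-24-32-64-96) are
kept compact so a forward pass costs a fraction of a second in pure R;
the architectural contract (stride-32 arithmetic, 1280 features) is
what the analysis depends on, not the parameter count.

Weights are seeded He-scaled Gaussian draws by default: a deterministic
random-projection feature extractor that preserves class geometry well
enough for the statistical layer and keeps the package fully testable
offline. ImageNet-pretrained weights can be supplied as a saved weight
list through the `weights` argument for real-data use; no test requires
them.

The classifier head is one dense layer on the pooled vector: 1280
weights + 1 bias = 1281 trainable parameters. Positive logits predict
class 1 (control), negative class 0 (tinnitus); a logit of exactly zero
is class 0, since only positive numbers predict control. Training
follows the fixed recipe — Adam, learning rate $10^{-4}$, dropout 0.2
between pooling and the dense layer (training only), batch size 32, 25
epochs, stratified 80/20 train/validation split — with binary
cross-entropy on the logit (the loss is not stated in the protocol;
cross-entropy is the standard choice for a single-logit binary
classifier). The split is made stratified and seed-controlled. Features
are z-scored with training-split statistics by default, which
random-weight features need for sane optimization scales. The backbone
is frozen throughout.

# Comparison analysis

The statistical layer operates on one scalar $Y$ per scalogram. Which
scalar the original analysis used is not stated; the default here is
the mean of the 1280 feature components, with the distance to a
reference centroid and any single named feature as switchable
alternatives, and the choice recorded in output metadata.

*Normality.* The Lilliefors statistic is the maximum absolute deviation
between the sample ECDF and the normal CDF with estimated mean and SD.
Because the null distribution has no closed form, p-values come from a
seeded Monte-Carlo null table ($10^4$ standard-normal samples per
sample size, cached per session); this supports arbitrary $n$ rather
than the small printed tables. The implementation is cross-checked
against an independent reference implementation in the test suite.

*t-test matrices.* Two-sample Student's t-tests with pooled variance
(Welch optional), coded "+" when $p > 0.05$ (significant relationship)
and "−" when $p < 0.05$ (significant difference). The within design
emits six cohort-level pairings (tinnitus/control crossed over S1/S2
plus both within-group session contrasts); the between design compares
each tinnitus subject's scalograms against the pooled control
scalograms — the only reading consistent with a per-subject table whose
columns are group-level comparisons. No multiple-testing correction is
applied, matching the source analysis; this is a faithfulness choice,
not a statistical recommendation.

*DID.* $Y = \beta_0 + \beta_1\,\mathrm{Time} + \beta_2\,\mathrm{Intervention}
+ \beta_3(\mathrm{Time}\cdot\mathrm{Intervention}) + \varepsilon$, fit by
OLS with 0/1 indicators. $\beta_3$ equals the closed-form difference of
cell-mean differences (asserted to $10^{-10}$ in the tests), and its sign
gives the qualitative label: positive → "Positive effect", otherwise
"Negative effect". Only the point estimate and sign are reported;
standard errors for $\beta_3$ are deliberately out of scope.

*Centroids and distances.* Cell centroids are coordinate-wise means;
per-instance Euclidean distances to a reference centroid are summarized
by their mean and the *population* standard deviation (denominator
$N$), exactly as the summary formulas are printed — the conventional
$N-1$ form is strictly larger for any non-constant sample, and the
tests pin this down. The distance table reports the five pairings of
instances against control centroids; post-treatment convergence of the
tinnitus group toward controls appears as a shorter
Tinnitus-S2-to-control mean distance than Tinnitus-S1.

Box-plot summaries use linear-interpolation quartiles
(`stats::quantile` type 7).

# The synthetic cohort generator

The generator emulates the study design so every stage is testable
without the clinical recordings: two groups × two sessions, 16
channels at 256 Hz, five 1 s auditory stimuli repeated 50 times at a
random rate (the inter-stimulus interval is exposed as configuration,
uniform 0.5–1.5 s by default, since the protocol states only "a random
rate"), one keypress per repetition at stimulus onset plus a sampled
reaction time, $1/f$ background noise (spectral shaping of white noise,
exponent 1.0, 10 µV SD), and event-locked Hann-windowed sinusoidal
bursts in configured bands. The burst shape is a package choice — the
study recorded real EEG and specifies no generative model — selected
for band-limited, artifact-free injection with analytically known
power ($a^2 \cdot \overline{w^2}/2$ for envelope $w$).

The default effect profile encodes the qualitative pattern the analysis
is meant to detect: controls show an alpha (8–13 Hz) ERS in both
sessions; tinnitus patients lack it before treatment, show late
25–30 Hz activity after 500 ms instead, and regain the alpha response
after treatment. Reaction times are uniform 0–1 s before treatment and
uniform 0–0.5 s after, mirroring the reported tightening of response
latencies. Every recording derives its own RNG stream from the master
seed and its (group, session, subject) cell, so regenerating a cohort
is bit-stable and changing one cell's configuration cannot perturb
another's stream.

What the generator does *not* emulate: ocular/muscular artifact
morphology (bursts for the rejection tests are synthetic amplitude
excursions), volume-conduction topography (bursts are injected
montage-wide), subject-level heterogeneity of tinnitus
characteristics, and the acoustic content of the soundscapes. Passing
tests therefore demonstrate that the pipeline recovers known injected
structure under realistic noise — not that it reproduces the clinical
findings, which require the original recordings.

The scalogram fixture generator produces the four-class image corpus
(801/667/500/500 by default, 2468 images) as class-conditional Gaussian
blobs at class-specific time-frequency positions plus pixel noise, with
a `separation` dial scaling the between-class contrast; at separation 0
the classes are exchangeable and a trained head stays at chance.

# Problem sizes and numerical choices in the test suite

The suites run the full-size protocol only where the test is about it
(event counts, the 2468-image corpus at reduced resolution). Elsewhere
cohorts are scaled down — typically 1–2 subjects per group, 2 stimuli ×
2–8 repetitions, 24–40 analysis frequencies — which keeps the recovery
and determinism checks inside a few minutes while exercising identical
code paths. Monte-Carlo checks use 20 seeds (DID recovery, within two
Monte-Carlo standard errors), 100 seeds (null calibration of the
comparison matrix at a per-cell "−" rate inside $[0.01, 0.10]$), and
1000 replicates (Lilliefors type-I rate inside $[0.03, 0.07]$).

Degenerate inputs are defined, not accidental: a t-test of two
zero-variance samples with equal means returns $p = 1$ rather than an
error; a burst window at exactly 20× the calibration SD is *not*
masked ("exceeded" is strict); correcting a baseline twice, empty
group/session cells, ragged feature vectors, collinear DID designs and
untrained heads all raise explicit errors.

# Known limitations

- Random-weight deep features are a geometry-preserving projection, not
  semantic features; absolute classification accuracies are not
  comparable to pretrained-backbone results.
- Frequencies below ~0.7 Hz are under-resolved at 1.5 s epochs.
- The burst rejector removes whole windows; it does not reconstruct the
  underlying signal.
- Band-resolved (theta/alpha/beta) feature comparisons and
  multi-channel topographic maps are out of scope.
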