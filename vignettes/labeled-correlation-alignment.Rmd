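---
title: "Labeled correlation alignment of EEG and audio features: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labeled correlation alignment of EEG and audio features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcasonify)
```

## The model

The package estimates how strongly multichannel EEG responses are coupled
to the auditory stimuli that elicited them, *conditioned on emotion
labels*, and uses the coupled representation to generate acoustic
envelopes. The pipeline has three stages.

### Windowed features

EEG epochs (trials × channels × samples, epoched at stimulus onset) pass
through a fixed conditioning chain — zero-phase 3rd-order Butterworth
bandpass 1–45 Hz, channel removal (presets `E17`: drop O1/O2; `E14`:
additionally drop Fp1/Fp2/Pz), common-average referencing, downsampling
to 80 Hz — before Hann-tapered windowing with 50% overlap. The window
grid τ ∈ {12, 6, 3, 1.5, 0.75, 0.375} s tiles a 12-s trial into
M_τ = ⌊(T − τ)/(τ/2)⌋ + 1 full windows; trailing remainders are dropped
so that formula is exact. Rhythm-specific copies (θ 4–8, α 8–12,
β 12–30 Hz) re-run the same Butterworth design per band.

Per window, two functional-connectivity measures fill an
N_φ × N_φ matrix whose strict upper triangle (row-major) is vectorized:

* **PLV** — modulus of the time-averaged unit phasor of the
  instantaneous-phase difference. Phases come from the analytic signal
  (FFT Hilbert construction) of the already band-limited, tapered
  window; the first and last 5% of samples are excluded from the
  average because the analytic signal is distorted at the edges.
  PLV is amplitude-invariant by construction.
* **GFC** — `exp(−‖x_c − x_c′‖²/2σ²)` on per-channel z-scored windows.
  Without z-scoring the distance is dominated by amplitude offsets that
  common-average referencing does not fully remove; with it, GFC sees
  waveform similarity and (through the signal-to-noise ratio) relative
  amplitude structure that PLV cannot. σ is selected on a grid of 20
  log-spaced values spanning 0.1–10× the median pairwise distance by
  maximizing the variance of the off-diagonal kernel values: both
  σ → 0 (all values 0) and σ → ∞ (all values 1) kill the variance, so
  the maximizer is interior. A degenerate profile (e.g. a single pair)
  falls back to the grid median with a warning. The selection criterion
  is implemented as the printed arg-max-of-variance rule; the
  accompanying prose reading ("reduce variability") contradicts it, and
  we follow the formula.

Audio windows (same τ grid in seconds — seconds are the synchronization
contract between modalities, since the two sampling rates differ) yield
20 descriptors per 2048-sample frame: zero-crossing rate, high/low
energy ratio (1500 Hz split), spectral entropy, spread, roll-off (85%),
flatness (geometric/arithmetic mean of the *magnitude* spectrum, whose
white-noise value ≈ 0.85 matches the calibrated threshold), roughness
(pairwise Plomp–Levelt-style interaction of the strongest spectral
peaks), RMS, broadband spectral flux, spectral centroid, and flux in ten
octave bands anchored at 31.25 Hz. The published descriptor list names
zero-crossing rate twice while counting 20; we fill the duplicate slot
with spectral centroid, a standard member of the same music-information
family. Frame trajectories are reduced to one value per descriptor per
window by projecting onto the first principal axis and taking the
projection of the window-mean frame (the mean of centered scores is
identically zero, so the uncentered projection is the meaningful
summary). Each window is completed with N_φ − 1 samples drawn evenly
from that window's envelope — we read the per-window placement from the
dimension formula Q = N_τ(20 + N_φ − 1), which it makes exact. The
envelope itself is squared, smoothed with a 125-ms square window
(passing amplitude modulation below ~8 Hz), resampled to 64 Hz, and
cube-root compressed; the smoothing makes plain interpolation a safe
resampler.

### Two-step alignment

Step one learns, independently per modality, a weighting matrix W
(P × d) maximizing the centered kernel alignment between the Gaussian
kernel `exp(−‖(ξ_i−ξ_j)ᵀW‖²/2)` and the label delta kernel. Features
are standardized column-wise first (the Gaussian kernel is scale
sensitive; the published formulation leaves this open and
standardization is the conservative choice). The optimizer is
full-batch gradient ascent with an adaptive step (accepted steps grow
it ×1.2, rejections halve it), stopping after 500 iterations or when
the relative alignment change over 10 accepted steps falls below 1e-6.
W is initialized from the leading directions of the centered class-mean
matrix — the natural supervised subspace for a label-alignment
objective — padded with principal axes when d exceeds the class count,
and scaled so the median projected pairwise squared distance is ~2 (a
usable kernel length scale). The init is deterministic, which makes the
whole fit reproducible without seeding. The rank default d = min(P, 32)
regularizes and speeds the fit; only WᵀW enters the kernel, so rank
reduction loses nothing the objective can see. "Selection" is realized
as soft weighting through the projection ξW (the learned metric), not
hard thresholding — relevance is continuous in this method and the
projection is what the next stage consumes.

Step two is CCA on the projected blocks with a ridge term
(default 1e-3 × mean auto-covariance diagonal) because P and Q can
approach the number of trials; whitening by symmetric inverse square
roots, SVD of the whitened cross-covariance, first pair only (the
single-dimensionality latent subspace). The first nonzero entry of the
EEG-side loading is forced positive for reproducible signs.
Rank-deficient inputs with the ridge disabled raise an error with
guidance rather than silently pseudo-inverting.

Relevance of feature p is ‖row p of W‖₂ normalized to sum one;
electrode relevance averages it over all features whose channel pair
contains the electrode and normalizes to maximum one. This is the
backward transformation that makes the fit physiologically readable.

### Partition quality and evaluation

The statistic γ combines a per-sample silhouette term
(ξ₁ − ξ₀)/max(ξ₀, ξ₁) — ξ₀ the mean distance to the sample's own group,
ξ₁ to the nearest other group, the standard silhouette denominator
resolving the printed formula's unstated index set — with the mean
squared distance to group centers. The additive composition is kept
verbatim as the default, but note its scatter term *increases* with
intra-class spread, which contradicts "larger γ = more separable"; both
terms are therefore reported separately and a `variant = "silhouette"`
switch drops the scatter term. Comparisons that ask "which fit separates
labels better" (two-step vs single-step CCA) use the silhouette
variant, because the unit-variance CCA constraint makes the scatter
term maximal exactly when labels are *not* separated, inverting the
additive statistic's ordering.

Leave-one-subject-out refits the full two-step alignment on the pooled
remaining subjects and evaluates r² on the held-out subject's projected
features; dynamic resolution is the mean absolute difference of
neighboring windowed r² values; `lca_sweep()` re-runs extraction and
alignment along one axis (window, band, electrode set, subject),
reporting both the fit-level r² and the per-label mean (correlation
within each label's trials, then averaged), since published summaries
average across the label set.

## The synthetic-data module

The generator is first-class, tested code; its defaults are the study
conditions (40 trials × 12 s per subject, 19-channel 10–20 montage,
1 kHz raw rate, the four arousal–valence quadrant labels).

* **EEG**: white noise mixed through a per-label channel matrix
  (I + amp_mix·R) plants label-dependent amplitude covariance — visible
  to GFC, invisible to PLV; coupled channel pairs additionally share a
  narrowband sinusoid (10 Hz) with a per-trial random phase and a fixed
  lag, so PLV of a planted pair is analytically 1 in the noiseless
  limit. The noise standard deviation may be 0 for exactly that
  contract. An optional `amp` column in `coupled_pairs` grades the
  coupling strength per label (so one pair can encode labels through
  its strength), and `coupling_jitter` adds a per-trial log-normal
  amplitude latent, returned as an attribute, that lets a synthetic
  audio block co-vary with the coupling.
* **Audio**: four distinct attack/decay envelope templates (one per
  label) modulating a fixed harmonic carrier with small seeded jitter.
* **Abstract features**: one shared standard-normal latent placed in
  the first column of each block as `√ρ·z + √(1−ρ)·e` (unit variance,
  population first canonical correlation exactly ρ); disjoint columns
  of X carry label mean shifts; everything else is isotropic noise.
  `latent_label_sep` shifts the latent's mean per label, making the
  canonical pair itself label-separated (used by the two-step-vs-
  single-step comparison; it perturbs the exact-ρ contract).
  `x_profile` distributes the latent across all X columns with a given
  unit-norm profile — used to emulate windowed feature *sequences*
  whose canonical direction is smooth along the window axis, which is
  what makes alignment-projected sonification visibly smoother than raw
  sonification.

What the generator does **not** emulate: eye-blink/muscle/line
artifacts, 1/f spectra, volume conduction, real musical excerpts, or
nonstationarity beyond the planted structure. Green tests therefore
demonstrate the estimators' correctness and calibration on known ground
truth, not performance on recorded EEG.

## The sonification stage

The VQ-VAE is deliberately compact and hand-differentiated: a
segment-wise (stride = kernel = 8 samples) encoder — tanh hidden layer,
linear map to a D-dimensional latent — nearest-neighbour quantization
against a K-entry codebook (ties to the lowest index), and a mirrored
decoder with a softplus head because envelopes are nonnegative.
Defaults K = 64, D = 16, hidden 32, β = 0.25 (within the unit
interval), Adam at 0.02 for 300 full-batch epochs — sizes chosen so
envelope sets of ≤768 samples train in seconds on one CPU; the
published architecture leaves all of them open. The three-term
objective routes gradients exactly as the stop-gradient notation
prescribes: reconstruction → decoder and (straight-through) encoder;
codebook term → codebook only (the published gradient rule, not
exponential moving averages); β-weighted commitment → encoder only.
Dead codebook entries are re-seeded each epoch from the worst-quantized
latents, a deterministic rescue that keeps the codebook covered.
Training aborts with diagnostics if the loss goes non-finite.

EEG features reach the encoder through a convolution-style front
projection: each output sample has a Gaussian-bump receptive field over
the feature index with 5% seeded weight jitter and a softplus
nonlinearity, and the resulting sequences are affinely calibrated to
the training envelopes' mean and spread (the coder demands inputs of
its training scale and dimension). With `smoothing = TRUE` the features
are first replaced by their rank-1 reconstruction along the fitted
canonical EEG direction — the alignment-selected representation — which
strips off-direction noise; raw features keep it, and their decoded
envelopes show more abrupt changes. The spectral transfer check
(95%-energy bandwidths within a tolerance, dimensions equal) is a
report-only operation; `sonify()` enforces it only when given a
training reference, because sharp-attack envelopes legitimately carry
high bandwidth and the caller knows which comparison is meaningful.

## Numerical and testing choices

* All stochastic stages consume explicit integer seeds and are
  bit-reproducible single-threaded; deterministic fits (CKA, CCA) need
  no seed at all.
* Degenerate inputs have defined behaviour: all-zero signals are
  rejected for phase extraction; constant descriptor trajectories
  summarize to 0 with a warning; an all-zero weighting yields a uniform
  relevance map with a warning; silent audio yields a zero envelope.
* Test and acceptance problem sizes are scaled-down study analogues
  chosen once — e.g. 8-channel montages at 64 Hz with 3-s trials for
  electrode recovery, n = 100–500 and P, Q ≤ 80 for the alignment and
  CCA calibrations, 64-sample envelopes for the autoencoder — so the
  full suite runs in minutes while every planted structure stays
  detectable at its stated success rate.
* The permutation-null calibration of the CKA fit compares fresh
  shuffled-label fits against the band (range) of 500 label-permutation
  refits on one reference realization of the same size: both routes fit
  random labels, so the check verifies the fitted-alignment
  distribution is stable across data realizations.

## Known limitations

* The CKA alignment *value* saturates on small trial counts (a flexible
  metric can align almost any kernel to the labels), so the value alone
  is not evidence of label structure; the calibrated permutation band
  and the relevance *pattern* carry the signal.
* GFC's z-scoring discards absolute amplitude; amplitude information
  enters only through signal-to-noise structure.
* The 3rd-order Butterworth band splits have shallow roll-offs: strong
  narrowband activity leaks into neighbouring rhythm bands, which the
  band-sweep test accounts for by burying the leaked component in
  broadband noise.
* The sonifier is a low-level envelope generator, not an audio-fidelity
  model; symbolic/MIDI structure and learned spectral priors are out of
  scope.
* Real-data claims (per-subject rankings, absolute r² ranges on the
  public music-listening dataset) require that dataset and are not
  reproduced here.
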