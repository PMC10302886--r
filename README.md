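# lcasonify

Couples multichannel EEG responses to affective auditory stimuli through
**Labeled Correlation Alignment (LCA)** and sonifies the EEG-selected
features back into acoustic envelopes.

## The problem

In affective music-listening experiments, participants hear short musical
clips labeled by arousal–valence quadrant (HAPV, HANV, LANV, LAPV) while
multichannel EEG is recorded. Two questions follow: *which* brain-response
features co-vary with the eliciting audio under each emotion, and can those
features drive the *generation* of new, emotion-distinct sound? Plain
canonical correlation between EEG and audio feature blocks is easily
swamped by the noise and inter-subject variability of EEG, and it ignores
the emotion labels entirely.

## The method

1. **Feature extraction.** EEG epochs are bandpassed (zero-phase 3rd-order
   Butterworth, 1–45 Hz, plus θ 4–8 / α 8–12 / β 12–30 Hz variants),
   re-referenced to the common average, downsampled, and cut into
   Hann-tapered windows with 50% overlap (τ ∈ {12, 6, 3, 1.5, 0.75,
   0.375} s). Per window, two functional-connectivity measures are computed
   for every channel pair *(c, c′)* and vectorized (N_FC = N_φ(N_φ−1)/2
   values per matrix):

   - phase locking value `PLV = |E_t exp(j(φ_c(t) − φ_c′(t)))|`,
   - Gaussian functional connectivity
     `GFC = exp(−‖x_c − x_c′‖² / 2σ²)`, σ chosen by maximizing the
     variance of the kernel values over a grid.

   Audio windows yield 20 spectral/temporal descriptors (first-PCA-reduced
   over frames) plus N_φ−1 samples of the cube-root-compressed 64 Hz
   envelope, so Q = N_τ(20 + N_φ − 1).

2. **Two-step alignment.** For each modality Ξ ∈ {X, Y}, a weighting
   matrix W_Ξ is learned by maximizing the **centered kernel alignment**
   between the Gaussian kernel `κ(ξ, ξ′) = exp(−‖(ξ−ξ′)ᵀW‖²/2)` and the
   delta kernel on the labels:

       W* = argmax ⟨K̄_Ξ(W), K̄_Λ⟩_F / (‖K̄_Ξ(W)‖_F ‖K̄_Λ‖_F)

   Then **CCA** finds the first canonical pair of the projected blocks
   X̃ = XW_X, Ỹ = YW_Y under unit-variance constraints; r² measures the
   stimulus–response coupling. Back-projecting ‖rows of W_X‖ onto channel
   pairs yields per-electrode relevance maps. A silhouette-style partition
   statistic γ scores how well the canonical variates separate the four
   emotion labels, and leave-one-subject-out folds give confidence bands.

3. **Sonification.** A compact vector-quantized variational autoencoder
   (VQ-VAE) is trained on acoustic envelopes with the three-term objective
   (reconstruction + codebook + β·commitment, stop-gradients as usual) and
   then driven by LCA-selected EEG features through a convolution-style
   front projection, generating label-distinct envelopes.

Everything is testable offline: a seeded synthetic module plants phase
coupling between named electrodes, label-dependent amplitude covariance,
label-templated audio envelopes, and a known canonical correlation.

## Worked example

```r
library(lcasonify)

# EEG with a 10 Hz oscillator shared by (F3, F4), amplitude graded by label
spec <- coupling_spec(
  n_channels = 8,
  channel_names = c("F3","F4","C3","C4","P3","P4","O1","O2"),
  fs_eeg = 64, trial_length = 3, n_trials_per_subject = 32,
  coupled_pairs = data.frame(ch1 = "F3", ch2 = "F4",
                             label = c("HAPV","HANV","LANV"),
                             amp = c(1.5, 1, 0.5)),
  noise_sd = 0.4, amp_mix = 0, seed = 1)
eeg <- gen_eeg_trials(spec)

fx  <- extract_fc_features(eeg, window_grid(3, 3), bands = "broadband")
ck  <- fit_cka(fx$values, fx$labels, d = 1, max_iter = 60)
electrode_relevance(feature_relevance(ck), fx$index)
```

```
# A tibble: 8 × 2
  electrode relevance
  <chr>         <dbl>
1 F4            1
2 F3            0.944
3 P4            0.777
4 P3            0.751
5 C3            0.739
6 O2            0.702
7 O1            0.587
8 C4            0.552
```

The two planted electrodes rank first, clearly above every uncoupled
channel: the supervised alignment step has recovered the pair whose
coupling strength encodes the labels. A full two-step fit against a
coupled feature block reports the canonical correlation, the per-modality
label alignments, and the label separation of the canonical variates:

```r
g   <- gen_coupled_features(200, 10, 10, rho = 0.8, label_sep = 2, seed = 1)
fit <- lca(g$X, g$Y, g$labels, d = 4)
glance(fit)
```

```
# A tibble: 1 × 6
      r r_squared alignment_x alignment_y two_step     n
  <dbl>     <dbl>       <dbl>       <dbl> <lgl>    <int>
1 0.641     0.411       0.224       0.161 TRUE       200
```

(The two-step r trades a little raw correlation for label alignment; the
plain CCA route `fit_cca(g$X, g$Y)` returns r = 0.81 here, recovering the
planted ρ = 0.8 within sampling error.)

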