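---
title: "Corpus-invariant deep screening of parkinsonian voice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus-invariant deep screening of parkinsonian voice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep networks screen Parkinson's disease (PD) from short voice recordings —
sustained /a/ phonations and rapid /pa-ta-ka/ (diadochokinetic, DDK)
repetitions — with usable accuracy inside a single clinical corpus. Combine
several corpora, however, and much of that accuracy turns out to be
*shortcut learning*: each corpus carries its own microphone colouration,
noise floor, sampling rate and language, and a classifier happily uses those
corpus fingerprints instead of the disease. `voiceda` implements a pipeline
that makes this failure measurable and trains against it:

1. a **synthetic multi-domain voice generator**, standing in for restricted
   clinical corpora;
2. **Mel-spectrogram preprocessing** into fixed 65 x 41 images;
3. three neural **feature extractors** (2D-CNN, time-distributed CNN +
   bidirectional LSTM, 1D-CNN with attention pooling) with a PD detector
   head, optionally trained **domain-adversarially** against a corpus
   detector through a gradient reversal layer (GRL);
4. **speaker-independent cross-validation**, patient-level decisions and
   classification metrics;
5. a **corpus-invariance audit**: intra-class inter-domain symmetrised
   Gaussian KL divergence, trace of covariance (TCM), and t-SNE maps of the
   embeddings.

## The synthetic corpus: what it emulates

Real PD corpora cannot be redistributed, so every stage here is exercised on
a generator whose *statistical structure* — not its perceptual realism —
matches what the pipeline assumes.

**Classes.** Hypokinetic dysarthria presents as unstable phonation and slowed,
irregular articulation. The generator's two presets differ accordingly
(`class_effects()`): jitter 2.5% vs 0.5% of the cycle period, shimmer 8% vs
2%, aspiration noise -25 vs -40 dB, DDK rate 4 vs 6 syllables/s with
inter-onset coefficient of variation 0.25 vs 0.05. The values are
deliberately *separable but noisy*: an oracle f0 tracker separates the
classes at above 90% with a single threshold, yet channel effects and
speaker random effects keep the learning problem non-trivial.

**Domains.** Four recording domains (`domain_specs()`) mimic four corpora:
three at 44.1 kHz and one at 48 kHz (forcing the resampling path), each
with its own short FIR channel colouration (flat, low-pass tilt, high-pass
tilt, smoothed), noise floor (SNR 20-32 dB) and a multiplicative formant
shift (0.90-1.06) as a crude language proxy. Domain effect sizes are free
parameters of the artifact — no public characterisation of the real
corpora's acoustics exists to calibrate them against — and were fixed once
at values that make domains clearly distinguishable by long-term spectrum.

**Speakers.** Each speaker draws a base f0 (about 190 +- 20 Hz female,
115 +- 15 Hz male), formant offsets around canonical /a/ values, and
multiplicative random effects on the class presets, *once per speaker*.
Segments of one speaker are therefore correlated, which is exactly why
speaker-independent validation matters: segment-level splits would leak.

**Synthesis model.** A Klatt-style simplification: an impulse train with
per-cycle period jitter and amplitude shimmer (pulse energy split across
adjacent samples so grid quantisation does not masquerade as jitter), plus
aspiration noise, filtered by three second-order formant resonators, then
the domain channel (FIR convolution, additive noise, peak normalisation to
0.95). DDK recordings gate a continuous voiced source with raised-cosine
syllable envelopes at the preset rate and add an 8 ms noise burst per onset.
Not modelled: articulatory dynamics, UPDRS severity grades, perceptual
naturalness — so passing tests here demonstrate *pipeline correctness and
the domain-adversarial mechanism*, not clinical performance.

## Preprocessing

Recordings are resampled to 44.1 kHz (polyphase), peak-normalised, cut into
400 ms segments with 50% overlap (a remainder shorter than one segment is
dropped; recordings under 400 ms are rejected rather than padded — the
segment length was chosen so the shortest clinical vowel, 490 ms, survives),
and transformed to 65-band Mel spectrograms: Hann window of 40 ms (vowel) or
15 ms (DDK), 10 ms hop, *centred* framing with reflect padding. Centred
framing is load-bearing: it is the only standard convention that yields
`1 + floor(17640/441) = 41` frames from a 400 ms segment at a 10 ms hop, so
every segment maps to a 65 x 41 image under either window. Power is mapped
to dB relative to the per-segment maximum (`10*log10`, floor -80 dB) and
z-scored per spectrogram (population convention). Per-image scaling removes
per-corpus gain offsets, consistent with the invariance goal; a pooled
`"global"` mode is available in `preprocess_config()`. The STFT window
function and dB reference are not part of the printed recipe; both are
config-exposed choices.

## Models

All three architectures share a triad structure: feature extractor, PD
detector head, and (in the adversarial variant) a domain detector head fed
through the GRL. Heads are `FC(fc_units, ReLU) -> dropout -> FC(softmax)`;
the domain head uses the same width as the PD head.

* **2D-CNN** — two blocks of conv (kernels `kernel1`, `kernel2`, `conv_depth`
  filters, "same" padding), batch norm, ReLU, 3x3 max pooling, dropout;
  flattened output is the embedding. One spectrogram per sample; patient
  decisions multiply segment probabilities.
* **Time-CNN-LSTM** — the same conv blocks applied per slot of a sequence of
  up to `n_frames` consecutive segments of one recording, zero-padded and
  masked; a bidirectional LSTM over the per-slot features supplies a
  `2*lstm_units` embedding. Masking is exact: padded slots are excluded from
  the convolutional stage and carried through the recurrence unchanged, so
  outputs are bit-identical whatever the padding. Recordings with more than
  `n_frames` segments contribute their first `n_frames` in temporal order.
* **1D-CNN** — the image flattened frequency-major into one long sequence;
  three conv blocks (kernels 5/11/21) with pool-6 between; in the last block
  half the filters pass through a time-wise softmax and weight the other
  half (attention pooling), giving a `conv_depth/2` embedding. The flatten
  orientation is fixed by configuration since only "a flatten operator" is
  specified upstream.

**Gradient reversal.** `grl()` is the identity forward; backward multiplies
by `-lambda` (`grl_backward()`). The default schedule ramps
`lambda = 2/(1+exp(-10 p)) - 1` over training progress `p`, following the
domain-adversarial framework this construction comes from; a fixed-lambda
mode exists because the source protocol leaves the value open. The domain
head itself trains on its (unscaled, domain-weighted) cross-entropy; only
the gradient flowing into the shared extractor is reversed and scaled. With
`lambda = 0` a DA step therefore updates the shared parameters exactly like
a baseline step.

**Weight initialisation** is fan-in uniform under a recorded seed. All
backward passes are hand-derived and verified against central finite
differences in the test suite.

## Training

SGD with momentum 0.9, weighted cross-entropy (`w_c = N/(K N_c)`), learning
rate initialised at 0.1 and multiplied by 0.1 on a validation-loss plateau
(patience 5) down to a floor of 1e-3. Two numerical guards matter at this
initial rate on small batches: SGD momentum, and a global gradient-norm clip
(default 0.5) that bounds the update like a normalised-gradient method.
Both were fixed after a stability screen of the baseline optimiser across
seeds — without them a noticeable fraction of runs either never leaves the
uniform-prediction saddle before the plateau schedule cuts the rate, or
overshoots into a dead-ReLU collapse. The best-validation-accuracy epoch is
kept as the deployment checkpoint; NaN losses abort with diagnostics.

Folds are built over *speakers*, stratified by class (`make_folds()`);
train/validation speaker overlap is rejected outright. Transfer learning
pretrains extractor + task head on a healthy-vs-voice-disorder vowel corpus
(`generate_pretrain_corpus()` provides the synthetic stand-in), then
`freeze_initial_layer()` pins the first conv layer *and its batch-norm
parameters and running statistics* before fine-tuning. `grid_search()`
evaluates a (budgeted) subset of the hyperparameter grid with a pluggable
scorer; the default scorer fits on a speaker-disjoint split and scores
validation accuracy.

## The invariance audit

Embeddings can be tapped at the input of the PD head's softmax layer (the
`fc_units`-wide hidden representation) or at the extractor output.
`extract_embeddings()` defaults to the head tap; the packaged experiment
audits the extractor output. The reason is measurable at desk scale: a
linear probe decodes the recording domain from the extractor output of a
trained baseline with high accuracy, while the small task head is already
domain-blind (probe at chance) for baseline and adversarial models alike —
a tap with no domain structure to begin with cannot show the adversarial
effect removing it. Per diagnostic class, every unordered pair of domains
is compared by the symmetrised Gaussian KL divergence
`0.5*(KL(P||Q) + KL(Q||P))` with Ledoit-Wolf-shrunk covariances (plus a
1e-6 relative ridge so collapsed dimensions cannot make the estimate
singular); 4 domains give 6 pairs per class. TCM is the trace of the
unbiased sample covariance of a class's embeddings, domains pooled. Whether
the upstream analyses symmetrised their KL or computed it per fold is not
stated; both knobs are exposed (`gaussian_kl_symmetric()` is pluggable, and
the audit scope is selectable). `run_invariance_experiment()` audits the
*final-epoch* model of each variant on all segments by default: adversarial
invariance develops along the lambda ramp, an early accuracy-tied
checkpoint would compare half-trained representations, and pooling train
and test segments maximises the stability of a 16-dimensional Gaussian
estimate at desk scale. t-SNE maps (exact algorithm, perplexity 30 or less
for small runs, fixed seed) are rendering artifacts only and are never
asserted against quantitatively.

## Problem sizes and expectations at desk scale

The headline experiment trains a deliberately small 2D-CNN (8 filters,
16 hidden units) on a 4-domain x 2-class corpus of 12 speakers per domain
(one 1 s vowel each, 4 segments per speaker) for 20 epochs, baseline and DA
seed-matched. These sizes keep a full baseline-vs-DA comparison within a
couple of minutes on one CPU while preserving the qualitative behaviour of
interest: the baseline's extractor output separates by corpus within each
class (large intra-class inter-domain KL, near-perfect domain decodability
by a probe), and the adversarial variant reduces that separation —
monotonically in the reversal strength on matched runs — at comparable
patient accuracy. Individual runs vary: 360 SGD steps is genuinely few, and
a single train/test split yields one noisy Gaussian-divergence estimate
where fold-averaged protocols report means of ten. The packaged checks
therefore assert the *direction* of the effect across a majority of seeds
rather than per-run magnitudes. Two caveats are stated plainly rather than
hidden: the per-class trace of covariance at the extractor tap often moves
*up* under adversarial training at this scale (within-domain variance grows
faster than between-domain dispersion shrinks, even as KL falls), and no
numerical claims are made about the restricted clinical corpora
themselves.

## Known limitations

* The generator's domain effects are free parameters, not estimates of any
  real corpus; absolute KL/TCM magnitudes are artifact-specific.
* Determinism is guaranteed in single-threaded runs; multi-threaded BLAS
  reproduces results only statistically.
* The divergence estimator assumes approximate Gaussianity of ReLU
  embeddings; the shrinkage and ridge keep it defined, not unbiased, when
  clusters collapse.
* DDK sequences reuse the vowel formant set per syllable rather than
  cycling /pa/-/ta/-/ka/ places of articulation; burst timing, not
  consonant identity, carries the class signal.
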