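---
title: "Supervised contrastive fine-tuning for voice-based Parkinson's detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised contrastive fine-tuning for voice-based Parkinson's detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(supconvoice)
```

## The problem

Hypokinetic dysarthria is among the earliest functional signs of
Parkinson's disease (PD). Relative to healthy speech it shows elevated
cycle-to-cycle perturbation of the vocal fundamental frequency (jitter)
and of cycle amplitudes (shimmer), reduced F0 range (monotone pitch),
added aspiration noise from incomplete glottal closure, reduced vocal
intensity, and a slower speaking rate. `supconvoice` implements a complete
pipeline for detecting these phonatory/prosodic signatures from short
sentence recordings: preprocessing, hand-crafted acoustic baselines, a
dual-head neural classifier trained with a multi-positive supervised
contrastive objective, a speaker-independent evaluation protocol, and
Grad-CAM explanations over the waveform.

## The model

A frame-level speech encoder maps a fixed-length waveform to a `T x d`
matrix of contextual frame embeddings (in large pre-trained encoders,
`d = 768` at a 20 ms hop). Frames are mean-pooled to one utterance
embedding, which feeds two heads:

* a **classification head** — linear `d -> 64`, ReLU, dropout 0.2, linear
  `64 -> 2` logits;
* a **projection head** — a two-layer perceptron `d -> 128 -> p`
  (default `p = 32`) followed by L2 normalization onto the unit
  hypersphere.

Training is single-phase. The projections `z` carry the supervised
contrastive loss

$$
L = \sum_{i \in I} \frac{-1}{|P(i)|} \sum_{p \in P(i)}
  \log \frac{\exp(\mathrm{sim}(z_i, z_p) / \tau)}
            {\sum_{a \in A(i)} \exp(\mathrm{sim}(z_i, z_a) / \tau)},
$$

with `sim` the cosine similarity, `P(i)` the same-label batch members
other than the anchor `i`, and `A(i)` all members other than the anchor
(positives included in the denominator — the loss is implemented exactly
as printed). The temperature is `tau = 0.07`. For each anchor, the
`hard_k` most similar negatives (default one) have their denominator
terms multiplied by a **hard-pair scaling** factor of 1.5, sharpening
gradients on the hardest confusions; at scale 1 the plain loss is
recovered bit-for-bit. A softmax cross-entropy loss on the classifier
complements the contrastive loss with unit weight — but the classifier
reads a **gradient-detached copy** of the utterance embedding, so
classification error can never update the encoder; only the contrastive
pathway shapes the representation. `CE_ONLY` mode removes the detachment
and the projection path, giving plain fine-tuning as the comparison
condition.

Anchors whose batch contains no same-label partner are skipped (their
`1/|P(i)|` is undefined); this follows the usual multi-positive
convention. Log-sum-exp terms are evaluated with max-subtraction, so the
loss is finite even at `tau = 0.01` with near-duplicate projections.

### Optimization

AdamW (`beta1 = 0.9`, `beta2 = 0.999`, decoupled weight decay 0.01,
never applied to biases or normalization gains), batch size 32, cosine
annealing from the initial learning rate, up to 100 epochs with early
stopping: after each epoch a validation metric is computed and the
best-scoring epoch's parameters are retained; training halts after
`patience` (default 15) epochs without improvement. The monitor is
validation AUC by default (F1 selectable): validation folds hold only a
few speakers, and the threshold-free AUC is a much smoother selection
signal there than thresholded F1. The published fine-tuning rate of 2e-5
suits large pre-trained encoders; the bundled tiny encoder trains from
scratch and uses 1e-3 in the desk-scale experiments, with encoder updates
additionally scaled by `encoder_lr_scale` (default 0.1) so representation
fine-tuning is gentler than the training of the freshly initialized heads
— without it the encoder memorizes the small training speaker set before
the transferable cues are found. All loops are bit-reproducible from
their seed.

## The tiny encoder

No GPU-scale pre-trained encoder ships with the package; instead
`make_tiny_encoder()` provides a small, fully trainable encoder honouring
the same contract (waveform in, `T x d` frames out, selectable layer):

* a strided linear patch embedding (stride 320 samples = the 20 ms hop at
  16 kHz), whose filters are **initialized as a Hamming-windowed,
  mel-spaced cosine/sine filterbank**, followed by half-wave
  rectification and `log(1 + 50 x)` compression — a learnable analogue of
  the log-mel front end used across audio modelling;
* `n_layers` single-head self-attention blocks with pre-norm feed-forward
  sublayers, whose residual-branch output projections are initialized
  near zero (identity-preserving initialization). By default the
  *attention* sublayer reads the unnormalized residual stream (post-norm
  style, with down-scaled query/key initialization): layer-normalizing the
  attention input removes each frame's overall energy from the query/key
  comparison, and with it the model's ability to learn energy-selective
  (max-like) temporal weighting; a `prenorm_attention` switch restores
  the fully pre-norm variant.

Both choices are load-bearing at desk scale. With random filters and
full-scale residual branches, the layer-normalized attention outputs
swamp the front-end features and erase exactly the amplitude and
spectral-balance cues that distinguish the classes; ridge probes on
frozen embeddings sit at chance. With the filterbank + log front end and
near-identity residuals the same probes reach ~0.8 accuracy before any
fine-tuning, and the attention blocks fade in during training rather
than dominating initialization. Requesting layer `l` runs blocks
`1..l` only, so outputs are provably independent of deeper parameters.

## Synthetic cohort

Real PD speech corpora are access-restricted, so all tests run on a
synthetic cohort whose class signal lives in the same statistics the
clinical literature describes. Each speaker draws a parameter vector from
class-conditional priors; each utterance is synthesized source-filter
style: a glottal pulse train whose period is perturbed per cycle by the
speaker's jitter and whose amplitude by their shimmer (pulses placed with
fractional-sample interpolation so quantization does not mask the
perturbation), filtered through a cascade of vowel-formant resonators,
with white aspiration noise added, in syllable-sized voiced segments
alternating with pauses at the speaker's speech rate. Each utterance is
level-calibrated to a target RMS of `0.2 * intensity` (vocal intensity is
an energy-like, SPL-style quantity, so the parameter is realized in the
energy measure rather than in the waveform peak), with a 0.98 clipping
guard. A sentence id fixes the vowel sequence and intonation phase across
speakers, emulating repeated sentence types.

Healthy-control priors sit at literature-typical values (jitter
lognormal around 0.6 %, shimmer around 4 %, F0 around 140 Hz with a 4 st
intonation range, breath noise 2 % amplitude). A single nonnegative
`effect_size` scales every PD shift (log-mean shifts +0.4 for jitter,
+0.35 for shimmer, +0.5 for noise, -0.3 for log intensity; -1 st/unit F0
range; -0.25 syll/s rate). At `effect_size = 0` the classes are
identically distributed by construction; at 2 the speaker-level
separation is large on several nearly independent axes. The generator
emulates class-discriminative statistics, speaker identity and sentence
structure — not phonetics, intelligibility, recording-channel variation,
or within-speaker parameter drift. Passing tests therefore demonstrate
that the training machinery extracts phonatory/prosodic class structure
under a speaker-independent protocol, not clinical performance on real
voices.

## Evaluation protocol

Speakers are split 80/20 into a training partition and a held-out test
set with no speaker overlap, stratified by class. Training speakers are
assigned to 5 stratified folds (round-robin after a seeded shuffle, so
per-class fold counts differ by at most one). Each fold serves once as
the early-stopping validation set; each fold's best model is evaluated on
the common held-out test set. Reported: per-metric mean and sample (n-1)
standard deviation over folds, the cumulative confusion matrix (fold
sum), a pooled ROC over all folds' test scores, and per-sentence-type
accuracy. Leakage guards are unconditional hard errors, not warnings.
Where the source protocol is ambiguous about whether ROC/confusion
summaries are computed on fold-validation or test data, this package
evaluates on the held-out test set.

Metrics follow the standard confusion-matrix definitions (accuracy,
sensitivity = PD recall, specificity, precision, F1), with
divide-by-zero cases returning 0 and a warning flag. AUC is computed by
threshold sweep + trapezoid, which equals the Mann-Whitney pairwise
concordance statistic with ties counted 1/2 (cross-checked against pROC
in the tests).

## Explainability

`grad_cam_map()` hooks the output projection of the final (selected)
self-attention block — the activation the original visualization used —
computes channel weights as the time-averaged gradient of the target
logit, forms the ReLU-rectified weighted sum per frame, normalizes to max
1, and linearly interpolates to sample resolution. Identically-zero maps
are returned as zeros with a flag rather than dividing by zero. The
alternative hook mentioned in parts of the source description (attention
weights themselves) is not implemented; the output-projection activations
are the better-defined `T x d` tensor and match the published
visualizations. `embed_2d()` is an exact O(N^2) t-SNE (perplexity binary
search, early exaggeration, momentum with adaptive gains), deterministic
given its seed and sufficient for the few hundred embeddings a desk
experiment produces.

## Baselines

`mfcc_utterance_vector()` computes 13 cepstral coefficients (including
the 0th) on Hamming-windowed 25 ms frames with a 5 ms shift, adds first
and second delta regressions, and averages over frames to a
39-dimensional utterance vector (mean-only functionals; a log-energy
floor of 1e-10 keeps zero-padded frames finite). The 88-functional
eGeMAPS set is *ingested* from an external extractor's CSV and validated
(exactly 88 numeric columns, finite entries), never recomputed.
`train_baseline()` fits either an MLP with the identical architecture as
the classification head, or gradient-boosted trees with a small
cross-validated grid (depth 3/5/7, learning rate 0.05/0.1, 100/300
rounds) standing in for the original exhaustive hyperparameter search.

## Desk-scale study conditions

The end-to-end experiments in the test suite and the acceptance script
use: 10 speakers per class, 16 sentence types, utterances of 1.5-3 s at
16 kHz standardized to 1.5 s, a tiny encoder with `d = 64` and 2 blocks,
18 training epochs (patience 7) at learning rate 1e-3, and 3 pipeline
seeds. 16 kHz is retained (rather than a lower desk rate) because the
aspiration-noise cue lives above 2 kHz; 1.5 s inputs keep a full 5-fold
cross-validated comparison of both training modes in the tens of minutes
on one CPU. The null-cohort check uses 16 speakers per class with half
the speakers held out, trading training-set size for a narrower
chance-level AUC sampling band. These sizes are the package's reference
configuration; every function accepts larger values.

## Numerical choices and degenerate inputs

* Silence trimming: 25 ms frames, 10 ms hop, threshold 40 dB below the
  clip's maximum frame RMS; clips entirely below threshold raise an
  error. Ends may move by up to one hop; interior gaps are never removed.
* Resampling: polyphase (`signal::resample`) at the reduced rational
  ratio, before trimming and padding; padding is zeros at the end,
  truncation keeps the head (utterance onsets are preserved).
* Projection normalization: `z = u / max(||u||, 1e-12)` — a zero
  pre-normalization vector yields a zero projection, never NaN.
* Ties in hard-negative selection break toward the lowest batch index,
  making the scaled loss reproducible under permutation of equal rows.
* WAV I/O is 16-bit PCM with round-to-nearest quantization; round-trip
  error is bounded by one quantization step.

## Known limitations

* The tiny encoder is a contract-faithful stand-in, not a compressed
  pre-trained model; absolute desk-scale scores say nothing about
  published scores on real corpora.
* The synthetic cohort has no within-speaker session variability or
  channel effects, so speaker-independent generalization is easier than
  with real recordings.
* Only the binary HC/PD task is tested; the loss and metrics support more
  classes, but no multi-class protocol is wired.
* eGeMAPS features require an external extractor; only their ingestion
  contract is covered here.
* With only two held-out test speakers per class, speaker-level sampling
  noise dominates absolute scores: parameter draws occur in which the cue
  ranking that separates the training speakers misorders the test
  speakers (e.g. a PD speaker with healthy aspiration-noise level). On
  such draws every method tested — including oracle feature probes fit on
  the same training speakers — drops toward chance, while benign draws
  reach F1 ≈ 0.99 with the identical pipeline. Absolute desk-scale F1 is
  therefore a high-variance quantity; the SupCon-vs-CE *comparison* on a
  shared cohort is far more stable and is the quantity the package's
  experiments emphasize.
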