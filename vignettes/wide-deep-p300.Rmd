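---
title: "Wide-and-deep P300 detection: model, simulator and evaluation designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-and-deep P300 detection: model, simulator and evaluation designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A P300 matrix speller flashes the rows and columns of a 6 x 7 character grid
while the user attends one character. Flashes of the attended character's row
or column are rare, task-relevant events and elicit a P300 — a positive
event-related deflection over centro-parietal scalp roughly 300 ms after the
stimulus. Spelling reduces to a binary classification problem: does a given
stimulus-locked EEG epoch contain a target response?

Single-trial P300 detectors trained on one person often transfer poorly to
new people, because P300 amplitude and latency vary systematically across
individuals — notably with sex and age. `p300wd` implements a detector built
for that setting: a *wide-and-deep* hybrid in which a wide, sparse linear
branch memorizes participant-specific structure while a convolutional branch
learns response features shared across participants.

## The model

An epoch is a 30-channel x 90-sample matrix (900 ms at 100 Hz, baseline
included). Each participant also carries categorical attributes — an
identifier, sex, and an age bin — one-hot encoded into a vector
$d_2 \in \{0,1\}^T$ with one active bit per field (an *unknown* participant
id encodes as an all-zero id block; see below).

**Wide branch.** The wide input is
$x = [\,\mathrm{vec}(E),\ d_2,\ \varphi(d_2)\,]$, where $\mathrm{vec}(E)$
flattens the epoch channel-by-channel ($d_1 = 2700$ values) and
$\varphi(d_2)$ holds cross-product features
$\psi_k(d_2) = \prod_{i : c_{ki} = 1} d_{2i}$ — for 0/1 inputs, the AND of
the selected indicators. The default cross set is every pairwise combination
of levels from two distinct fields (id x sex, id x age, sex x age). The
branch contributes a linear logit $w^\top x$. With no sparse features this
branch has exactly $2700 + 1 = 2701$ trainable scalars.

**Deep branch.** The one-hot vector is embedded through a $T \times 90$
table into a single 90-sample row, stacked beneath the 30 EEG channels to a
$31 \times 90$ input. Three 1-D convolutions with $1 \times 7$ kernels run
along time, identically on each of the 31 rows (no cross-channel mixing
before the head), each followed by LeakyReLU (negative slope 0.01,
configurable):

| layer | filters | stride | pad | output width | parameters |
|-------|---------|--------|-----|--------------|------------|
| conv1 | 16 | 2 | 0 | 42 | 16·1·7+16 = 128 |
| conv2 | 32 | 2 | 0 | 18 | 32·1·7·16+32 = 3616 |
| conv3 | 16 | 1 | 1 (left) | 13 | 16·7·32+16 = 3600 |

The stride/padding geometry is *defined by* the feature-map widths
42/18/13: a stride-2 kernel-7 layer maps 18 to 6, not 13, so the third
layer uses stride 1 with a single left zero pad. The activations flatten to
$a \in \mathbb{R}^{31 \cdot 13 \cdot 16 = 6448}$ and a dense layer maps them
to a logit $w_{\mathrm{conv}}^\top a$.

**Combined prediction.** Both branches share one bias:
$$P(Y = 1 \mid x) = \sigma\!\left(w_{\mathrm{wide}}^\top [x, \varphi(x)] +
w_{\mathrm{conv}}^\top a + b\right),$$
and the package guarantees (and tests) that this equals composing the two
branch logits independently, bit for bit. During prediction the embedding
and cross products of a participant are computed once and reused across all
of that participant's epochs.

**Loss.** Mean logistic loss
$J = -\tfrac1m \sum_i [\,y_i \log p_i + (1-y_i)\log(1-p_i)\,]$, with
probabilities clipped to $[10^{-7}, 1-10^{-7}]$ because the loss is
undefined at exactly 0 or 1.

## FTRL-Proximal optimization

All trainable parameters — wide weights, embedding, kernels, dense head and
the shared bias — are updated per coordinate with FTRL-Proximal. Each
coordinate keeps an accumulator $z_i$ and a squared-gradient sum $q_i$; a
step with gradient $g_i$ performs

$$\sigma_i = \frac{\sqrt{q_i + g_i^2} - \sqrt{q_i}}{\alpha}, \quad
q_i \leftarrow q_i + g_i^2, \quad
z_i \leftarrow z_i + g_i - \sigma_i w_i,$$

$$w_i = \begin{cases} 0 & |z_i| \le \lambda_1 \\
-\dfrac{z_i - \lambda_1\,\mathrm{sgn}(z_i)}
       {\lambda_2 + (\beta + \sqrt{q_i})/\alpha} & \text{otherwise.}
\end{cases}$$

This closed form is the exact argmin of the follow-the-regularized-leader
objective
$G_{1:t} w + \tfrac12\sum_s \sigma_s \lVert w - w_s\rVert^2 +
\lambda_1 \lVert w\rVert_1 + \tfrac12 \lambda_2 \lVert w\rVert^2$
per coordinate; the test suite verifies the match against direct numeric
minimization on a thousand random instances. The L1 term zeroes coordinates
whose accumulator never escapes $\pm\lambda_1$, giving sparse wide weights;
$\lambda_2$ smooths the trajectory. The tie $|z_i| = \lambda_1$ truncates to
zero, the limit of the else branch.

Two design choices deserve a note:

* **Initial weights are folded into the accumulator.** A raw FTRL state with
  $z = 0$ discards any nonzero initialization after the first step, because
  $w$ is recomputed from $z$. We instead invert the closed form at $q = 0$,
  setting $z_0 = -(\lambda_2 + \beta/\alpha)\,w_0 - \lambda_1\,
  \mathrm{sgn}(w_0)$, so the optimizer's first step departs from the seeded
  fan-in-scaled deep initialization rather than from zero. Wide weights
  start at zero, the usual convention for the sparse branch.
* **One optimizer for the whole mixed model** is the default, with a
  configurable split (`deep_optimizer = "adagrad"`) that keeps FTRL on the
  wide branch and uses a conventional adaptive-gradient rule for the deep
  branch, as is customary for wide-and-deep models.

Gradients are computed by hand-written backpropagation through the conv
stack (verified against central finite differences in the test suite) and
fed to the optimizer in minibatches (default 32) over a configurable number
of passes. The defaults $\alpha = 0.1$, $\beta = 1$,
$\lambda_1 = \lambda_2 = 10^{-4}$, 3 passes were fixed by watching the
*training* loss plateau on the synthetic cohort (0.71 → 0.07 → 0.04 over
three passes on a 7-subject training set); they are exposed, not hard-coded.

## Preprocessing chain

`preprocess_recording()` applies, in order:

1. **Montage selection** — 30 standard 10-20 electrodes (FP1 … O2), rows
   reordered to the montage.
2. **Bandpass** — order-3 Butterworth, 0.1–30 Hz. Offline the filter runs
   forward–backward (zero phase; the effective magnitude order doubles);
   the online path uses the causal direction only. The 0.1 Hz edge has a
   multi-second settling transient, which is why filtering precedes
   epoching on the continuous signal.
3. **Epoching** — one epoch per flash marker over [−100, +800) ms, half-open
   at sample resolution with sample 0 at stimulus onset; 900 ms windows that
   would leave the recording are dropped with a message.
4. **Baseline correction** — per epoch and channel, subtracting the mean of
   [−100, 0) ms.
5. **Artifact rejection** — any epoch with a sample outside ±100 µV is
   removed. Rejection runs *after* baseline correction so constant offsets
   cannot trigger it; the kept set provably equals a brute-force per-sample
   scan.
6. **Decimation** — a linear-phase 151-tap FIR lowpass (cutoff
   0.45 x target rate, Hamming) applied centered with edge reflection,
   then every 10th sample: 900 samples at 1000 Hz become exactly the 90
   model inputs at 100 Hz. Within half a filter length of the epoch edges
   the reflection padding distorts the signal slightly; interior samples
   match ideal resampling to well under 1%.

The model consumes the full 900 ms epoch (baseline interval included) at
100 Hz — 90 samples — matching the detector's declared input shape; the
alternative of feeding only 0–800 ms would give 80 samples and contradict
that shape.

## The synthetic cohort

The study conditions are a speller session: 6 x 7 grid, 13 flashes per
sequence (one per row/column, uniformly permuted within each sequence — the
flash-order law is a simulator choice), 8 sequences per run (104 flashes,
16 of them targets), 5 runs per session, one session per subject by
default. Flash duration 100 ms and inter-flash interval 75 ms (175 ms
stimulus-onset asynchrony) are presentation parameters the source paradigm
leaves open; they are configurable defaults in the realistic range for
matrix spellers. Acquisition runs at 1000 Hz and is decimated to 100 Hz.

Each subject draws a profile from heterogeneity distributions tied to the
premise the wide branch exploits: amplitude depends on sex (7 µV for males,
9 µV for females at the best channel, SD 1 µV), latency on age group
(310/350/400 ms for young/mid/old, SD 15 ms), trial-to-trial latency jitter
15 ms, and background scale log-normal around 4 µV. The target response is
a Gaussian bump (SD 45 ms) scaled per channel by a fixed centro-parietal
topography; non-target flashes evoke nothing by default (configurable).
Background activity is 1/f noise (spectral power ∝ 1/f above a 0.5 Hz
floor) plus a 10 Hz alpha sinusoid at half the noise scale. At these
settings the matched-filter SNR of a single trial is high but the paradigm's
175 ms flash spacing makes consecutive 900 ms epochs overlap heavily, so
non-target epochs contain neighbouring targets' responses — the main
realistic difficulty the simulator retains.

What the simulator does **not** emulate: volume-conduction forward models,
ocular/muscle artifact physiology (artifacts are injected as labelled
low-frequency pulses when tests need them), non-stationarity across a
session, and any overlap *structure* beyond linear superposition.
Passing tests therefore demonstrate correctness of the pipeline and the
claimed cross-subject behaviour *under these conditions*, not performance
on recorded EEG.

## Evaluation designs

Three harnesses mirror the standard designs, all pure functions of
(dataset, classifier, seed), all speaking a factory contract
(`fit(epochs, labels, profiles)` / `predict_proba(...)`) that accepts any
classifier, so off-the-shelf baselines can be compared without changes:

1. **Within-subject** — per subject, stratified 5-fold cross-validation
   (each fold a ~20% test set preserving the 16:88 class ratio), mean over
   folds.
2. **Leave-one-subject-out** — train on 7 subjects, test on the held-out
   one. The held-out id is outside the one-hot vocabulary and encodes as an
   all-zero subject block while sex and age remain active, so the wide
   branch still applies its demographic memorization to unseen people —
   this is what makes cross-subject prediction work without retraining.
3. **Split-half** — 4 repeats of random 4-train / 4-test subject splits.

Accuracy uses a 0.5 decision threshold (with `p = 0.5` predicting the
positive class); no class rebalancing is applied, mirroring raw-accuracy
reporting. Character decoding sums per-flash probabilities over a run's 8
sequences per line and takes the best row and best column, ties toward the
lowest index. Online prediction scores the trailing 1 s buffer every 0.5 s
through the causal path.

## Numerical choices and degenerate inputs

* Sigmoid outputs are clipped to $[10^{-12}, 1-10^{-12}]$; the loss clips
  at $10^{-7}$.
* `ftrl_step()` rejects non-finite gradients, naming the first offending
  coordinate.
* Epoch windows are half-open; all sample indices are 0-based in marker
  storage and 1-based only inside R code.
* Amplitudes are microvolts everywhere; the EDF reader rescales mV/V
  channels on the way in. EDF roundtrips are exact to the 16-bit
  quantization step; the JSON container roundtrips bitwise.
* An empty marker table epochs to an empty set with a warning rather than
  an error; an epoch set with non-binary labels is rejected at construction
  and again at serialization.
* Problem sizes: the shipped evaluation uses 8 subjects x 1 session
  (520 epochs each, ~17,700 trainable parameters per leave-one-out fold),
  sizes at which a full leave-one-subject-out sweep completes in minutes on
  a single core.

## Known limitations

* The simulator's Gaussian-bump response and fixed topography are a
  deliberately minimal ERP model; effect sizes on real data will differ.
* The deep branch's embedding row hands the convolutional branch the same
  categorical participant information the wide branch memorizes, in
  additive form. On cohorts whose individual differences are fully
  explained by *additive* demographic effects — as in this package's
  default simulator, where amplitude depends on sex and latency on age
  group — the deep branch alone can match the combined detector under
  leave-one-subject-out evaluation. The wide branch's distinctive
  contribution (cross-product interactions, per-subject memorization)
  matters when individual structure includes demographic interactions or
  when previously seen participants return.
* Cross products are restricted to the sparse categorical features (the
  wide-model tradition); crossing dense EEG values with categorical
  features is not implemented.
* The dense head is a single binary logit; multi-class character-level
  softmax decoding is out of scope (characters are decoded by aggregating
  binary scores).
* Heavy class imbalance (16:88) means accuracy alone can mask a
  majority-class detector; the harness reports raw accuracy by design, and
  users comparing classifiers on other data may want to add AUC.
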