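---
title: "Methods: supervised biomedical WSD with recurrent and self-attention encoders"
author: "biowsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised biomedical WSD with recurrent and self-attention encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biowsd)
```

## The task

An ambiguous biomedical term (say *nursing*, or the acronym *CRF*) has a
small fixed inventory of senses. Given a paragraph containing exactly one
marked occurrence of the term, the task is to pick the correct sense.
Training data come as one file per ambiguous word with a few hundred
sense-annotated paragraphs; sense labels are opaque per-word symbols
`M1, M2, ...` shared across words, so the label itself carries no meaning
beyond "the i-th sense of this word".

`biowsd` implements a supervised neural approach end to end: paragraphs are
embedded with a frozen pre-trained word-embedding table, encoded by a
two-layer sequence encoder, summarized by max-pooling over time, and
classified by a small dense network. Two interchangeable encoders and four
ways of combining the two encoder layers are provided, together with
word-specific and universal (all-words) training regimes, voting ensembles
and a consensus-error report. Everything — forward passes,
backpropagation, the Adagrad optimizer — is implemented in the package
itself; there is no external deep-learning dependency.

## Model

### Input

Each instance is a token sequence $w_1,\dots,w_T$ with target position $t$.
Tokens are mapped through the embedding table to $X = (x_1,\dots,x_T)$,
$x_i \in \mathbb{R}^{d}$ (default $d = 200$). Out-of-vocabulary tokens map
to the zero vector *in place*, so $T$, the target index and positional
encodings are unaffected. The table is frozen throughout training. Input
can be the whole paragraph or a symmetric window of 25 tokens on each side
of the target (`input_mode = "window25"`), which shortens recurrent
training at a small cost in context.

Both encoders first scale $X$ by a single per-sequence scalar so its
root-mean-square entry is 1. Softmax attention is sensitive to the absolute
input scale relative to the additive positional code (entries of order 1),
and gradient magnitudes throughout either network track the input scale; the
normalization makes training dynamics invariant to the arbitrary overall
scale of whatever embedding table is supplied. For a table with entries of
order 1 this is nearly a no-op; the related convention in the Transformer
literature is multiplying embeddings by $\sqrt{d_{model}}$, which is the
same idea with a fixed rather than data-derived constant.

### Recurrent encoder

A cell of the LSTM computes, with $\sigma(x) = 1/(1+e^{-x})$:

$$
\begin{aligned}
i_t &= \sigma(W_{xi} x_t + W_{hi} h_{t-1} + b_i) \\
f_t &= \sigma(W_{xf} x_t + W_{hf} h_{t-1} + b_f) \\
c_t &= f_t \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c) \\
o_t &= \sigma(W_{xo} x_t + W_{ho} h_{t-1} + b_o) \\
h_t &= o_t \odot \tanh(c_t)
\end{aligned}
$$

The forget gate is what protects the cell state across long spans: in the
$f \equiv 1$, $i \equiv 0$ limit, $c_t$ is conserved exactly (a unit test
checks this limit). A bidirectional layer runs two independent LSTMs over
the sequence and its reversal and concatenates per-step outputs, so each
position sees both sides of the target. The encoder stacks two such layers
($Y$ from layer 1, $Z$ from layer 2, both $T \times D$ with $D = 2H$);
inverted-scaling dropout (default rate 0.5) is applied to $Y$ before layer
2, during training only. Hidden size defaults to $H = 100$ per direction so
that $D = 200$ matches the attention encoder's width; the architecture
leaves $H$ free, and tests use $H = 16$.

### Self-attention encoder

The alternative encoder is a stack of two identical Transformer-style
encoder layers of width $d_{model} = d$. Each layer applies, with post-norm
residuals $\mathrm{LayerNorm}(X + \mathrm{Sublayer}(X))$
($\varepsilon = 10^{-6}$, learned gain/bias):

1. **Multi-head scaled dot-product self-attention.**
   $\mathrm{Attention}(Q,K,V) = \mathrm{Softmax}(QK^\top/\sqrt{d_k})V$ with
   $Q = XW^Q_i$, $K = XW^K_i$, $V = XW^V_i$ per head $i$, and
   $d_q = d_k = d_v = d_{model}/h$; the $h$ head outputs are concatenated
   and projected by $W^O$ back to $d_{model}$, so the residual is
   well-shaped. Dividing scores by $\sqrt{d_k}$ keeps their magnitude
   stable as $d_k$ grows, away from the softmax's small-gradient region.
2. **Position-wise feed-forward network.**
   $\mathrm{FFN}(z_t) = \max(0, z_t W_1 + b_1) W_2 + b_2$ applied
   identically at every position; $W_1, W_2$ are
   $d_{model} \times d_{model}$ exactly (not the widened inner dimension
   used elsewhere in the Transformer literature), the ReLU being the only
   activation in the stack.

Since attention is order-agnostic, the sinusoidal positional encoding
$pe_{t,2i} = \sin(t/10000^{2i/d_{model}})$,
$pe_{t,2i+1} = \cos(t/10000^{2i/d_{model}})$ (positions 0-based) is added
to the (normalized) input once, before layer 1. For any offset $k$,
$pe_{t+k}$ is a fixed rotation of $pe_t$, which is what lets the model
attend by relative position; a test verifies the rotation identity to
$10^{-9}$ and that the encoder is permutation-equivariant exactly when the
positional encoding is disabled. The layer-1 and layer-2 outputs play the
same roles $Y$ and $Z$ as the two BiLSTM layers. No dropout is used inside
this encoder.

### The upper layer

Four structures combine $Y$ and $Z$ into a single matrix $H$:

| structure | $H$ | shape |
|---|---|---|
| `direct` | $Z$ | $T \times D$ |
| `weighted_sum` | $\lambda Y + (1-\lambda) Z$ | $T \times D$ |
| `concat_time` | rows of $Y$ then rows of $Z$ | $2T \times D$ |
| `concat_vector` | $[Y, Z]$ per row | $T \times 2D$ |

$\lambda$ is trainable and kept in $(0,1)$ by storing an unconstrained
scalar passed through the logistic function, initialized at $0.5$.
Max-pooling over time takes the per-dimension maximum across (valid) rows
of $H$, giving $h \in \mathbb{R}^{D}$ (or $\mathbb{R}^{2D}$ for
`concat_vector`). A useful identity, tested: pooling `concat_time` equals
the elementwise max of pooling $Y$ and pooling $Z$ — time concatenation
preserves both layers for the pooling to choose from, which is the intuition
for why it tends to work best.

Optionally the **hint layer** concatenates the target word's own
pre-trained embedding: $\xi = [h, x_k]$. Inside the model the hint vector
is RMS-normalized like the encoder inputs so that its magnitude is
commensurate with $h$; without this, a small-scale embedding table renders
the hint numerically invisible. The (possibly augmented) vector passes
through dense layers of 256 and 64 ReLU units and a softmax over the $K$
sense labels. The hint matters in the universal regime, where one model
serves all words: it re-emphasizes *which* word is being disambiguated.
For word-specific models it is redundant and slightly harmful, so the
default is hint ON for universal and OFF for word-specific training.

## Training

* **Loss**: cross-entropy on the softmax output.
* **Optimizer**: Adagrad — per-parameter accumulated squared gradients
  divide each step. Accumulators start at $0.1$, which damps the first few
  updates (a zero accumulator takes a full-learning-rate step in every
  coordinate on step one, regardless of gradient size).
* **Learning rate**: staircase exponential decay,
  $\mathrm{lr}(s) = 0.05 \times 0.96^{\lfloor s/2500 \rfloor}$ where $s$
  counts optimizer steps (one step = one minibatch).
* **Early stopping**: after each epoch the validation loss is computed; a
  checkpoint is stored at every new minimum, and training stops once the
  loss has failed to improve for 5 consecutive epochs, restoring the best
  checkpoint. The stopping metric is validation *loss* for both the
  checkpoint and the patience counter (the self-consistent reading of
  monitoring "the lowest validation loss"). With no validation set,
  training runs a fixed 50 epochs with no checkpointing.
* **Splits**: per-word 70/10/20 train/valid/test by default, or 90/–/10 for
  the fixed-epoch regime. Splitting is stratified by label (with ~200
  paragraphs per word, an unstratified 10% validation set is unstable);
  overall part sizes are exactly $\lfloor f N \rfloor$ with the remainder
  in train.
* **Batch sizes**: 16 (word-specific) and 32 (universal) by default.
* **Regimes**: `train_word_specific()` fits one independent model per word
  and reports per-word and macro-average accuracy;
  `train_universal()` merges all words (labels are shared and not
  remapped) and fits a single model with $K$ = the largest sense count.
* **Determinism**: one seed controls initialization, shuffling and dropout;
  reports are bitwise reproducible for a fixed seed, and no function
  disturbs the caller's RNG state.
* **Initialization**: uniform $\pm 1/\sqrt{\mathrm{fan~in}}$ weights
  (per-direction $\pm 1/\sqrt H$ in the LSTM), zero initial LSTM states,
  layer-norm gain 1 / bias 0. The two ReLU dense layers start with bias
  $0.1$ so no unit begins dead — with zero biases and small inputs an
  entire layer can start exactly at the ReLU kink, which is both
  untrainable and non-differentiable.

Ensembles combine the four structures' predictions by majority vote or by
weighted vote (weights from validation performance); ties go to the label
of the highest-ranked model that voted for a tied label. The
consensus-error report lists test instances on which *every* model agrees
on the same wrong label — an estimate of the irreducible (possibly
mislabeled) fraction of a dataset, hence of its accuracy ceiling.

## Synthetic corpora

`generate_corpus()` produces self-contained fixture corpora shaped like the
benchmark collections this method targets: one dataset per ambiguous word,
$n$ paragraphs each, the target embedded exactly once at a uniform random
position, labels balanced within ±1. Context tokens come from a two-pool
mixture: with probability `separability` from the (word, sense)-specific
cue pool, otherwise from a shared noise pool. This makes difficulty a
single dial with a known oracle: at `separability = 1` a unigram
naive-Bayes rule on cue counts approaches perfect accuracy as paragraphs
grow, and at 0 the context is independent of the label. Embedding vectors
are i.i.d. uniform in $[-0.5/d, 0.5/d]$ (the word2vec initialization
convention), written/read in word2vec text format with 17 significant
digits so round trips are bitwise exact.

`cue_sharing` arranges words into pairs that *share* cue pools with a
swapped sense-to-label mapping. For such pairs the context distribution
alone cannot determine the label — the target word's identity is required.
This is precisely the situation the universal hint layer addresses, so the
hint-direction test uses a fully shared-cue corpus: a context-only model is
capped near 50%, while a model that exploits the target word can solve the
task. `generate_mislabeled_variant()` flips an exact fraction of labels
(recording which), used to verify that consensus errors recover planted
label noise.

What the generator does *not* emulate: grammar, topical coherence, Zipfian
token frequencies, correlated senses across words, and realistic trained
embedding geometry (vectors are random, so all semantic signal flows
through token identity, not embedding similarity). Passing tests therefore
demonstrate that the architecture, optimization and bookkeeping are
correct and that the models can extract a planted contextual signal — not
that the printed accuracies of any published benchmark are reproduced;
that requires the external corpus and pre-trained embeddings.

## Problem sizes used by the tests and acceptance script

Chosen so the full pipeline exercises every path at desk scale: the
sense-recovery check trains both encoders with all four structures
($H = d_{model} = 16$, $h = 2$, dense 256/64) on one word with 200
paragraphs of 20–40 tokens at separability 0.9, 70/10/20 split, at most 50
epochs with early stopping, and requires ≥ 0.95 test accuracy from all 8
configurations. The universal hint check uses 10 words (5 shared-cue
pairs, separability 0.85, 80 paragraphs of 15–25 tokens), 3 seeds, 25
fixed epochs, comparing mean test accuracy with and without the hint. The
acceptance script runs reduced versions of the same computations plus the
word-specific macro average, voting ensembles and the consensus report.

## Numerical notes and limitations

* Max-pooling backpropagates to the arg-max row per dimension (first row on
  exact ties).
* Softmax rows are computed with max-subtraction; masked attention keys
  receive $-\infty$ scores pre-softmax and exactly zero weight after; a
  query row with no valid keys is an error, as is pooling over zero valid
  rows.
* Gradient correctness for every encoder × structure × hint combination is
  verified against central finite differences (coordinates at ReLU kinks or
  pooling ties, where the derivative does not exist, are excluded by a
  two-step-size consistency check).
* Training is CPU-bound pure R; it is intended for the corpus sizes above
  (hundreds of paragraphs per word), not for training on millions of
  tokens. The windowed input mode exists precisely to bound recurrent cost.
* The package reads one TSV dialect (documented in `read_sense_file()`) and
  word2vec *text* tables; the native serialization of any particular public
  WSD distribution, binary embedding formats and subword vocabularies are
  out of scope.
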