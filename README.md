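# biowsd

Supervised word sense disambiguation (WSD) for ambiguous biomedical terms.
Given paragraphs in which one occurrence of an ambiguous word (*nursing*,
*CRF*, *cold*, ...) is marked, `biowsd` learns to pick the correct sense
from the word's inventory `M1, M2, ...` using the surrounding context. It is
aimed at biomedical text-mining pipelines (NER/concept normalization) that
need a trainable, dependency-free disambiguation component, and at anyone
studying how recurrent and self-attention encoders compare on this task.

The model family, implemented entirely in the package (forward passes,
backpropagation and the Adagrad optimizer included — no deep-learning
framework underneath):

* a frozen pre-trained embedding table maps tokens to
  `x_1, ..., x_T ∈ R^d` (word2vec text format; OOV tokens become zero
  vectors in place);
* a two-layer **context encoder**, either
  * a bidirectional LSTM (`h_t = o_t ⊙ tanh(c_t)` with the usual
    input/forget/output gates; per-direction hidden size `H`, layer width
    `D = 2H`, dropout between layers), or
  * a Transformer-style self-attention encoder
    (`Attention(Q,K,V) = Softmax(QKᵀ/√d_k)V`, `h` heads with
    `d_k = d_v = d_model/h`, position-wise FFN, post-norm residuals,
    sinusoidal positional encoding);
* an **upper layer** that combines the two encoder outputs `Y` and `Z` by
  one of four structures — `Z` itself, `λY + (1−λ)Z`, stacking along time
  (`2T × D`), or concatenating per position (`T × 2D`) — then max-pools
  over time into a context vector `h`;
* optionally the **hint layer** `ξ = [h, x_k]`, appending the target
  word's own embedding (essential for the *universal* one-model-for-all-words
  regime);
* a dense `256 → 64 → K` softmax classifier.

Training follows a fixed recipe: Adagrad, learning rate
`0.05 · 0.96^⌊step/2500⌋`, checkpoint at each new minimum of the validation
loss, stop after 5 epochs without improvement and restore the best
checkpoint (or a fixed 50 epochs when no validation set exists). Voting
ensembles over the four structures and a consensus-error report (instances
every model gets identically wrong — an estimate of a dataset's label-noise
ceiling) are included. A synthetic-corpus generator with a controllable
sense-separability dial makes the whole pipeline testable offline; see the
methods vignette (`vignettes/biowsd-methods.Rmd`) for the model, the
generator and every numerical choice.

## Worked example

```r
library(biowsd)

# a synthetic ambiguous word: 120 paragraphs, 2 senses, 90% of context
# tokens drawn from sense-specific cue pools
spec <- synth_spec(n_words = 1, senses_per_word = 2, n_paragraphs = 120,
                   paragraph_len_range = c(15L, 30L), vocab_size = 500,
                   dim = 16, separability = 0.9, seed = 42)
corpus <- generate_corpus(spec)
parts <- split_dataset(corpus$datasets[[1]], c(0.7, 0.1, 0.2), seed = 42)

cfg <- train_config(encoder = "bilstm", hidden_size = 16L,
                    structure = "concat_time", max_epochs = 30L, seed = 42L)
fit <- train_model(parts$train, parts$valid, corpus$table, cfg)
ev <- evaluate_wsd(fit$model, parts$test, corpus$table, cfg)

cat("epochs run: ", fit$report$epochs_run,
    "  best epoch: ", fit$report$best_epoch, "\n", sep = "")
cat("test accuracy: ", ev$accuracy, "\n", sep = "")
head(ev$predictions[, c("doc_id", "gold", "pred", "prob_M1", "prob_M2")], 3)
```

```
epochs run: 30  best epoch: 30
test accuracy: 1
         doc_id gold pred   prob_M1     prob_M2
1 term001_p0001   M1   M1 0.9977670 0.002232982
2 term001_p0007   M1   M1 0.9711168 0.028883246
3 term001_p0010   M1   M1 0.9954709 0.004529060
```

The validation loss kept improving through epoch 30, so no early stop was
triggered; the 24 held-out paragraphs are all classified correctly, with
confident posteriors — at separability 0.9 the planted cue structure makes
the task nearly noiseless, so this is the expected outcome (a naive-Bayes
reference on the same split also approaches 1.0).

A command-line wrapper covering `synthesize`, `train`, `evaluate`,
`ensemble` and `report` is installed at `inst/cli/biowsd`:

```sh
Rscript inst/cli/biowsd synthesize --out corpus/ --seed 7 --n-words 3
Rscript inst/cli/biowsd train --data corpus/ --embeddings corpus/embeddings.txt \
        --out run/ --mode word --encoder bilstm --structure concat_time
```

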