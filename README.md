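# medtext

Hybrid convolutional–recurrent classifiers for medical and biomedical text,
implemented from first principles in R.

## The problem and who this is for

Document-level classification of medical text — biomedical abstracts labeled
with cancer-hallmark categories, clinical notes labeled by condition — is a
standard task in biomedical NLP, but most reference implementations live in
Python deep-learning frameworks. `medtext` provides a fully inspectable R
implementation of two hybrid architectures for this task, aimed at
researchers who want layer-level math they can verify (every forward
operation is a pure function checked against brute-force oracles in the test
suite) plus the surrounding pipeline: corpus I/O, deterministic splitting,
word- and character-level tokenization, skip-gram embeddings, seeded
training, metrics, and hyperparameter sweeps.

## The two architectures

**Quad-channel hybrid LSTM (`build_qc_lstm`)** runs four parallel channels —
{word, character} embeddings × {convolution branch, LSTM branch}:

- per level, `channel(x) = conv(x) ⊕ LSTM(x)` in parallel, not in series;
- the convolution branch applies filters of widths {1, 3, 5} (valid, stride
  1): `tᵢ = f(w · x_{i:i+h−1} + b)`, reduced by global max pooling;
- the LSTM branch uses the standard gated recurrence
  `z_t = tanh(W_z[h_{t−1}, x_t] + b_z)`, sigmoid input/forget/output gates,
  `c_t = f_t ⊙ c_{t−1} + i_t ⊙ z_t`, `h_t = o_t ⊙ tanh(c_t)`, followed by
  hybrid (additive) attention over the concatenated states
  `h_i = [h_t ; c_t]`: scores `e_i = v_aᵀ tanh(W_r h_i + b)`,
  softmax-normalized into a weighted context vector;
- the merged channel outputs pass through dropout and a dense softmax layer.

**Hybrid BiGRU with multihead self-attention (`build_bigru_mha`)** runs two
parallel branches over the word-embedded sequence:

- a CNN branch (same text convolution) pooled by global max **and** average,
  concatenated;
- a stack of bidirectional GRUs
  (`z_t = σ(W_z[h,x])`, `r_t = σ(W_r[h,x])`,
  `h̃_t = tanh(W[r ⊙ h, x])`, `h_t = (1−z)h_{t−1} + z h̃_t`), whose output
  sequence feeds multihead scaled-dot-product self-attention
  `Attention(Q,K,V) = softmax(QKᵀ/√d)V` with `Q = K = V`, per-head
  projections and an output projection, pooled max+avg;
- branch features concatenated → dropout → dense softmax.

Training minimizes cross entropy (binary form for 2 classes, categorical
beyond) with hand-derived backpropagation through every layer and a choice
of Adam, Nadam, SGD or AdaGrad. Metrics are accuracy, precision, recall and
F1 (`F1 = 2PR/(P+R)`), one-vs-rest with macro averaging for multiclass.

Because the package depends on no deep-learning framework, every gradient
is hand-written and verified by finite-difference checks in the tests.

## Worked example

Generate a separable synthetic corpus, split it, train skip-gram embeddings
and the quad-channel model, and evaluate:

```r
library(medtext)

corp <- generate_corpus(synth_spec(n_docs = 600, doc_len = c(20, 40), seed = 42))
corpus_stats(corp)
#> # A tibble: 1 × 6
#>   n_docs n_classes max_length mean_length vocab_size class_counts
#>    <int>     <int>      <int>       <dbl>      <int> <list>
#> 1    600         2         40        29.8       8126 <int [2]>

spl <- split_corpus(corp, seed = 42)             # 420 / 120 / 60 (floor rule)
wv <- build_vocab(spl$train, "word", min_count = 2)
cv <- build_vocab(spl$train, "char")
enc <- function(x) encode_corpus(x, wv, 64, cv, 64)

emb  <- train_skipgram(spl$train, "word", vocab = wv, d = 16, epochs = 2, seed = 42)
cemb <- random_embedding(cv, 16, seed = 43)

model <- build_qc_lstm(emb, cemb, n_classes = 2, n_w = 64, n_c = 64,
                       widths = c(1, 3, 5), n_filters = 16, hidden = 16,
                       dropout = 0.5, seed = 42)
model
#> <qc_lstm> 2 classes, 19,090 trainable parameters (untrained)

fit <- train_model(model, enc(spl$train), enc(spl$val),
                   train_config(batch_size = 32, lr = 0.01, epochs = 10, seed = 42))
tidy(fit)
#> # A tibble: 2 × 3
#>   epoch train_loss val_accuracy
#>   <int>      <dbl>        <dbl>
#> 1     1     0.299         0.967
#> 2     2     0.0477        1

evaluate_model(fit, enc(spl$test))
#> # A tibble: 1 × 5
#>   accuracy precision recall    f1 average
#>      <dbl>     <dbl>  <dbl> <dbl> <chr>
#> 1      100       100    100   100 binary
```

The training loss falls from 0.299 to 0.048 in two epochs, validation
accuracy reaches 1, and the held-out test metrics are 100% — expected on a
noiseless corpus whose classes are separable by injected keywords.
`grid_sweep()` repeats such runs over a hyperparameter axis
(kernel widths, learning rate, dropout, optimizer, activation, BiGRU depth)
and returns a tidy table with the best row marked; `autoplot()` plots
histories and sweeps. A command-line wrapper for the corpus tools and
training loops ships in `inst/cli/medtext.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","medtext.R",package="medtext"))') synth --spec spec.yaml --out corpus.tsv`).

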