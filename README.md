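# medmatch

Answer selection for Chinese medical community question answering, cast as
semantic text matching. On consultancy sites a patient posts a question and
adopts one of several replies; given a question and a ranking list of five
candidate answers (one adopted, four distractors), the task is to rank the
adopted answer first. `medmatch` implements the full pipeline at desk
scale: corpus construction in the 5-field tab-separated dialect,
character/word preprocessing, a clustered convolutional representation, two
deep matching networks trained from scratch in R, classical baselines, and
ranking evaluation — plus a seeded synthetic corpus generator so everything
is testable without any download.

## What is inside

**Corpus tooling** — read/write the `id<TAB>label<TAB>category<TAB>question
<TAB>answer` dialect; clean raw text to digits, Latin letters, CJK
ideographs and punctuation; keep only questions with exactly one adopted
answer of at most 500 characters; sample 4 negatives per question
(supplementing from other questions when a thread is short); split 8:1:1
stratified by category.

**CSCR** (Convolutional Semantic Clustered Representation) — same-length
convolutions of several filter heights over token embeddings,
`c_i = f(w · x_{i:i+h−1} + b)`, followed by overlapped windowed max pooling
(window `m = 3`, stride `d = 2`), producing a block-level matrix
`z ∈ R^{⌈n/d⌉ × F}` whose rows act as latent word/clinical-term
representations. Useful when Chinese word segmentation is unreliable on
clinical terms.

**Matching networks** —

* *MV-LSTM*: siamese bidirectional LSTM positional representations
  `p_t = [h→_t, h←_t]`, bilinear interaction `S_ij = Q_i B A_jᵀ + b`,
  matrix-wide k-max pooling, two-layer MLP to class scores `(s0, s1)`.
* *MatchPyramid*: dot-product matching matrix `S_ij = Q_i · A_j` treated as
  a gray image, stacked 3×3 ReLU convolutions, dynamic max pooling to a
  fixed 3×10 grid, fully connected head.

Both train with softmax cross-entropy over `(s0, s1)` (`p_k =
e^{s_k}/(e^{s0}+e^{s1})`), Adam, and dropout; all gradients are derived by
hand and verified against numerical differentiation in the test suite.
Either network can run over raw embeddings or CSCR blocks.

**Baselines** — Okapi BM25 (`k1 = 1.2`, `b = 0.75`), a siamese multi-scale
CNN with cosine scoring and pairwise hinge loss (margin 0.01), and a seeded
random ranker.

**Evaluation** — P@1 and MAP over single-positive ranking lists
(`MAP = mean 1/rank(positive)`), with a pessimistic tie policy so ties
never flatter the model. A uniform random ranker scores P@1 = 20.0% and
MAP = 45.7%, which the tests verify by Monte Carlo against the closed
forms.

## Worked example

```r
library(medmatch)

# 1. seeded synthetic ranking corpus: 120 questions, 5 topics,
#    90% topical overlap between question and adopted answer
cfg <- synth_config(n_questions = 120L, question_len = c(6L, 12L),
                    answer_len = c(10L, 20L), overlap = 0.9, noise = 0.1,
                    seed = 7L)
lists <- generate_corpus(cfg)
parts <- split_corpus(lists, seed = 7L)          # 100 train / 10 dev / 10 test

# 2. character-level encoding (vocabulary fitted on train only)
prep <- prepare_data(parts$train, parts$dev, unit = "char",
                     length_q = 12L, length_a = 20L)
prep$vocab
#> <vocabulary> 302 entries (incl. PAD/OOV), min_count = 2

# 3. BM25 baseline on the dev lists
bm <- vapply(parts$dev, function(l) {
  s <- bm25_rank(tokenize_chars(l$question),
                 lapply(l$candidates$answer, tokenize_chars))
  rank_candidates(s, l$candidates$label)$positive_rank
}, integer(1))
c(p_at_1 = p_at_1(bm), map = mean_ap(bm))
#> p_at_1    map
#>   0.70   0.79

# 4. train MatchPyramid
mp <- matchpyramid_model(prep$vocab$size, embed_dim = 32L, kernels = 16L,
                         n_layers = 2L, mlp_hidden = 32L, seed = 1L)
fit <- train_model(mp, prep$train, prep$dev,
                   train_config(epochs = 6L, batch_size = 16L, seed = 2L,
                                verbose = TRUE))
#> epoch 1  loss 0.5716  dev P@1 0.200  dev MAP 0.452
#> epoch 2  loss 0.5064  dev P@1 0.200  dev MAP 0.493
#> epoch 3  loss 0.4916  dev P@1 0.400  dev MAP 0.610
#> epoch 4  loss 0.4683  dev P@1 0.600  dev MAP 0.740
#> epoch 5  loss 0.3671  dev P@1 0.900  dev MAP 0.950
#> epoch 6  loss 0.1836  dev P@1 0.900  dev MAP 0.950

# 5. evaluate the checkpoint selected on dev MAP (epoch 5)
format_metrics(evaluate_model(fit$model, prep$dev))
#> p_at_1    map
#> "90.0" "95.0"
```

The trained matching network reads 90% of dev lists correctly at rank 1,
beating the purely lexical BM25 baseline (70%): the network's embeddings
cluster topic tokens, so it credits topical matches that BM25 misses
because the exact characters differ. A CSCR front end is enabled by passing
e.g. `cscr = cscr_config(heights = c(2, 3, 4), filters = 64)` to either
model constructor.

A thin command-line wrapper is installed under `inst/cli/medmatch`
(`medmatch synth | corpus | train | eval`), built on `medmatch_main()`.

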