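---
title: "Matching models for medical answer selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching models for medical answer selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmatch)
```

## The task

Community medical QA sites let patients post a question and collect replies
until the asker adopts one answer. Answer selection casts this as ranking:
for each question we form a list of five candidate answers — the adopted
one (label 1) and four distractors (label 0) — and a model must rank the
adopted answer first. Quality is measured by Precision at 1 (the fraction
of lists whose top-ranked candidate is the adopted answer) and Mean Average
Precision, which with a single positive per list reduces to the mean
reciprocal rank of that positive. A uniform random ranker over 5 candidates
therefore scores P@1 = 1/5 = 20.0% and MAP = (1/5)(1 + 1/2 + 1/3 + 1/4 +
1/5) = 45.7%, which `medmatch` uses as a calibration point.

Chinese text adds a specific difficulty: word segmentation (CWS) tools are
error-prone on clinical terms, so the toolkit supports both character-level
input (no segmenter needed) and word-level input over pre-segmented text,
and provides a representation module (CSCR, below) that clusters characters
or segments into latent term-level blocks instead of trusting a segmenter.

## Corpus dialect and construction

Corpora use a 5-field tab-separated line format: question id, binary
adoption label, clinical category, question text, answer text. The
construction pipeline mirrors how such corpora are built from raw
consultancy dumps:

* `clean_text()` strips HTML tags and URLs, then keeps only digits, Latin
  letters, CJK ideographs and punctuation; whitespace runs collapse to one
  space. The character classes are named, not enumerated code points, so we
  use Unicode properties (`\p{Han}`, `\p{P}` plus the CJK fullwidth blocks).
  The function is idempotent.
* `filter_questions()` keeps only questions with exactly one adopted answer
  of at most 500 characters (inclusive boundary; lengths are Unicode
  characters, not bytes).
* `sample_negatives()` gives each question 4 distractors: native same-thread
  negatives first, topped up uniformly (seeded, without replacement) from
  other questions' answers. Only the current question's own answers are
  excluded from supplementation; a supplemented negative may coincide with
  another list's positive, which is accepted because the alternative —
  global exclusion — couples lists together.
* `split_corpus()` splits 8:1:1 stratified by category. Because no rounding
  rule is implied by the ratios alone, dev and test each get
  `floor(n/10)` per category with the remainder to train: deterministic and
  train-favoring. Categories with fewer than 3 questions go wholly to train.
* Tabs and newlines inside text are replaced by one space at write time;
  the dialect reserves them as structure and defines no escaping scheme.

## Preprocessing

Tokens are single code points (`tokenize_chars()`) or pre-segmented words
(`tokenize_words()`, splitting on whitespace and `/`). `build_vocab()`
drops tokens seen fewer than `min_count = 2` times; indices are dense with
PAD = 0 and OOV = 1, ordered by descending frequency with first-occurrence
tie-break so the vocabulary is reproducible regardless of stream order.
Unseen tokens at evaluation time map to OOV rather than being dropped —
dropping would silently shorten test sequences. `encode()` truncates to the
configured length keeping the head (the opening of a consultancy question
carries the complaint) and right-pads with PAD. Reference sequence lengths
are 50/100 (question/answer) for word-level input and 200/400 for
character-level input; desk-scale runs in this package use 12/20 on
generated corpora roughly one tenth that long. Embeddings are randomly
initialized uniform on [-0.1, 0.1] (dimension 200 at full scale; 32 at desk
scale) with the PAD row fixed at zero; no pre-trained embeddings are used.

## CSCR: convolutional semantic clustered representation

CSCR turns a length-`n` sequence of `k`-dimensional token embeddings into a
block-level matrix `z`:

1. For every filter `w` of height `h`, a same-length convolution
   `c_i = f(w . x_{i:i+h-1} + b)` over all windows, zero-padded so the
   feature map keeps length `n` (`floor((h-1)/2)` zeros on the left, the
   remainder on the right). The default activation is ReLU; tanh is
   available.
2. Windowed max pooling with window `m = 3` and stride `d = 2`: block `j`
   takes `max(c[1+(j-1)d : (j-1)d+m])`. With these defaults adjacent
   windows overlap by exactly one position, letting neighbouring characters
   compete so the strongest local composition — a latent word or clinical
   term — wins the block.
3. The pooled maps of all filters become the columns of `z`
   (`ceiling(n/d)` rows; filters are concatenated height-major, an order
   with no observable effect past the following dense layers).

Two boundary conventions make this total on arbitrary inputs: sequences are
right-padded with PAD (zero) embeddings to a multiple of `d` before
convolution, and the final pooling window, which would otherwise overrun
the map, is clipped — equivalently end-padded with values that never win a
maximum. Both are exercised directly by the brute-force oracle tests.

Configured heights are `[1,2,3]` (64 filters each) in front of MV-LSTM and
`[2,3,4]` in front of MatchPyramid.

## MV-LSTM

A siamese bidirectional LSTM (shared weights for question and answer, 100
hidden units per direction at reference scale) produces positional
representations `p_t = [h_fwd_t, h_bwd_t]`. Every question/answer position
pair is scored by a bilinear form `S_ij = Q_i B A_j' + b`; k-max pooling
(`k = 50` at reference scale) over the flattened matrix keeps the strongest
interactions in descending order; a two-layer MLP with tanh hidden layer
maps them to two class scores `(s0, s1)`. When CSCR is enabled the bi-LSTM
runs over the CSCR block rows rather than being replaced by them — the
design reading under which CSCR stays a drop-in representation for both
matchers. The LSTM uses standard gates with forget-gate bias initialized to
1; non-embedding weights use Glorot-uniform initialization. No tensor layer
is used.

k-max pooling is matrix-wide, not per-row, and is therefore invariant to
permutations of the interaction matrix; dropout (rate 0.5) is applied to
the pooled vector during training only.

## MatchPyramid

The matching matrix `S_ij = Q_i . A_j` of embedding (or CSCR-row) dot
products is treated as a gray image. A stack of square-kernel ReLU
convolutions (3x3, 64 kernels at reference scale; depth configurable 1-3,
default 2 since "hierarchical" implies at least two levels) extracts
matching patterns; dynamic max pooling maps the variable-sized result onto
a fixed 3x10 grid; a fully connected head with one tanh hidden layer
produces `(s0, s1)`. Dynamic pooling partitions rows and columns into even
integer cells with the remainder given to the leading cells. Matrices
smaller than the grid — possible at desk scale once CSCR halves the row
count — are padded with sentinel values that never win a maximum (a cell
consisting only of padding yields 0 and no gradient). Whether the head has
one or two layers is a genuinely open choice; one hidden layer is the
default and the head width is configurable.

## Training

Candidates train as independent binary examples under softmax
cross-entropy over `(s0, s1)`: the standard mean binary cross-entropy,
computed in log-sum-exp form for numerical safety. Optimization is Adam at learning rate 0.001 with dropout 0.5.
Gradients for every layer (LSTM backprop through time, im2col convolutions,
max-pooling argmax routing, bilinear form, embedding scatter) are derived
by hand and verified against central differences to 1e-4 relative in the
test suite. After each epoch the dev set is scored and the checkpoint with
the best dev MAP (the selection metric; P@1 is available) is returned.
The default batch size is 64; the desk-scale experiments below use 16,
which gives the small corpus enough optimizer steps per epoch.

The multi-CNN baseline (siamese convolutions of heights 3 and 4, 80 kernels
each, max-over-time pooling, cosine score) trains with a pairwise hinge
loss of margin 0.01, one sampled distractor per question per epoch.

BM25 uses the Okapi form with `k1 = 1.2`, `b = 0.75` and
`idf = log(1 + (N - df + 0.5)/(df + 0.5))`, computed over the candidate
answers of each list; repeated query terms count once.

## Evaluation

`rank_candidates()` sorts by descending score with a pessimistic tie
policy: the positive ranks below any negative it ties with, so tied scores
never overstate model quality (a stable policy is available for debugging).
`p_at_1()` and `mean_ap()` consume the resulting positive ranks; P@1 is
never larger than MAP, and both depend only on ranking order. Reports print
percentages to one decimal.

## The synthetic corpus generator

`generate_corpus()` emulates the structure of the real task without any
download: each question gets a topical category with its own CJK-range
token block plus a shared topic-neutral pool. The `overlap` parameter sets
the fraction of question and adopted-answer tokens drawn from the topic
block; `noise` sets the fraction of the question's topic tokens leaked into
distractors, which otherwise draw from their own (different) topic at the
same topical rate. At `overlap = 0, noise = 0` positives and negatives are
construction-identical (pure shared pool), so no ranker can beat chance; at
high overlap the task is solvable both lexically (BM25) and semantically.
Default lengths mimic the real length profile (questions about 87 tokens,
answers about 147); desk-scale runs use ranges of 6-12 and 10-20 tokens,
about one tenth.

What the generator does *not* emulate: real Chinese morphology and
segmentation errors, the severe category imbalance of real consultancy
data, label noise in category assignment, and answers whose correctness is
semantic rather than topical. Passing the learnability tests therefore
shows that the models, losses and gradients are implemented correctly and
can exploit topical co-occurrence — it does not certify performance on real
clinical text.

## Desk-scale study conditions

The test suite and the acceptance script train both matching networks on a
generated corpus with overlap 0.9, noise 0.1, 200 training and 50
development questions, character-level input, lengths 12/20, embedding
dimension 32, MV-LSTM hidden size 32 with k-max 30, MatchPyramid with 16
kernels over 2 layers, dropout 0.5, Adam at 0.001, batch 16, at most 10
epochs. Under these conditions both networks reliably exceed dev P@1 0.6
and the BM25 baseline on the same lists. Full-scale published-style scores
require the real corpus and full-size models and are out of scope here.

## Known limitations

* Pure-R training: adequate at desk scale, not meant for the full corpus.
* The bilinear interaction is dense (`d x d`); very large hidden sizes are
  memory-hungry.
* `k_top` must not exceed the interaction matrix size; very short inputs
  combined with CSCR's row halving can violate this, which is reported as
  an error rather than silently clamped.
* Checkpoints are R serializations; no interoperability with other
  frameworks is attempted.
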