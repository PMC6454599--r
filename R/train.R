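#' Mean binary cross-entropy over match scores
#'
#' `-(1/N) sum_i [ y_i log p1_i + (1 - y_i) log p0_i ]` with the class
#' probabilities obtained from the softmax over `(s0, s1)`. Computed in
#' log-sum-exp form, so confident scores never produce `log(0)`.
#'
#' @param scores a list of [match_scores()] objects, or an N x 2 matrix of
#'   `(s0, s1)` rows.
#' @param labels integer vector in \{0,1\}, one per score pair.
#' @return Non-negative scalar loss.
#' @export
xent_loss <- function(scores, labels) {
  S <- if (is.matrix(scores)) scores else
    t(vapply(scores, function(m) c(m$s0, m$s1), numeric(2)))
  stopifnot(nrow(S) == length(labels), all(labels %in% c(0L, 1L)))
  m <- pmax(S[, 1L], S[, 2L])
  lse <- m + log(exp(S[, 1L] - m) + exp(S[, 2L] - m))
  s_y <- ifelse(labels == 1L, S[, 2L], S[, 1L])
  mean(lse - s_y)
}

# gradient of per-example cross-entropy wrt (s0, s1): softmax(s) - onehot(y)
xent_grad <- function(s, y) {
  p <- softmax2(s)
  p - c(1 - y, y)
}

#' Encode ranking lists for a matcher
#'
#' Tokenizes question and candidates with the configured input unit and
#' encodes them as fixed-length index sequences.
#'
#' @param lists list of `ranking_list` objects.
#' @param vocab a [build_vocab()] vocabulary.
#' @param length_q,length_a fixed encoded lengths.
#' @param unit `"char"` or `"word"`.
#' @return A list of encoded lists: each has `question_id`, `q` (integer
#'   vector), `A` (candidates x `length_a` integer matrix), `labels`.
#' @export
encode_lists <- function(lists, vocab, length_q, length_a,
                         unit = c("char", "word")) {
  unit <- match.arg(unit)
  lapply(lists, function(l) {
    A <- t(vapply(l$candidates$answer,
                  function(a) encode(tokenize(a, unit), vocab, length_a),
                  integer(length_a)))
    rownames(A) <- NULL
    list(question_id = l$question_id,
         q = encode(tokenize(l$question, unit), vocab, length_q),
         A = A, labels = l$candidates$label)
  })
}

#' Tokenize, build the vocabulary, and encode a corpus split
#'
#' The vocabulary is fitted on the training questions and answers only;
#' unseen dev/test tokens map to OOV.
#'
#' @param train_lists,dev_lists,test_lists ranking lists (`dev`/`test`
#'   optional).
#' @param unit input unit, `"char"` or `"word"`.
#' @param min_count vocabulary frequency threshold (default 2).
#' @param length_q,length_a encoded lengths (the word-level reference
#'   setting is 50/100; character level uses 200/400; desk-scale runs use
#'   smaller values).
#' @return List with `vocab` and encoded `train`, `dev`, `test`.
#' @export
prepare_data <- function(train_lists, dev_lists = NULL, test_lists = NULL,
                         unit = c("char", "word"), min_count = 2L,
                         length_q = 50L, length_a = 100L) {
  unit <- match.arg(unit)
  streams <- unlist(lapply(train_lists, function(l) {
    c(list(tokenize(l$question, unit)),
      lapply(l$candidates$answer, tokenize, unit = unit))
  }), recursive = FALSE)
  vocab <- build_vocab(streams, min_count = min_count)
  enc <- function(ls) if (is.null(ls)) NULL else
    encode_lists(ls, vocab, length_q, length_a, unit)
  list(vocab = vocab,
       train = enc(train_lists), dev = enc(dev_lists), test = enc(test_lists),
       unit = unit, length_q = length_q, length_a = length_a)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 40; 50 is the usual setting for
#'   model comparison runs).
#' @param batch_size gradient accumulation batch (default 64).
#' @param seed seed controlling shuffling, dropout and negative sampling.
#' @param selection_metric dev metric maximized for checkpoint selection,
#'   `"map"` (default) or `"p_at_1"`.
#' @param verbose print per-epoch progress (default `FALSE`).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 40L,
                         batch_size = 64L, seed = 1L,
                         selection_metric = c("map", "p_at_1"),
                         verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 selection_metric = match.arg(selection_metric),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

matcher_forward <- function(model, q, a, train = FALSE) {
  switch(model$type,
         mvlstm = mvlstm_forward(model, q, a, train),
         matchpyramid = matchpyramid_forward(model, q, a, train),
         stop("no forward pass for model type ", model$type))
}

matcher_backward <- function(model, cache, ds) {
  switch(model$type,
         mvlstm = mvlstm_backward(model, cache, ds),
         matchpyramid = matchpyramid_backward(model, cache, ds),
         stop("no backward pass for model type ", model$type))
}

#' Score every candidate of an encoded ranking list
#'
#' For the matching networks the score is the class-1 probability `p1`;
#' for the multi-CNN it is the cosine similarity.
#'
#' @param model a `matcher_model`.
#' @param enc one encoded list from [encode_lists()].
#' @return Numeric score per candidate.
#' @export
score_list <- function(model, enc) {
  if (model$type == "multicnn") {
    vq <- multicnn_encode(model, enc$q)$v
    return(apply(enc$A, 1L, function(a) {
      cosine_sim(vq, multicnn_encode(model, a)$v)
    }))
  }
  apply(enc$A, 1L, function(a) {
    s <- matcher_forward(model, enc$q, a, train = FALSE)$s
    softmax2(s)[2L]
  })
}

#' Evaluate a matcher on encoded ranking lists
#'
#' @param model a `matcher_model`.
#' @param lists encoded lists from [encode_lists()].
#' @param tie_policy passed to [rank_candidates()].
#' @return List with `p_at_1`, `map`, `n_lists`, `ranks`.
#' @export
evaluate_model <- function(model, lists, tie_policy = "pessimistic") {
  evaluate_ranker(function(l) score_list(model, l), lists, tie_policy)
}

#' Train a matcher with Adam and dev-set model selection
#'
#' The matching networks (MV-LSTM, MatchPyramid) treat every candidate as
#' an independent binary example under softmax cross-entropy; the multi-CNN
#' is trained with a pairwise hinge loss (adopted answer vs one distractor
#' sampled per question per epoch). After each epoch the dev set is scored
#' and the checkpoint maximizing the selection metric is kept. Fully
#' reproducible given the config seed.
#'
#' @param model a `matcher_model`.
#' @param train encoded training lists (non-empty).
#' @param dev encoded development lists.
#' @param config a [train_config()].
#' @return List with `model` (best checkpoint), `history` (per-epoch data
#'   frame: `epoch`, `loss`, `dev_p_at_1`, `dev_map`), `best_epoch`.
#' @export
train_model <- function(model, train, dev, config = train_config()) {
  if (length(train) == 0L) stop("empty training set")
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_p_at_1 = numeric(), dev_map = numeric())
  best <- list(metric = -Inf, params = model$params, epoch = 0L)
  hinge <- model$type == "multicnn"
  for (epoch in seq_len(config$epochs)) {
    res <- with_seed(derive_seed(config$seed, epoch), {
      if (hinge) {
        train_epoch_hinge(model, train, state, config)
      } else {
        train_epoch_xent(model, train, state, config)
      }
    })
    model$params <- res$params
    state <- res$state
    dev_metrics <- evaluate_model(model, dev)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = res$loss,
      dev_p_at_1 = dev_metrics$p_at_1, dev_map = dev_metrics$map))
    sel <- if (config$selection_metric == "map") dev_metrics$map else
      dev_metrics$p_at_1
    if (sel > best$metric) {
      best <- list(metric = sel, params = model$params, epoch = epoch)
    }
    if (config$verbose) {
      message(sprintf("epoch %d  loss %.4f  dev P@1 %.3f  dev MAP %.3f",
                      epoch, res$loss, dev_metrics$p_at_1, dev_metrics$map))
    }
  }
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch)
}

train_epoch_xent <- function(model, train, state, config) {
  pairs <- do.call(rbind, lapply(seq_along(train), function(i) {
    cbind(i, seq_len(nrow(train[[i]]$A)))
  }))
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  total_loss <- 0
  n_seen <- 0L
  i0 <- 1L
  while (i0 <= nrow(pairs)) {
    i1 <- min(i0 + config$batch_size - 1L, nrow(pairs))
    acc <- NULL
    for (r in i0:i1) {
      l <- train[[pairs[r, 1L]]]
      j <- pairs[r, 2L]
      y <- l$labels[j]
      fwd <- matcher_forward(model, l$q, l$A[j, ], train = TRUE)
      total_loss <- total_loss + xent_loss(matrix(fwd$s, 1L), y)
      n_seen <- n_seen + 1L
      g <- matcher_backward(model, fwd$cache, xent_grad(fwd$s, y))
      acc <- grad_accumulate(acc, g)
    }
    nb <- i1 - i0 + 1L
    acc <- lapply(acc, function(x) x / nb)
    upd <- adam_step(model$params, acc, state, lr = config$learning_rate)
    model$params <- upd$params
    state <- upd$state
    i0 <- i1 + 1L
  }
  list(params = model$params, state = state, loss = total_loss / n_seen)
}

train_epoch_hinge <- function(model, train, state, config) {
  order_lists <- sample.int(length(train))
  total_loss <- 0
  n_seen <- 0L
  i0 <- 1L
  margin <- model$config$margin
  while (i0 <= length(order_lists)) {
    i1 <- min(i0 + config$batch_size - 1L, length(order_lists))
    acc <- NULL
    for (r in i0:i1) {
      l <- train[[order_lists[r]]]
      pos_j <- which(l$labels == 1L)[1L]
      negs <- which(l$labels == 0L)
      if (length(negs) == 0L) next
      neg_j <- if (length(negs) == 1L) negs else sample(negs, 1L)
      fq <- multicnn_encode(model, l$q)
      fp <- multicnn_encode(model, l$A[pos_j, ])
      fn <- multicnn_encode(model, l$A[neg_j, ])
      s_pos <- cosine_sim(fq$v, fp$v)
      s_neg <- cosine_sim(fq$v, fn$v)
      loss <- hinge_loss(s_pos, s_neg, margin)
      total_loss <- total_loss + loss
      n_seen <- n_seen + 1L
      if (loss > 0) {
        gp <- cosine_backward(fq$v, fp$v, -1)
        gn <- cosine_backward(fq$v, fn$v, +1)
        bq <- multicnn_encode_backward(model, fq$cache, gp$du + gn$du)
        bp <- multicnn_encode_backward(model, fp$cache, gp$dw)
        bn <- multicnn_encode_backward(model, fn$cache, gn$dw)
        g <- grad_accumulate(grad_accumulate(bq$grads, bp$grads), bn$grads)
        dE <- matrix(0, nrow(model$params$E), ncol(model$params$E))
        scatter <- function(dX, ids) {
          for (t in seq_along(ids)) {
            rr <- ids[t] + 1L
            dE[rr, ] <<- dE[rr, ] + dX[t, ]
          }
        }
        scatter(bq$dX, fq$cache$e$ids)
        scatter(bp$dX, fp$cache$e$ids)
        scatter(bn$dX, fn$cache$e$ids)
        dE[1L, ] <- 0
        g$E <- dE
        acc <- grad_accumulate(acc, g)
      }
    }
    if (!is.null(acc)) {
      nb <- i1 - i0 + 1L
      acc <- lapply(acc, function(x) x / nb)
      upd <- adam_step(model$params, acc, state, lr = config$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    i0 <- i1 + 1L
  }
  list(params = model$params, state = state,
       loss = if (n_seen > 0L) total_loss / n_seen else 0)
}
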