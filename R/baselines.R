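#' Okapi BM25 scores of candidate answers against a question
#'
#' Scores each answer as a document against the question as the query,
#' with inverse document frequencies computed over the candidate corpus
#' using +0.5 smoothing: `idf(t) = log(1 + (N - df + 0.5) / (df + 0.5))`.
#' Repeated query terms are counted once. `k1 = 1.2` and `b = 0.75` are the
#' classical defaults.
#'
#' @param question_tokens character vector of query tokens.
#' @param answer_token_lists list of character vectors, one per candidate.
#' @param k1 term-frequency saturation (default 1.2).
#' @param b length normalization (default 0.75).
#' @return Numeric score per candidate.
#' @export
bm25_rank <- function(question_tokens, answer_token_lists, k1 = 1.2, b = 0.75) {
  if (length(answer_token_lists) == 0L) stop("candidate set must be non-empty")
  N <- length(answer_token_lists)
  dl <- lengths(answer_token_lists)
  avgdl <- mean(dl)
  if (avgdl == 0) avgdl <- 1
  q_terms <- unique(question_tokens)
  if (length(q_terms) == 0L) return(numeric(N))
  df <- vapply(q_terms, function(t) {
    sum(vapply(answer_token_lists, function(d) t %in% d, logical(1)))
  }, numeric(1))
  idf <- log(1 + (N - df + 0.5) / (df + 0.5))
  vapply(seq_len(N), function(i) {
    d <- answer_token_lists[[i]]
    tf <- vapply(q_terms, function(t) sum(d == t), numeric(1))
    denom <- tf + k1 * (1 - b + b * dl[i] / avgdl)
    sum(ifelse(tf > 0, idf * tf * (k1 + 1) / denom, 0))
  }, numeric(1))
}

#' Uniform random ranking of candidates
#'
#' @param n_candidates number of candidates.
#' @param seed integer seed; the permutation is reproducible given the seed.
#' @return Integer permutation of `1:n_candidates`: element `i` is the rank
#'   assigned to candidate `i`.
#' @export
random_rank <- function(n_candidates, seed = 1L) {
  stopifnot(n_candidates >= 1L)
  with_seed(seed, sample.int(n_candidates))
}

#' Multi-scale siamese CNN scorer
#'
#' A siamese convolutional encoder: same-length convolutions of heights 3
#' and 4 (80 kernels each by default) with ReLU, max-over-time pooling to
#' one vector per text, and cosine similarity between the question and
#' answer vectors as the matching score. Trained with a pairwise hinge loss
#' of margin 0.01: unlike the matching networks it never interacts question
#' and answer positions directly, which is exactly the limitation the
#' matching matrix models address.
#'
#' @param vocab_size vocabulary size including PAD/OOV.
#' @param embed_dim embedding dimension (default 200).
#' @param heights convolution window heights (default `c(3, 4)`).
#' @param kernels kernels per height (default 80).
#' @param margin hinge-loss margin (default 0.01).
#' @param seed parameter initialization seed.
#' @return A `matcher_model` of type `"multicnn"`.
#' @export
multicnn_model <- function(vocab_size, embed_dim = 200L, heights = c(3L, 4L),
                           kernels = 80L, margin = 0.01, seed = 1L) {
  with_seed(seed, {
    params <- list(E = init_embeddings(vocab_size, embed_dim,
                                       seed = derive_seed(seed, 3L)))
    for (h in heights) {
      params[[paste0("Wc_h", h)]] <- glorot(h * embed_dim, kernels)
      params[[paste0("bc_h", h)]] <- numeric(kernels)
    }
    structure(list(type = "multicnn",
                   config = list(embed_dim = embed_dim, heights = heights,
                                 kernels = kernels, margin = margin),
                   cscr = NULL, vocab_size = vocab_size, params = params),
              class = c("multicnn_model", "matcher_model"))
  })
}

# encode one text to its pooled vector; caches for backprop
multicnn_encode <- function(model, ids) {
  p <- model$params
  cfg <- model$config
  e <- embed_sequence(ids, p$E)
  X <- e$X
  pieces <- list()
  caches <- list()
  for (h in cfg$heights) {
    W <- p[[paste0("Wc_h", h)]]
    b <- p[[paste0("bc_h", h)]]
    P <- im2col1d(X, h)
    Z <- sweep(P %*% W, 2L, b, `+`)
    A <- pmax(Z, 0)
    arg <- max.col(t(A), ties.method = "first")
    pooled <- A[cbind(arg, seq_len(ncol(A)))]
    pieces[[as.character(h)]] <- pooled
    caches[[as.character(h)]] <- list(P = P, Z = Z, arg = arg, W = W, h = h)
  }
  list(v = unlist(pieces, use.names = FALSE),
       cache = list(per_h = caches, e = e, n = nrow(X), k = ncol(X)))
}

multicnn_encode_backward <- function(model, cache, dv) {
  cfg <- model$config
  K <- cfg$kernels
  g <- list()
  dX <- matrix(0, cache$n, cache$k)
  off <- 0L
  for (h in cfg$heights) {
    ch <- cache$per_h[[as.character(h)]]
    dpool <- dv[off + seq_len(K)]
    dA <- matrix(0, cache$n, K)
    dA[cbind(ch$arg, seq_len(K))] <- dpool
    dZ <- dA * (ch$Z > 0)
    g[[paste0("Wc_h", h)]] <- crossprod(ch$P, dZ)
    g[[paste0("bc_h", h)]] <- colSums(dZ)
    dX <- dX + col2im1d(dZ %*% t(ch$W), cache$n, cache$k, h)
    off <- off + K
  }
  list(grads = g, dX = dX)
}

#' Cosine matching score of the multi-CNN encoder
#'
#' @param model a [multicnn_model()].
#' @param q_ids,a_ids encoded index sequences (see [encode()]).
#' @return Cosine similarity of the pooled representations (0 when either
#'   vector is all-zero).
#' @export
multicnn_score <- function(model, q_ids, a_ids) {
  vq <- multicnn_encode(model, q_ids)$v
  va <- multicnn_encode(model, a_ids)$v
  cosine_sim(vq, va)
}

cosine_sim <- function(u, w) {
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) return(0)
  sum(u * w) / (nu * nw)
}

# d(cos)/du and d(cos)/dw
cosine_backward <- function(u, w, dscore) {
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) {
    return(list(du = numeric(length(u)), dw = numeric(length(w))))
  }
  s <- sum(u * w) / (nu * nw)
  list(du = dscore * (w / (nu * nw) - s * u / nu^2),
       dw = dscore * (u / (nu * nw) - s * w / nw^2))
}

#' Pairwise hinge loss
#'
#' `max(0, margin - score_pos + score_neg)`: zero once the adopted answer
#' outscores the distractor by at least the margin.
#'
#' @param score_pos score of the adopted answer.
#' @param score_neg score of a distractor.
#' @param margin hinge margin (default 0.01).
#' @return Non-negative scalar.
#' @export
hinge_loss <- function(score_pos, score_neg, margin = 0.01) {
  max(0, margin - score_pos + score_neg)
}
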