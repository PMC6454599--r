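#' MV-LSTM matching model
#'
#' A positional matching network: a siamese bidirectional LSTM produces a
#' positional representation of question and answer, a bilinear form scores
#' every position pair, k-max pooling keeps the strongest interactions, and
#' a two-layer MLP (tanh hidden layer) aggregates them into two class
#' scores. Optionally a CSCR module is applied to the embedded sequences
#' first, in which case the bi-LSTM runs over the CSCR block rows.
#'
#' @param vocab_size vocabulary size including PAD/OOV.
#' @param embed_dim embedding dimension (default 200).
#' @param hidden bi-LSTM hidden units per direction (default 100).
#' @param k_top k of k-max pooling (default 50).
#' @param mlp_hidden MLP hidden width (default 64).
#' @param dropout dropout rate on the pooled vector during training
#'   (default 0.5).
#' @param cscr optional [cscr_config()]; `NULL` disables CSCR.
#' @param seed parameter initialization seed.
#' @return A `matcher_model` of type `"mvlstm"`.
#' @export
mvlstm_model <- function(vocab_size, embed_dim = 200L, hidden = 100L,
                         k_top = 50L, mlp_hidden = 64L, dropout = 0.5,
                         cscr = NULL, seed = 1L) {
  stopifnot(hidden >= 1L, k_top >= 1L, dropout >= 0, dropout < 1)
  with_seed(seed, {
    lstm_in <- if (is.null(cscr)) embed_dim else cscr_total_filters(cscr)
    params <- c(
      list(E = init_embeddings(vocab_size, embed_dim, seed = derive_seed(seed, 1L))),
      if (!is.null(cscr)) cscr_init(cscr, embed_dim),
      bilstm_init(lstm_in, hidden),
      list(B = glorot(2L * hidden, 2L * hidden),
           b_bi = matrix(0, 1L, 1L),
           W_r = glorot(mlp_hidden, k_top),
           b_r = numeric(mlp_hidden),
           W_s = glorot(2L, mlp_hidden),
           b_s = numeric(2L))
    )
    structure(list(type = "mvlstm",
                   config = list(embed_dim = embed_dim, hidden = hidden,
                                 k_top = k_top, mlp_hidden = mlp_hidden,
                                 dropout = dropout),
                   cscr = cscr, vocab_size = vocab_size, params = params),
              class = c("mvlstm_model", "matcher_model"))
  })
}

mvlstm_forward <- function(model, q_ids, a_ids, train = FALSE) {
  p <- model$params
  cfg <- model$config
  eq <- embed_sequence(q_ids, p$E)
  ea <- embed_sequence(a_ids, p$E)
  cq <- ca <- NULL
  if (!is.null(model$cscr)) {
    cq <- cscr_fwd(eq$X, model$cscr, p)
    ca <- cscr_fwd(ea$X, model$cscr, p)
    Xq <- cq$z; Xa <- ca$z
  } else {
    Xq <- eq$X; Xa <- ea$X
  }
  bq <- bilstm_forward(Xq, p)
  ba <- bilstm_forward(Xa, p)
  S <- bilinear_interaction(bq$P, ba$P, p$B, p$b_bi[1L, 1L])
  if (cfg$k_top > length(S))
    stop("k_top (", cfg$k_top, ") exceeds interaction matrix size (",
         length(S), "); shorten k_top or lengthen the inputs")
  km <- k_max_pool_idx(S, cfg$k_top)
  mask <- if (train) dropout_mask(cfg$k_top, cfg$dropout) else rep(1, cfg$k_top)
  v <- km$v * mask
  hpre <- as.numeric(p$W_r %*% v) + p$b_r
  hh <- tanh(hpre)
  s <- as.numeric(p$W_s %*% hh) + p$b_s
  list(s = s,
       cache = list(eq = eq, ea = ea, cq = cq, ca = ca, bq = bq, ba = ba,
                    S_dim = dim(S), km = km, mask = mask, v = v, hh = hh,
                    BA = NULL))
}

mvlstm_backward <- function(model, cache, ds) {
  p <- model$params
  g <- list()
  hh <- cache$hh
  g$W_s <- ds %o% hh
  g$b_s <- ds
  dhh <- as.numeric(t(p$W_s) %*% ds)
  dhpre <- dhh * (1 - hh^2)
  g$W_r <- dhpre %o% cache$v
  g$b_r <- dhpre
  dv <- as.numeric(t(p$W_r) %*% dhpre) * cache$mask
  dS <- matrix(0, cache$S_dim[1L], cache$S_dim[2L])
  dS[cache$km$idx] <- dv
  Pq <- cache$bq$P
  Pa <- cache$ba$P
  g$B <- crossprod(Pq, dS %*% Pa)
  g$b_bi <- matrix(sum(dS), 1L, 1L)
  dPq <- dS %*% Pa %*% t(p$B)
  dPa <- t(dS) %*% Pq %*% p$B
  gq <- bilstm_backward(dPq, cache$bq)
  ga <- bilstm_backward(dPa, cache$ba)
  g <- grad_accumulate(g, gq$grads)
  g <- grad_accumulate(g, ga$grads)
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  scatter_embedding_grad <- function(dX, ids) {
    for (t in seq_along(ids)) {
      r <- ids[t] + 1L
      dE[r, ] <<- dE[r, ] + dX[t, ]
    }
  }
  if (!is.null(model$cscr)) {
    bq_in <- cscr_backward(gq$dX, cache$cq)
    ba_in <- cscr_backward(ga$dX, cache$ca)
    g <- grad_accumulate(g, bq_in$grads)
    g <- grad_accumulate(g, ba_in$grads)
    scatter_embedding_grad(bq_in$dX, cache$eq$ids)
    scatter_embedding_grad(ba_in$dX, cache$ea$ids)
  } else {
    scatter_embedding_grad(gq$dX, cache$eq$ids)
    scatter_embedding_grad(ga$dX, cache$ea$ids)
  }
  dE[1L, ] <- 0  # PAD embedding stays fixed at zero
  g$E <- dE
  g
}
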