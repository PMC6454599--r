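#' MatchPyramid matching model
#'
#' Treats the question-answer dot-product matching matrix as a gray image:
#' a stack of square-kernel ReLU convolutions extracts hierarchical matching
#' patterns (n-gram and n-term matches), dynamic max pooling maps the
#' variable-sized result onto a fixed grid, and a fully connected head (one
#' tanh hidden layer) produces the two class scores. Optionally a CSCR
#' module transforms the embedded sequences first, in which case the
#' matching matrix is computed over CSCR block rows.
#'
#' @param vocab_size vocabulary size including PAD/OOV.
#' @param embed_dim embedding dimension (default 200).
#' @param kernel_size square convolution kernel side (default 3).
#' @param kernels convolution kernels per layer (default 64).
#' @param n_layers number of convolution layers, 1 to 3 (default 2).
#' @param pool_size dynamic pooling output grid, rows x cols
#'   (default `c(3, 10)`).
#' @param mlp_hidden fully connected hidden width (default 64).
#' @param dropout dropout rate on the pooled vector during training
#'   (default 0.5).
#' @param cscr optional [cscr_config()] (the `c(2, 3, 4)` heights setting
#'   is the usual companion); `NULL` disables CSCR.
#' @param seed parameter initialization seed.
#' @return A `matcher_model` of type `"matchpyramid"`.
#' @export
matchpyramid_model <- function(vocab_size, embed_dim = 200L,
                               kernel_size = 3L, kernels = 64L,
                               n_layers = 2L, pool_size = c(3L, 10L),
                               mlp_hidden = 64L, dropout = 0.5,
                               cscr = NULL, seed = 1L) {
  stopifnot(n_layers >= 1L, n_layers <= 3L, all(pool_size >= 1L),
            kernel_size %% 2L == 1L, dropout >= 0, dropout < 1)
  with_seed(seed, {
    params <- c(
      list(E = init_embeddings(vocab_size, embed_dim, seed = derive_seed(seed, 2L))),
      if (!is.null(cscr)) cscr_init(cscr, embed_dim)
    )
    in_ch <- 1L
    for (l in seq_len(n_layers)) {
      params[[paste0("Wc", l)]] <- glorot(kernel_size^2 * in_ch, kernels)
      params[[paste0("bc", l)]] <- numeric(kernels)
      in_ch <- kernels
    }
    n_feat <- prod(pool_size) * kernels
    params$W_r <- glorot(mlp_hidden, n_feat)
    params$b_r <- numeric(mlp_hidden)
    params$W_s <- glorot(2L, mlp_hidden)
    params$b_s <- numeric(2L)
    structure(list(type = "matchpyramid",
                   config = list(embed_dim = embed_dim,
                                 kernel_size = kernel_size, kernels = kernels,
                                 n_layers = n_layers, pool_size = pool_size,
                                 mlp_hidden = mlp_hidden, dropout = dropout),
                   cscr = cscr, vocab_size = vocab_size, params = params),
              class = c("matchpyramid_model", "matcher_model"))
  })
}

#' Convolution-and-pooling head over a matching matrix
#'
#' Applies the configured stack of square-kernel ReLU convolutions to the
#' matching matrix, dynamic max pooling onto the fixed output grid, and the
#' fully connected layers, returning the two class scores. Matrices smaller
#' than the pooling grid are padded (padding never wins a max); a matrix
#' smaller than one kernel after padding is an error.
#'
#' @param S matching matrix (m x n).
#' @param model a `matchpyramid_model` (its parameters are used).
#' @return A [match_scores()] object.
#' @export
matchpyramid_head <- function(S, model) {
  out <- mp_head_forward(S, model, train = FALSE)
  match_scores(out$s[1L], out$s[2L])
}

mp_head_forward <- function(S, model, train = FALSE) {
  p <- model$params
  cfg <- model$config
  if (nrow(S) < 1L || ncol(S) < 1L) stop("empty matching matrix")
  A <- array(S, c(nrow(S), ncol(S), 1L))
  convs <- list()
  for (l in seq_len(cfg$n_layers)) {
    cv <- conv2d_relu_forward(A, p[[paste0("Wc", l)]], p[[paste0("bc", l)]],
                              cfg$kernel_size)
    convs[[l]] <- cv
    A <- cv$Y
  }
  pool <- dynamic_max_pool(A, cfg$pool_size[1L], cfg$pool_size[2L])
  v0 <- as.numeric(pool$Y)
  mask <- if (train) dropout_mask(length(v0), cfg$dropout) else rep(1, length(v0))
  v <- v0 * mask
  hh <- tanh(as.numeric(p$W_r %*% v) + p$b_r)
  s <- as.numeric(p$W_s %*% hh) + p$b_s
  list(s = s, cache = list(convs = convs, pool = pool, mask = mask,
                           v = v, hh = hh, S_dim = dim(S)))
}

mp_head_backward <- function(model, cache, ds) {
  p <- model$params
  cfg <- model$config
  g <- list()
  hh <- cache$hh
  g$W_s <- ds %o% hh
  g$b_s <- ds
  dhh <- as.numeric(t(p$W_s) %*% ds)
  dhpre <- dhh * (1 - hh^2)
  g$W_r <- dhpre %o% cache$v
  g$b_r <- dhpre
  dv <- as.numeric(t(p$W_r) %*% dhpre) * cache$mask
  dY <- array(dv, c(cfg$pool_size[1L], cfg$pool_size[2L], cfg$kernels))
  dA <- dynamic_max_pool_backward(dY, cache$pool$cache)
  for (l in rev(seq_len(cfg$n_layers))) {
    cb <- conv2d_relu_backward(dA, cache$convs[[l]]$cache)
    g[[paste0("Wc", l)]] <- cb$dW
    g[[paste0("bc", l)]] <- cb$db
    dA <- cb$dX
  }
  list(grads = g, dS = matrix(dA, cache$S_dim[1L], cache$S_dim[2L]))
}

matchpyramid_forward <- function(model, q_ids, a_ids, train = FALSE) {
  p <- model$params
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
  S <- dot_matching_matrix(Xq, Xa)
  head <- mp_head_forward(S, model, train = train)
  list(s = head$s,
       cache = list(eq = eq, ea = ea, cq = cq, ca = ca, Xq = Xq, Xa = Xa,
                    head = head$cache))
}

matchpyramid_backward <- function(model, cache, ds) {
  hb <- mp_head_backward(model, cache$head, ds)
  g <- hb$grads
  dS <- hb$dS
  dXq <- dS %*% cache$Xa
  dXa <- t(dS) %*% cache$Xq
  p <- model$params
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  scatter <- function(dX, ids) {
    for (t in seq_along(ids)) {
      r <- ids[t] + 1L
      dE[r, ] <<- dE[r, ] + dX[t, ]
    }
  }
  if (!is.null(model$cscr)) {
    bq <- cscr_backward(dXq, cache$cq)
    ba <- cscr_backward(dXa, cache$ca)
    g <- grad_accumulate(g, bq$grads)
    g <- grad_accumulate(g, ba$grads)
    scatter(bq$dX, cache$eq$ids)
    scatter(ba$dX, cache$ea$ids)
  } else {
    scatter(dXq, cache$eq$ids)
    scatter(dXa, cache$ea$ids)
  }
  dE[1L, ] <- 0
  g$E <- dE
  g
}
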