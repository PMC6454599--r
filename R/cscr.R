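#' CSCR configuration
#'
#' The Convolutional Semantic Clustered Representation applies same-length
#' convolution filters of several heights over a token-embedding sequence,
#' then an overlapped windowed max pooling (window `m`, stride `d`) to each
#' feature map, producing one row of clustered semantic signals per pooled
#' block. With the defaults `m = 3`, `d = 2`, adjacent pooling windows
#' overlap by exactly one position, letting neighbouring characters or
#' segments compete so the strongest local composition (a latent word or
#' clinical term) wins the block.
#'
#' @param heights integer vector of filter window heights (default
#'   `c(1, 2, 3)`, the setting used in front of MV-LSTM; `c(2, 3, 4)` is
#'   the MatchPyramid setting).
#' @param filters filters per height (default 64).
#' @param m pooling window size (default 3).
#' @param d pooling stride (default 2).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param bias include a bias term per filter (default `TRUE`).
#' @return A `cscr_config` list.
#' @export
cscr_config <- function(heights = c(1L, 2L, 3L), filters = 64L,
                        m = 3L, d = 2L, activation = c("relu", "tanh"),
                        bias = TRUE) {
  activation <- match.arg(activation)
  stopifnot(m >= 1L, d >= 1L, all(heights >= 1L), filters >= 1L)
  structure(list(heights = as.integer(heights), filters = as.integer(filters),
                 m = as.integer(m), d = as.integer(d),
                 activation = activation, bias = isTRUE(bias)),
            class = "cscr_config")
}

cscr_total_filters <- function(config) length(config$heights) * config$filters

# parameters: one weight matrix (h*k x filters) and bias vector per height
cscr_init <- function(config, input_dim) {
  params <- list()
  for (h in config$heights) {
    params[[paste0("W_h", h)]] <- glorot(h * input_dim, config$filters)
    params[[paste0("b_h", h)]] <- numeric(config$filters)
  }
  params
}

#' Same-length convolution of one filter over an embedded sentence
#'
#' Computes the feature map `c_i = f(w . x_{i:i+h-1} + b)` for every window
#' position, with zero padding (`floor((h-1)/2)` on the left, the remainder
#' on the right) so the map has the same length as the sentence.
#'
#' @param embedded n x k matrix of token embeddings.
#' @param w h x k filter matrix.
#' @param bias scalar bias (default 0).
#' @param f activation function (default identity).
#' @return Numeric feature map of length n.
#' @export
convolve_same <- function(embedded, w, bias = 0, f = identity) {
  stopifnot(is.matrix(embedded), is.matrix(w), ncol(w) == ncol(embedded))
  n <- nrow(embedded)
  if (n < 1L) stop("empty input")
  h <- nrow(w)
  if (h > 2L * n) stop("filter height ", h, " exceeds padded input capacity")
  P <- im2col1d(embedded, h)
  f(as.numeric(P %*% as.numeric(t(w))) + bias)
}

#' Overlapped windowed max pooling of a feature map
#'
#' Pools `max(c[1 + (j-1)d : (j-1)d + m])` for `j = 1, ..., ceiling(n/d)`.
#' Windows that overrun the end of the map are clipped (equivalently,
#' end-padded with values that never win); a window with no real values
#' would yield 0, but every window here starts inside the map.
#'
#' @param feature_map numeric vector (length n >= 1).
#' @param m window size (default 3).
#' @param d stride (default 2).
#' @return Numeric vector of length `ceiling(n/d)`.
#' @export
windowed_max_pool <- function(feature_map, m = 3L, d = 2L) {
  if (m < 1L || d < 1L) stop("m and d must be >= 1")
  n <- length(feature_map)
  if (n < 1L) stop("empty feature map")
  out <- strided_max_pool_mat(matrix(feature_map, ncol = 1L), m, d)
  as.numeric(out$P)
}

# Windowed max over every column of C (n x F), window m, stride d.
# Returns pooled matrix (ceiling(n/d) x F) and the winning row per entry.
strided_max_pool_mat <- function(C, m, d) {
  n <- nrow(C)
  nb <- ceiling(n / d)
  F_ <- ncol(C)
  starts <- 1L + (seq_len(nb) - 1L) * d
  P <- matrix(-Inf, nb, F_)
  arg <- matrix(NA_integer_, nb, F_)
  for (off in 0L:(m - 1L)) {
    rows <- starts + off
    valid <- rows <= n
    if (!any(valid)) break
    cand <- C[rows[valid], , drop = FALSE]
    cur <- P[valid, , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    P[valid, ] <- cur
    a <- arg[valid, , drop = FALSE]
    a[better] <- matrix(rows[valid], sum(valid), F_)[better]
    arg[valid, ] <- a
  }
  list(P = P, arg = arg)
}

# forward with caches for training
cscr_fwd <- function(embedded, config, params) {
  n0 <- nrow(embedded)
  if (is.null(n0) || n0 < 1L) stop("empty input")
  k <- ncol(embedded)
  # right-pad with PAD (zero) embeddings to a multiple of the stride
  n <- as.integer(ceiling(n0 / config$d) * config$d)
  X <- if (n > n0) rbind(embedded, matrix(0, n - n0, k)) else embedded
  act <- config$activation
  pieces <- list()
  caches <- list()
  for (h in config$heights) {
    W <- params[[paste0("W_h", h)]]
    b <- if (config$bias) params[[paste0("b_h", h)]] else numeric(config$filters)
    P <- im2col1d(X, h)
    Z <- sweep(P %*% W, 2L, b, `+`)
    A <- if (act == "relu") pmax(Z, 0) else tanh(Z)
    pool <- strided_max_pool_mat(A, config$m, config$d)
    pieces[[as.character(h)]] <- pool$P
    caches[[as.character(h)]] <- list(P = P, Z = Z, A = A, arg = pool$arg,
                                      h = h, W = W)
  }
  z <- do.call(cbind, pieces)
  attr(z, "block_start") <- 1L + (seq_len(nrow(z)) - 1L) * config$d
  list(z = z, cache = list(per_h = caches, n0 = n0, n = n, k = k,
                           config = config))
}

#' Clustered semantic representation of an embedded sentence
#'
#' Runs every configured filter over the sequence (same-length convolution),
#' applies the overlapped windowed max pooling to each feature map, and
#' concatenates the pooled maps as the columns of the block-level matrix
#' `z`. Sentences are right-padded with zero (PAD) embeddings to a multiple
#' of the stride `d` beforehand, so the row count is always
#' `ceiling(n/d)`.
#'
#' @param embedded n x k matrix of token embeddings (n >= 1).
#' @param config a [cscr_config()].
#' @param params parameter list from the model (one `W_h<h>` / `b_h<h>` pair
#'   per height); see [cscr_config()].
#' @return Matrix `z` of shape `ceiling(n/d)` x (heights x filters), with a
#'   `block_start` attribute giving the token offset of each pooled block.
#' @export
cscr_forward <- function(embedded, config, params) {
  cscr_fwd(embedded, config, params)$z
}

# backprop: dz is d(loss)/d(z); returns dX (n0 x k) and parameter grads
cscr_backward <- function(dz, fwd) {
  cache <- fwd$cache
  config <- cache$config
  F_ <- config$filters
  dX <- matrix(0, cache$n, cache$k)
  grads <- list()
  col0 <- 0L
  for (h in config$heights) {
    ch <- cache$per_h[[as.character(h)]]
    dzh <- dz[, col0 + seq_len(F_), drop = FALSE]
    dA <- matrix(0, cache$n, F_)
    for (j in seq_len(nrow(dzh))) {
      rows <- ch$arg[j, ]
      ok <- !is.na(rows)
      if (any(ok)) {
        idx <- cbind(rows[ok], which(ok))
        dA[idx] <- dA[idx] + dzh[j, ok]
      }
    }
    dZ <- if (config$activation == "relu") dA * (ch$Z > 0) else dA * (1 - ch$A^2)
    grads[[paste0("W_h", h)]] <- crossprod(ch$P, dZ)
    if (config$bias) grads[[paste0("b_h", h)]] <- colSums(dZ)
    dP <- dZ %*% t(ch$W)
    dX <- dX + col2im1d(dP, cache$n, cache$k, h)
    col0 <- col0 + F_
  }
  list(dX = dX[seq_len(cache$n0), , drop = FALSE], grads = grads)
}
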