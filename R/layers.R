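# Internal neural-network primitives with manually derived gradients.
# All models in this package are small enough that vectorized base R
# (one big matrix product per layer / per time step) is adequate on a
# single CPU at desk scale.

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable two-class softmax for a score pair (s0, s1)
softmax2 <- function(s) {
  m <- max(s)
  e <- exp(s - m)
  e / sum(e)
}

# Glorot-uniform weight init: limit sqrt(6 / (fan_in + fan_out))
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- LSTM ------------------------------------------------------------------

# One-direction LSTM over a sequence.
# X: T x k input; Wx: k x 4H; Wh: H x 4H; b: 4H (gate order i, f, g, o).
# Returns H_seq (T x H) plus the caches needed for backprop.
lstm_forward <- function(X, Wx, Wh, b) {
  Tn <- nrow(X)
  H <- ncol(Wh)
  Hh <- H / 4L
  XW <- X %*% Wx
  Hs <- matrix(0, Tn, Hh)
  I <- F_ <- G <- O <- C <- Ct <- matrix(0, Tn, Hh)
  h <- numeric(Hh)
  cc <- numeric(Hh)
  i_idx <- seq_len(Hh)
  f_idx <- Hh + i_idx
  g_idx <- 2L * Hh + i_idx
  o_idx <- 3L * Hh + i_idx
  for (t in seq_len(Tn)) {
    a <- XW[t, ] + as.numeric(h %*% Wh) + b
    i <- sigmoid(a[i_idx]); f <- sigmoid(a[f_idx])
    g <- tanh(a[g_idx]);    o <- sigmoid(a[o_idx])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[t, ] <- i; F_[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- cc; Ct[t, ] <- tc
    Hs[t, ] <- h
  }
  list(H = Hs, cache = list(X = X, I = I, F = F_, G = G, O = O,
                            C = C, Ct = Ct, Wx = Wx, Wh = Wh))
}

# Backprop through time. dH: T x H gradient on the hidden outputs.
# Returns dX, dWx, dWh, db.
lstm_backward <- function(dH, fwd) {
  cache <- fwd$cache
  X <- cache$X; I <- cache$I; F_ <- cache$F; G <- cache$G
  O <- cache$O; C <- cache$C; Ct <- cache$Ct
  Wx <- cache$Wx; Wh <- cache$Wh
  Tn <- nrow(X)
  Hh <- ncol(I)
  dA <- matrix(0, Tn, 4L * Hh)
  dh_next <- numeric(Hh)
  dc_next <- numeric(Hh)
  i_idx <- seq_len(Hh)
  for (t in rev(seq_len(Tn))) {
    dh <- dH[t, ] + dh_next
    i <- I[t, ]; f <- F_[t, ]; g <- G[t, ]; o <- O[t, ]; tc <- Ct[t, ]
    c_prev <- if (t > 1L) C[t - 1L, ] else numeric(Hh)
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g
    df <- dc * c_prev
    dg <- dc * i
    dc_next <- dc * f
    da <- c(di * i * (1 - i), df * f * (1 - f),
            dg * (1 - g^2), do_ * o * (1 - o))
    dA[t, ] <- da
    dh_next <- as.numeric(Wh %*% da)
  }
  H_prev <- rbind(numeric(Hh), fwd$H[-Tn, , drop = FALSE])
  list(dX = dA %*% t(Wx), dWx = crossprod(X, dA),
       dWh = crossprod(H_prev, dA), db = colSums(dA))
}

# Bidirectional LSTM: forward pass over X and over the reversed sequence;
# row t of the result is [h_fwd_t, h_bwd_t] (positional representation).
bilstm_forward <- function(X, params) {
  fw <- lstm_forward(X, params$Wx_f, params$Wh_f, params$b_f)
  Xr <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  bw <- lstm_forward(Xr, params$Wx_b, params$Wh_b, params$b_b)
  Hb <- bw$H[rev(seq_len(nrow(X))), , drop = FALSE]
  list(P = cbind(fw$H, Hb), fw = fw, bw = bw)
}

bilstm_backward <- function(dP, fwd) {
  Hh <- ncol(fwd$fw$H)
  dHf <- dP[, seq_len(Hh), drop = FALSE]
  dHb <- dP[, Hh + seq_len(Hh), drop = FALSE]
  n <- nrow(dP)
  gf <- lstm_backward(dHf, fwd$fw)
  gb <- lstm_backward(dHb[rev(seq_len(n)), , drop = FALSE], fwd$bw)
  dX <- gf$dX + gb$dX[rev(seq_len(n)), , drop = FALSE]
  list(dX = dX,
       grads = list(Wx_f = gf$dWx, Wh_f = gf$dWh, b_f = gf$db,
                    Wx_b = gb$dWx, Wh_b = gb$dWh, b_b = gb$db))
}

bilstm_init <- function(input_dim, hidden) {
  one <- function() {
    Wx <- glorot(input_dim, 4L * hidden)
    Wh <- glorot(hidden, 4L * hidden)
    b <- numeric(4L * hidden)
    b[hidden + seq_len(hidden)] <- 1  # forget-gate bias
    list(Wx = Wx, Wh = Wh, b = b)
  }
  f <- one(); b <- one()
  list(Wx_f = f$Wx, Wh_f = f$Wh, b_f = f$b,
       Wx_b = b$Wx, Wh_b = b$Wh, b_b = b$b)
}

# ---- 2-D convolution (im2col) ----------------------------------------------

# X: m x n x C array; square odd kernel kh x kh, zero "same" padding.
# Returns the (m*n) x (kh*kh*C) patch matrix; positions are column-major
# (i + (j-1)*m), patch columns ordered (u, v, channel).
im2col2d <- function(X, kh) {
  m <- dim(X)[1]; n <- dim(X)[2]; C <- dim(X)[3]
  pad <- (kh - 1L) %/% 2L
  Xp <- array(0, c(m + 2L * pad, n + 2L * pad, C))
  Xp[pad + seq_len(m), pad + seq_len(n), ] <- X
  P <- matrix(0, m * n, kh * kh * C)
  col <- 0L
  for (u in seq_len(kh)) {
    for (v in seq_len(kh)) {
      block <- Xp[u - 1L + seq_len(m), v - 1L + seq_len(n), , drop = FALSE]
      P[, col + seq_len(C)] <- matrix(block, m * n, C)
      col <- col + C
    }
  }
  P
}

col2im2d <- function(dP, dims, kh) {
  m <- dims[1]; n <- dims[2]; C <- dims[3]
  pad <- (kh - 1L) %/% 2L
  dXp <- array(0, c(m + 2L * pad, n + 2L * pad, C))
  col <- 0L
  for (u in seq_len(kh)) {
    for (v in seq_len(kh)) {
      dXp[u - 1L + seq_len(m), v - 1L + seq_len(n), ] <-
        dXp[u - 1L + seq_len(m), v - 1L + seq_len(n), , drop = FALSE] +
        array(dP[, col + seq_len(C)], c(m, n, C))
      col <- col + C
    }
  }
  dXp[pad + seq_len(m), pad + seq_len(n), , drop = FALSE]
}

# ReLU convolution layer. W: (kh*kh*C_in) x F; b: F.
conv2d_relu_forward <- function(X, W, b, kh) {
  m <- dim(X)[1]; n <- dim(X)[2]
  P <- im2col2d(X, kh)
  Z <- sweep(P %*% W, 2L, b, `+`)
  A <- pmax(Z, 0)
  list(Y = array(A, c(m, n, ncol(W))),
       cache = list(P = P, mask = Z > 0, dims = dim(X), kh = kh, W = W))
}

conv2d_relu_backward <- function(dY, cache) {
  F_ <- ncol(cache$W)
  dA <- matrix(dY, ncol = F_)
  dZ <- dA * cache$mask
  list(dX = col2im2d(dZ %*% t(cache$W), cache$dims, cache$kh),
       dW = crossprod(cache$P, dZ),
       db = colSums(dZ))
}

# even integer partition of n into p cells, remainder to the leading cells
pool_cells <- function(n, p) {
  base <- n %/% p
  sizes <- rep(base, p) + as.integer(seq_len(p) <= n %% p)
  ends <- cumsum(sizes)
  mapply(function(s, e) if (s <= e) s:e else integer(0),
         ends - sizes + 1L, ends, SIMPLIFY = FALSE)
}

# Dynamic max pooling of an m x n x C array onto a fixed out_r x out_c grid.
# Inputs smaller than the grid are padded with -Inf rows/columns (a cell
# consisting only of padding yields 0 and no gradient).
dynamic_max_pool <- function(X, out_r, out_c) {
  m <- dim(X)[1]; n <- dim(X)[2]; C <- dim(X)[3]
  mp <- max(m, out_r); np <- max(n, out_c)
  if (mp > m || np > n) {
    Xp <- array(-Inf, c(mp, np, C))
    Xp[seq_len(m), seq_len(n), ] <- X
    X <- Xp
  }
  rows <- pool_cells(mp, out_r)
  cols <- pool_cells(np, out_c)
  Y <- array(0, c(out_r, out_c, C))
  arg <- array(NA_integer_, c(out_r, out_c, C))  # linear index into padded X
  for (i in seq_len(out_r)) {
    for (j in seq_len(out_c)) {
      block <- X[rows[[i]], cols[[j]], , drop = FALSE]
      br <- length(rows[[i]]); bc <- length(cols[[j]])
      Bm <- matrix(block, br * bc, C)
      w <- max.col(t(Bm), ties.method = "first")
      v <- Bm[cbind(w, seq_len(C))]
      finite <- is.finite(v)
      Y[i, j, ] <- ifelse(finite, v, 0)
      # map block-local argmax back to padded-array linear indices
      li <- (w - 1L) %% br + 1L
      lj <- (w - 1L) %/% br + 1L
      gi <- rows[[i]][li]; gj <- cols[[j]][lj]
      idx <- gi + (gj - 1L) * mp + (seq_len(C) - 1L) * mp * np
      arg[i, j, ] <- ifelse(finite, idx, NA_integer_)
    }
  }
  list(Y = Y, cache = list(arg = arg, m = m, n = n, C = C, mp = mp, np = np))
}

dynamic_max_pool_backward <- function(dY, cache) {
  dXp <- array(0, c(cache$mp, cache$np, cache$C))
  ok <- !is.na(cache$arg)
  idx <- cache$arg[ok]
  # accumulate: several cells can share an argmax position when cells overlap
  # (they never do here, but tapply keeps this safe)
  add <- tapply(dY[ok], idx, sum)
  dXp[as.integer(names(add))] <- dXp[as.integer(names(add))] + as.numeric(add)
  dXp[seq_len(cache$m), seq_len(cache$n), , drop = FALSE]
}

# ---- 1-D same-length convolution over a token-embedding sequence ----------

# X: n x k; W: (h*k) x F filters of height h; zero padding floor((h-1)/2)
# on the left, remainder on the right, so the feature map has length n.
im2col1d <- function(X, h) {
  n <- nrow(X); k <- ncol(X)
  pad_l <- (h - 1L) %/% 2L
  pad_r <- h - 1L - pad_l
  Xp <- rbind(matrix(0, pad_l, k), X, matrix(0, pad_r, k))
  P <- matrix(0, n, h * k)
  for (u in seq_len(h)) {
    P[, (u - 1L) * k + seq_len(k)] <- Xp[u - 1L + seq_len(n), , drop = FALSE]
  }
  P
}

col2im1d <- function(dP, n, k, h) {
  pad_l <- (h - 1L) %/% 2L
  pad_r <- h - 1L - pad_l
  dXp <- matrix(0, n + pad_l + pad_r, k)
  for (u in seq_len(h)) {
    dXp[u - 1L + seq_len(n), ] <- dXp[u - 1L + seq_len(n), , drop = FALSE] +
      dP[, (u - 1L) * k + seq_len(k), drop = FALSE]
  }
  dXp[pad_l + seq_len(n), , drop = FALSE]
}

# ---- dropout / Adam --------------------------------------------------------

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two same-shape gradient lists (NULL-tolerant)
grad_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
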