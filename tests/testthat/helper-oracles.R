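# Independent, loop-based reference implementations used as oracles.
# These deliberately avoid the package's vectorized code paths.

# CSCR: scalar-loop convolution (same-length, left-biased zero padding),
# activation, and strided windowed max pooling, one filter at a time.
brute_cscr <- function(X, config, params) {
  n0 <- nrow(X); k <- ncol(X)
  d <- config$d; m <- config$m
  n <- as.integer(ceiling(n0 / d) * d)
  Xp <- rbind(X, matrix(0, n - n0, k))
  cols <- list()
  for (h in config$heights) {
    W <- params[[paste0("W_h", h)]]
    b <- params[[paste0("b_h", h)]]
    pad_l <- (h - 1) %/% 2
    pad_r <- h - 1 - pad_l
    Xpad <- rbind(matrix(0, pad_l, k), Xp, matrix(0, pad_r, k))
    for (f in seq_len(config$filters)) {
      w <- matrix(W[, f], h, k, byrow = TRUE)
      cvec <- numeric(n)
      for (i in seq_len(n)) {
        acc <- 0
        for (u in seq_len(h)) for (j in seq_len(k)) {
          acc <- acc + Xpad[i + u - 1, j] * w[u, j]
        }
        cvec[i] <- acc + b[f]
      }
      cvec <- if (config$activation == "relu") pmax(cvec, 0) else tanh(cvec)
      pooled <- numeric(n %/% d)
      for (jj in seq_along(pooled)) {
        s <- 1 + (jj - 1) * d
        pooled[jj] <- max(cvec[s:min(s + m - 1, n)])
      }
      cols[[length(cols) + 1L]] <- pooled
    }
  }
  do.call(cbind, cols)
}

# dynamic pooling: explicit block-max enumeration with the same
# even-partition rule (remainder rows/cols go to the leading cells)
brute_dynamic_pool <- function(M, out_r, out_c) {
  part <- function(n, p) {
    sizes <- rep(n %/% p, p) + as.integer(seq_len(p) <= n %% p)
    ends <- cumsum(sizes)
    mapply(function(s, e) s:e, ends - sizes + 1L, ends, SIMPLIFY = FALSE)
  }
  rows <- part(nrow(M), out_r)
  cols <- part(ncol(M), out_c)
  out <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r)) for (j in seq_len(out_c)) {
    out[i, j] <- max(M[rows[[i]], cols[[j]]])
  }
  out
}

# textbook Okapi BM25, scalar loops
brute_bm25 <- function(q_tokens, docs, k1 = 1.2, b = 0.75) {
  N <- length(docs)
  dl <- vapply(docs, length, numeric(1))
  avgdl <- mean(dl)
  terms <- unique(q_tokens)
  scores <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (t in terms) {
      df <- 0
      for (d in docs) if (t %in% d) df <- df + 1
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      tf <- sum(docs[[i]] == t)
      if (tf > 0) {
        s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl[i] / avgdl))
      }
    }
    scores[i] <- s
  }
  scores
}

# central-difference gradient of f at params[[nm]][idx]
numeric_grad <- function(f, params, nm, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    (f(pp) - f(pm)) / (2 * eps)
  }, numeric(1))
}

# relative agreement used by the gradient checks
rel_err <- function(a, b) abs(a - b) / pmax(1e-4, abs(a) + abs(b))

# small ready-made ranking corpus for pipeline tests
tiny_ranking_lists <- function(n = 20L, seed = 5L) {
  cfg <- synth_config(n_questions = n, question_len = c(6L, 12L),
                      answer_len = c(10L, 20L), overlap = 0.9, noise = 0.1,
                      seed = seed)
  generate_corpus(cfg)
}
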