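#' Positional sentence representation via bidirectional LSTM
#'
#' Runs a forward and a backward LSTM over the representation sequence and
#' concatenates the two hidden states at every position, so row `t` reflects
#' the whole sentence seen from both directions at that position. Output
#' width is twice the hidden size.
#'
#' @param repr_sequence l x k matrix (token embeddings or CSCR rows).
#' @param params bi-LSTM parameter list (`Wx_f`, `Wh_f`, `b_f`, `Wx_b`,
#'   `Wh_b`, `b_b`), e.g. from an [mvlstm_model()].
#' @return l x (2 * hidden) positional matrix.
#' @export
bilstm_positions <- function(repr_sequence, params) {
  if (is.null(nrow(repr_sequence)) || nrow(repr_sequence) < 1L)
    stop("empty sequence")
  bilstm_forward(repr_sequence, params)$P
}

#' Bilinear interaction matrix between two positional representations
#'
#' `S[i, j] = Q_i B A_j' + b`: the bilinear form re-weights interactions
#' between representation dimensions before the dot product.
#'
#' @param Q m x d matrix (question positions).
#' @param A n x d matrix (answer positions).
#' @param B d x d bilinear matrix.
#' @param b scalar bias.
#' @return m x n similarity matrix.
#' @export
bilinear_interaction <- function(Q, A, B, b = 0) {
  if (ncol(Q) != ncol(A) || ncol(Q) != nrow(B) || nrow(B) != ncol(B))
    stop("dimension mismatch: Q, A and B must share the representation dimension")
  Q %*% B %*% t(A) + b
}

#' k-max pooling over an interaction matrix
#'
#' Extracts the `k_top` largest entries of the matrix, in descending order,
#' as the strongest matching signals. The pooling is over the flattened
#' matrix (matrix-wide top-k), not per row, and is therefore invariant to
#' any permutation of the entries.
#'
#' @param S numeric matrix.
#' @param k_top number of values to keep (at most `length(S)`).
#' @return Numeric vector of length `k_top`, descending.
#' @export
k_max_pool <- function(S, k_top) {
  if (k_top > length(S))
    stop("k_top (", k_top, ") exceeds the number of matrix entries (",
         length(S), ")")
  if (k_top < 1L) stop("k_top must be >= 1")
  v <- as.numeric(S)
  v[order(v, decreasing = TRUE)[seq_len(k_top)]]
}

# k-max with argument indices, for backprop
k_max_pool_idx <- function(S, k_top) {
  v <- as.numeric(S)
  idx <- order(v, decreasing = TRUE)[seq_len(k_top)]
  list(v = v[idx], idx = idx)
}

#' Two-class match scores from a pooled interaction vector
#'
#' The aggregation MLP: `(s0, s1) = W_s tanh(W_r v + b_r) + b_s`, followed
#' by a softmax over the two class scores. Class 1 is "adopted answer".
#'
#' @param v pooled interaction vector.
#' @param weights list with `W_r` (hidden x |v|), `b_r`, `W_s` (2 x hidden),
#'   `b_s` (length 2).
#' @return A `match_scores` object: `s0`, `s1`, `p0`, `p1`.
#' @export
mlp_score <- function(v, weights) {
  if (length(v) != ncol(weights$W_r))
    stop("pooled vector length ", length(v), " does not match W_r (",
         ncol(weights$W_r), " columns)")
  h <- tanh(as.numeric(weights$W_r %*% v) + weights$b_r)
  s <- as.numeric(weights$W_s %*% h) + weights$b_s
  match_scores(s[1L], s[2L])
}

#' Construct match scores with softmax probabilities
#'
#' @param s0,s1 real class scores.
#' @return A `match_scores` list with `p0 + p1 = 1`,
#'   `p_k = exp(s_k) / (exp(s0) + exp(s1))`.
#' @export
match_scores <- function(s0, s1) {
  p <- softmax2(c(s0, s1))
  structure(list(s0 = s0, s1 = s1, p0 = p[1L], p1 = p[2L]),
            class = "match_scores")
}

#' @export
print.match_scores <- function(x, ...) {
  cat(sprintf("<match_scores> s0=%.4f s1=%.4f p1=%.4f\n", x$s0, x$s1, x$p1))
  invisible(x)
}

#' Dot-product matching matrix
#'
#' `S[i, j] = Q_i . A_j`; the matching matrix corresponds to a gray image
#' over which the hierarchical convolutions operate.
#'
#' @param Q m x d matrix.
#' @param A n x d matrix.
#' @return m x n matrix of pairwise dot products.
#' @export
dot_matching_matrix <- function(Q, A) {
  if (ncol(Q) != ncol(A)) stop("dimension mismatch: Q and A must share d")
  tcrossprod(Q, A)
}
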