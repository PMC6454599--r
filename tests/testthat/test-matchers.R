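test_that("bilinear interaction matches the hand-expanded form", {
  set.seed(8)
  Q <- matrix(rnorm(12), 4, 3)
  A <- matrix(rnorm(15), 5, 3)
  # identity bilinear form reduces to plain dot products
  expect_equal(bilinear_interaction(Q, A, diag(3), 0), tcrossprod(Q, A))
  # zero vectors leave only the bias
  expect_equal(bilinear_interaction(matrix(0, 1, 3), matrix(0, 1, 3),
                                    diag(3), b = 2.5)[1, 1], 2.5)
  # hand expansion: (1,2) B (3,1)' + 0.5 with B = diag(1,2)
  S <- bilinear_interaction(matrix(c(1, 2), 1, 2), matrix(c(3, 1), 1, 2),
                            diag(c(1, 2)), b = 0.5)
  expect_equal(S[1, 1], 7.5)
  expect_error(bilinear_interaction(Q, matrix(0, 2, 4), diag(3)), "dimension")
})

test_that("k-max pooling equals sort-and-truncate and ignores entry positions", {
  S <- matrix(c(0.1, 0.5, 0.9, 0.3), 2, 2)
  expect_equal(k_max_pool(S, 3), c(0.9, 0.5, 0.3))
  expect_equal(k_max_pool(S, 4), sort(as.numeric(S), decreasing = TRUE))
  expect_equal(k_max_pool(matrix(2, 3, 3), 4), rep(2, 4))
  expect_error(k_max_pool(S, 5), "exceeds")
  set.seed(21)
  for (rep in 1:50) {
    nr <- sample(1:4, 1)
    nc <- sample(2:8, 1)
    S <- matrix(rnorm(nr * nc), nr, nc)
    k <- sample(seq_len(length(S)), 1)
    expect_equal(k_max_pool(S, k), sort(as.numeric(S), decreasing = TRUE)[1:k])
    perm <- matrix(sample(as.numeric(S)), nrow = nrow(S))
    expect_equal(k_max_pool(perm, k), k_max_pool(S, k))
  }
})

test_that("mlp_score follows the two-layer form and the softmax identities", {
  w0 <- list(W_r = matrix(0, 3, 4), b_r = rep(0, 3),
             W_s = matrix(0, 2, 3), b_s = c(0, 0))
  sc <- mlp_score(rep(1, 4), w0)
  expect_equal(c(sc$s0, sc$s1), c(0, 0))
  expect_equal(c(sc$p0, sc$p1), c(0.5, 0.5))

  sc2 <- match_scores(0, log(3))
  expect_equal(sc2$p1, 0.75)
  expect_equal(sc2$p0 + sc2$p1, 1)

  # shift invariance of the softmax
  sc3 <- match_scores(1.7, 1.7 + log(3))
  expect_equal(c(sc3$p0, sc3$p1), c(sc2$p0, sc2$p1))

  # full form against direct arithmetic
  set.seed(4)
  w <- list(W_r = matrix(rnorm(12), 3, 4), b_r = rnorm(3),
            W_s = matrix(rnorm(6), 2, 3), b_s = rnorm(2))
  v <- rnorm(4)
  s_hand <- as.numeric(w$W_s %*% tanh(as.numeric(w$W_r %*% v) + w$b_r)) + w$b_s
  sc4 <- mlp_score(v, w)
  expect_equal(c(sc4$s0, sc4$s1), s_hand)
  expect_error(mlp_score(rnorm(5), w), "does not match")
})

test_that("dot matching matrix is the grid of pairwise dot products", {
  Q <- rbind(c(1, 0), c(0, 1))
  A <- rbind(c(0, 1), c(1, 0))
  expect_equal(dot_matching_matrix(Q, Q), diag(2))
  expect_equal(dot_matching_matrix(Q, A), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(dot_matching_matrix(matrix(c(1, 2, 0), 1, 3),
                                   matrix(c(0, 1, 5), 1, 3))[1, 1], 2)
  expect_error(dot_matching_matrix(Q, matrix(0, 1, 3)), "dimension")
})

test_that("dynamic pooling maps any input onto the fixed grid, matching block-max", {
  set.seed(12)
  for (rep in 1:40) {
    m <- sample(3:17, 1)
    n <- sample(10:31, 1)
    M <- matrix(rnorm(m * n), m, n)
    got <- medmatch:::dynamic_max_pool(array(M, c(m, n, 1)), 3L, 10L)
    expect_equal(got$Y[, , 1], brute_dynamic_pool(M, 3L, 10L))
  }
  # constant map pools to a constant grid
  got <- medmatch:::dynamic_max_pool(array(1.5, c(6, 20, 2)), 3L, 10L)
  expect_true(all(got$Y == 1.5))
  expect_equal(dim(got$Y), c(3L, 10L, 2L))
  # 6 x 20 input: every cell is a 2 x 2 block max
  M <- matrix(rnorm(120), 6, 20)
  got <- medmatch:::dynamic_max_pool(array(M, c(6, 20, 1)), 3L, 10L)
  for (i in 1:3) for (j in 1:10) {
    expect_equal(got$Y[i, j, 1],
                 max(M[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
  }
})

test_that("matchpyramid head output size is fixed by the pooling grid", {
  mp <- matchpyramid_model(vocab_size = 30L, embed_dim = 6L, kernels = 5L,
                           n_layers = 2L, pool_size = c(3L, 10L),
                           mlp_hidden = 8L, seed = 2L)
  for (dims in list(c(4, 12), c(3, 10), c(9, 33), c(2, 6))) {
    S <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    out <- medmatch:::mp_head_forward(S, mp)
    expect_length(out$cache$v, 3 * 10 * 5)
    sc <- matchpyramid_head(S, mp)
    expect_s3_class(sc, "match_scores")
    expect_equal(sc$p0 + sc$p1, 1)
  }
})

test_that("bilstm positional representation concatenates both directions", {
  mv <- mvlstm_model(vocab_size = 20L, embed_dim = 4L, hidden = 7L,
                     k_top = 5L, seed = 9L)
  X <- matrix(rnorm(12), 3, 4)
  P <- bilstm_positions(X, mv$params)
  expect_equal(dim(P), c(3L, 14L))
  # the backward half equals running the backward-direction cell explicitly
  # over the reversed sequence
  Xr <- X[3:1, , drop = FALSE]
  Hb <- medmatch:::lstm_forward(Xr, mv$params$Wx_b, mv$params$Wh_b,
                                mv$params$b_b)$H
  expect_equal(P[, 8:14], Hb[3:1, ], tolerance = 1e-12)
  # with tied direction weights, reversing the input swaps the two halves
  tied <- mv$params
  tied$Wx_b <- tied$Wx_f; tied$Wh_b <- tied$Wh_f; tied$b_b <- tied$b_f
  Pt <- bilstm_positions(X, tied)
  Ptr <- bilstm_positions(Xr, tied)
  expect_equal(Ptr[, 1:7], Pt[3:1, 8:14], tolerance = 1e-12)
  expect_equal(Ptr[, 8:14], Pt[3:1, 1:7], tolerance = 1e-12)
  # an all-zero (all-PAD) input is deterministic
  Z <- matrix(0, 4, 4)
  expect_equal(bilstm_positions(Z, mv$params), bilstm_positions(Z, mv$params))
})

test_that("bm25 matches the textbook formula on toy corpora", {
  q <- c("头", "痛", "多", "梦")
  docs <- list(c("头", "痛", "头"), c("失", "眠", "多", "梦", "多"),
               c("健", "康"))
  expect_equal(bm25_rank(q, docs), brute_bm25(q, docs))
  set.seed(14)
  for (rep in 1:10) {
    vocab <- letters[1:8]
    q <- sample(vocab, 5, replace = TRUE)
    docs <- lapply(1:4, function(i) sample(vocab, sample(3:9, 1), replace = TRUE))
    expect_equal(bm25_rank(q, docs), brute_bm25(q, docs))
  }
  # absent query terms contribute nothing
  expect_equal(bm25_rank("z", docs), rep(0, 4))
  # identical answers get identical scores
  twin <- list(c("a", "b"), c("a", "b"), c("c"))
  s <- bm25_rank(c("a", "b"), twin)
  expect_equal(s[1], s[2])
  expect_error(bm25_rank(q, list()), "non-empty")
})

test_that("multi-CNN cosine scorer obeys the similarity identities", {
  mc <- multicnn_model(vocab_size = 25L, embed_dim = 6L, kernels = 4L, seed = 3L)
  ids <- c(2L, 5L, 9L, 3L, 7L)
  expect_equal(multicnn_score(mc, ids, ids), 1)
  u <- c(1, 0, 0, 0)
  w <- c(0, 1, 0, 0)
  expect_equal(medmatch:::cosine_sim(u, w), 0)
  expect_equal(medmatch:::cosine_sim(u, 3 * u), 1)
  # hinge loss closed forms
  expect_equal(hinge_loss(0.8, 0.75, margin = 0.01), 0)
  expect_equal(hinge_loss(0.5, 0.6, margin = 0.01), 0.11)
  expect_equal(hinge_loss(0.5, 0.5, margin = 0.01), 0.01)
})

test_that("random ranking is seeded, reproducible, and near-uniform", {
  expect_equal(random_rank(1L, seed = 4L), 1L)
  expect_equal(random_rank(5L, seed = 11L), random_rank(5L, seed = 11L))
  expect_setequal(random_rank(5L, seed = 11L), 1:5)
  # frequency of the rank assigned to candidate 1 over many seeds
  n_draws <- 5000L
  r1 <- vapply(seq_len(n_draws), function(s) random_rank(5L, seed = s)[1L],
               integer(1))
  tab <- tabulate(r1, 5L)
  chisq <- sum((tab - n_draws / 5)^2 / (n_draws / 5))
  expect_lt(chisq, qchisq(0.999, df = 4))
})

test_that("matchers are deterministic in inference mode", {
  lists <- tiny_ranking_lists(4L)
  prep <- prepare_data(lists, unit = "char", length_q = 12L, length_a = 20L)
  mv <- mvlstm_model(prep$vocab$size, embed_dim = 8L, hidden = 6L, k_top = 10L,
                     mlp_hidden = 6L, dropout = 0.5, seed = 5L)
  mp <- matchpyramid_model(prep$vocab$size, embed_dim = 8L, kernels = 4L,
                           mlp_hidden = 6L, dropout = 0.5, seed = 6L)
  for (model in list(mv, mp)) {
    s1 <- score_list(model, prep$train[[1]])
    s2 <- score_list(model, prep$train[[1]])
    expect_identical(s1, s2)
  }
})

test_that("CSCR halves the matcher input rows and end-to-end shapes stay consistent", {
  lists <- tiny_ranking_lists(3L)
  prep <- prepare_data(lists, unit = "char", length_q = 12L, length_a = 20L)
  cs <- cscr_config(heights = c(1L, 2L, 3L), filters = 4L)
  mv <- mvlstm_model(prep$vocab$size, embed_dim = 8L, hidden = 6L, k_top = 8L,
                     mlp_hidden = 6L, cscr = cs, seed = 5L)
  enc <- prep$train[[1]]
  fwd <- medmatch:::mvlstm_forward(mv, enc$q, enc$A[1, ])
  n_q_tokens <- sum(enc$q != 0L)
  expect_equal(fwd$cache$S_dim[1], ceiling(n_q_tokens / 2))
  expect_length(fwd$s, 2L)
  z <- cscr_forward(matrix(rnorm(10 * 8), 10, 8), cs,
                    medmatch:::cscr_init(cs, 8L))
  expect_equal(nrow(z), 5L)  # d = 2 halves the rows
})
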