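test_that("cross-entropy loss matches closed forms", {
  # p1 = 0.5, y = 1 -> ln 2
  expect_equal(xent_loss(matrix(c(0, 0), 1), 1L), log(2))
  # confident correct prediction -> loss near 0
  expect_lt(xent_loss(matrix(c(-20, 20), 1), 1L), 1e-8)
  # extreme scores stay finite (log-sum-exp stabilization)
  expect_true(is.finite(xent_loss(matrix(c(-1000, 1000), 1), 0L)))
  # label symmetry: flipping labels and swapping scores gives the same loss
  s <- matrix(c(0.3, 1.1), 1)
  expect_equal(xent_loss(s, 1L), xent_loss(s[, 2:1, drop = FALSE], 0L))
  # list-of-match_scores input and batch averaging
  scores <- list(match_scores(0, 0), match_scores(0, log(3)))
  expect_equal(xent_loss(scores, c(1L, 1L)),
               mean(c(log(2), -log(0.75))))
})

test_that("numerical and analytic gradients of the scored loss agree", {
  set.seed(17)
  # (a) loss through the aggregation MLP alone
  w <- list(W_r = matrix(rnorm(12, sd = 0.5), 3, 4), b_r = rnorm(3),
            W_s = matrix(rnorm(6, sd = 0.5), 2, 3), b_s = rnorm(2))
  v <- rnorm(4)
  y <- 1L
  lossf <- function(params) {
    sc <- mlp_score(v, params)
    xent_loss(matrix(c(sc$s0, sc$s1), 1), y)
  }
  sc <- mlp_score(v, w)
  ds <- medmatch:::xent_grad(c(sc$s0, sc$s1), y)
  hh <- tanh(as.numeric(w$W_r %*% v) + w$b_r)
  analytic <- list(
    W_s = ds %o% hh, b_s = ds,
    W_r = (as.numeric(t(w$W_s) %*% ds) * (1 - hh^2)) %o% v,
    b_r = as.numeric(t(w$W_s) %*% ds) * (1 - hh^2))
  for (nm in names(w)) {
    idx <- sample(length(w[[nm]]), min(6, length(w[[nm]])))
    ng <- numeric_grad(lossf, w, nm, idx)
    expect_lt(max(rel_err(analytic[[nm]][idx], ng)), 1e-4)
  }

  # (b) end to end through each matching network
  V <- 20L
  q <- c(2L, 5L, 7L, 3L, 10L, 11L)
  a <- c(4L, 6L, 2L, 8L, 9L, 12L, 13L, 3L, 5L, 7L, 2L, 14L)
  models <- list(
    mvlstm_model(V, embed_dim = 5L, hidden = 4L, k_top = 6L, mlp_hidden = 5L,
                 dropout = 0, seed = 3L),
    matchpyramid_model(V, embed_dim = 5L, kernels = 4L, n_layers = 2L,
                       pool_size = c(2L, 4L), mlp_hidden = 5L, dropout = 0,
                       seed = 3L),
    mvlstm_model(V, embed_dim = 5L, hidden = 4L, k_top = 4L, mlp_hidden = 5L,
                 dropout = 0, cscr = cscr_config(heights = c(1L, 2L),
                                                 filters = 3L), seed = 4L))
  for (m in models) {
    fwd <- medmatch:::matcher_forward(m, q, a)
    g <- medmatch:::matcher_backward(m, fwd$cache,
                                     medmatch:::xent_grad(fwd$s, 1L))
    lossm <- function(params) {
      mm <- m
      mm$params <- params
      f <- medmatch:::matcher_forward(mm, q, a)
      xent_loss(matrix(f$s, 1), 1L)
    }
    for (nm in names(m$params)) {
      idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
      ng <- numeric_grad(lossm, m$params, nm, idx)
      expect_lt(max(rel_err(g[[nm]][idx], ng)), 1e-4)
    }
  }
})

test_that("training is reproducible and selects the best dev epoch", {
  lists <- tiny_ranking_lists(16L)
  prep <- prepare_data(lists[1:12], lists[13:16], unit = "char",
                       length_q = 12L, length_a = 20L)
  build <- function() mvlstm_model(prep$vocab$size, embed_dim = 8L, hidden = 6L,
                                   k_top = 10L, mlp_hidden = 8L, seed = 21L)
  cfg <- train_config(epochs = 2L, batch_size = 16L, seed = 31L)
  f1 <- train_model(build(), prep$train, prep$dev, cfg)
  f2 <- train_model(build(), prep$train, prep$dev, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  sel <- f1$history$dev_map
  expect_equal(f1$best_epoch, which(sel == max(sel))[1L])
  expect_true(all(f1$history$loss >= 0))
  expect_error(train_model(build(), list(), prep$dev, cfg), "empty training set")
})

test_that("loss decreases and P@1 leaves chance level on separable synthetic data", {
  cfg <- synth_config(n_questions = 75L, question_len = c(6L, 12L),
                      answer_len = c(10L, 20L), overlap = 0.9, noise = 0,
                      seed = 13L)
  lists <- generate_corpus(cfg)
  prep <- prepare_data(lists[1:60], lists[61:75], unit = "char",
                       length_q = 12L, length_a = 20L)
  mv <- mvlstm_model(prep$vocab$size, embed_dim = 24L, hidden = 16L,
                     k_top = 20L, mlp_hidden = 16L, seed = 41L)
  fit <- train_model(mv, prep$train, prep$dev,
                     train_config(epochs = 5L, batch_size = 16L, seed = 51L))
  expect_lt(mean(tail(fit$history$loss, 2)), mean(head(fit$history$loss, 2)))
  expect_gt(max(fit$history$dev_p_at_1), 0.2)
})
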