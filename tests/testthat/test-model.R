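test_that("update gate extremes freeze or replace the hidden state", {
  model <- tiny_model(n = 4, order = 1, hidden = 3)
  cell <- model$params$enc[[1]]
  withr::with_seed(1, {
    x <- matrix(rnorm(4), 4, 1)
    h <- matrix(runif(12, -0.9, 0.9), 4, 3)
  })
  # u ~ 1: state unchanged
  open <- cell; open$bu <- rep(50, 3)
  expect_equal(dcgru_step(x, h, open, model), h, tolerance = 1e-12)
  # u ~ 0: state replaced by the tanh-bounded candidate
  closed <- cell; closed$bu <- rep(-50, 3)
  hn <- dcgru_step(x, h, closed, model)
  expect_true(all(abs(hn) < 1))
  expect_false(isTRUE(all.equal(hn, h)))
})

test_that("N = 1, K = 0 cell reduces to a plain GRU step", {
  a <- matrix(1, 1, 1)  # self-loop keeps the single node non-isolated
  tm <- transition_matrix(graph(a), include_reverse = FALSE)
  q <- 3
  model <- dcrnn(tm, order = 0, hidden_size = q, n_layers = 1, seed = 2)
  cell <- model$params$enc[[1]]
  x <- matrix(0.37, 1, 1)
  h <- matrix(c(0.1, -0.5, 0.8), 1, q)

  # independently coded scalar GRU (weights unpacked from the filter stack)
  sig <- function(z) 1 / (1 + exp(-z))
  wr_x <- cell$Wr[1, ]; wr_h <- cell$Wr[-1, ]
  wu_x <- cell$Wu[1, ]; wu_h <- cell$Wu[-1, ]
  wc_x <- cell$Wc[1, ]; wc_h <- cell$Wc[-1, ]
  r <- sig(drop(x) * wr_x + drop(h %*% wr_h) + cell$br)
  u <- sig(drop(x) * wu_x + drop(h %*% wu_h) + cell$bu)
  c_ <- tanh(drop(x) * wc_x + drop((r * h) %*% wc_h) + cell$bc)
  h_ref <- u * drop(h) + (1 - u) * c_

  expect_equal(drop(dcgru_step(x, h, cell, model)), h_ref, tolerance = 1e-10)
})

test_that("encoder is zero under zero parameters and matches a single step at T_p = 1", {
  model <- tiny_model(n = 5, order = 1, hidden = 4)
  z <- zero_params(model)
  hs <- encode(z, matrix(0, 5, 6))
  expect_true(all(vapply(hs, function(h) all(h == 0), TRUE)))

  x1 <- matrix(rnorm(5), 5, 1)
  hs1 <- encode(model, x1)
  h_l1 <- dcgru_step(x1, matrix(0, 5, 4), model$params$enc[[1]], model)
  h_l2 <- dcgru_step(h_l1, matrix(0, 5, 4), model$params$enc[[2]], model)
  expect_equal(hs1[[1]], h_l1, tolerance = 1e-12)
  expect_equal(hs1[[2]], h_l2, tolerance = 1e-12)
})

test_that("the full model is equivariant to node permutation", {
  withr::with_seed(31, a <- random_symmetric_adjacency(6))
  model <- tiny_model(adjacency = a, n = 6, order = 2, hidden = 4, seed = 5)
  perm <- c(3, 6, 1, 5, 2, 4)
  model_p <- model
  model_p$supports <- boldcast:::build_supports(
    transition_matrix(graph(a[perm, perm])))
  withr::with_seed(7, x <- matrix(rnorm(6 * 9), 6, 9))
  expect_equal(forecast(model_p, x[perm, ], 5), forecast(model, x, 5)[perm, ],
               tolerance = 1e-10)
})

test_that("decoder start, teacher forcing, and degenerate horizons behave as specified", {
  model <- tiny_model(n = 4, order = 1, hidden = 3, seed = 9)
  withr::with_seed(3, x <- matrix(rnorm(4 * 6), 4, 6))
  init <- encode(model, x)
  expect_equal(dim(decode(model, init, 0)), c(4, 0))

  z <- zero_params(model)
  expect_equal(decode(z, encode(z, x), 4), matrix(0, 4, 4))

  # with teacher forcing everywhere, step 1 equals the free-running step 1
  teach <- matrix(rnorm(4 * 4), 4, 4)
  p_free <- decode(model, init, 4)
  p_teach <- decode(model, init, 4, teacher = teach,
                    use_teacher = rep(TRUE, 3))
  expect_equal(p_free[, 1], p_teach[, 1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p_free[, 4], p_teach[, 4])))
  expect_error(decode(model, init, 4, use_teacher = rep(TRUE, 3)), "teacher")

  # purity: identical inputs give identical outputs
  expect_identical(forecast(model, x), forecast(model, x))
})

test_that("K = 0 predictions for one node ignore all other nodes", {
  model <- tiny_model(n = 5, order = 0, hidden = 4, seed = 13)
  withr::with_seed(4, {
    x <- matrix(rnorm(5 * 8), 5, 8)
    x2 <- x; x2[-2, ] <- rnorm(4 * 8)
  })
  expect_equal(forecast(model, x, 6)[2, ], forecast(model, x2, 6)[2, ],
               tolerance = 1e-12)
})

test_that("parameter count does not depend on the graph size", {
  m5 <- tiny_model(n = 5, order = 2, hidden = 6, seed = 1)
  m9 <- tiny_model(n = 9, order = 2, hidden = 6, seed = 1)
  expect_equal(n_params(m5), n_params(m9))
})

test_that("hidden states stay in [-1, 1] under repeated updates", {
  model <- tiny_model(n = 4, order = 1, hidden = 5, seed = 17)
  cell <- model$params$enc[[1]]
  withr::with_seed(6, {
    h <- matrix(runif(20, -1, 1), 4, 5)
    for (i in 1:50) {
      h <- dcgru_step(matrix(rnorm(4, sd = 3), 4, 1), h, cell, model)
      expect_true(all(abs(h) <= 1))
    }
  })
})

test_that("backpropagation yields finite gradients for every parameter", {
  model <- tiny_model(n = 5, order = 1, hidden = 4, seed = 23)
  withr::with_seed(8, {
    xs <- replicate(3, matrix(rnorm(5 * 6), 5, 6), simplify = FALSE)
    ys <- replicate(3, matrix(rnorm(5 * 4), 5, 4), simplify = FALSE)
  })
  res <- boldcast:::seq2seq_loss_grad_cpp(model$params, model$supports,
                                          model$order, xs, ys,
                                          c(TRUE, FALSE, TRUE))
  g <- boldcast:::flatten_params(res$grads)
  expect_length(g, n_params(model))
  expect_true(all(is.finite(g)))
  expect_gt(sum(abs(g)), 0)
})
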