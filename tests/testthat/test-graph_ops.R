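test_that("graph constructor enforces the structural-graph contract", {
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  g <- graph(a)
  expect_s3_class(g, "bc_graph")
  expect_equal(g$n_nodes, 2)

  expect_error(graph(matrix(1, 2, 3)), "square")
  expect_error(graph(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  expect_error(graph(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
  expect_error(graph(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
  # isolated node is a hard error naming the node
  a3 <- matrix(0, 3, 3); a3[1, 2] <- a3[2, 1] <- 1
  expect_error(graph(a3), "zero degree.*3")
})

test_that("transition matrix is the row-normalized adjacency", {
  expect_equal(transition_matrix(graph(matrix(c(0, 1, 1, 0), 2, 2)))$matrix,
               matrix(c(0, 1, 1, 0), 2, 2))
  # row normalization is scale invariant
  expect_equal(transition_matrix(graph(matrix(c(0, 2, 2, 0), 2, 2)))$matrix,
               matrix(c(0, 1, 1, 0), 2, 2))

  # brute-force row-division oracle on a random 5x5 graph
  withr::with_seed(5, {
    a <- random_symmetric_adjacency(5)
  })
  tm <- transition_matrix(graph(a))
  oracle <- a
  for (i in 1:5) for (j in 1:5) oracle[i, j] <- a[i, j] / sum(a[i, ])
  expect_equal(tm$matrix, oracle, tolerance = 1e-12)
  expect_true(all(abs(rowSums(tm$matrix) - 1) < 1e-10))
  expect_true(all(tm$matrix >= 0 & tm$matrix <= 1))
})

test_that("row-stochasticity is invariant under positive rescaling", {
  withr::with_seed(8, a <- random_symmetric_adjacency(6))
  for (s in c(0.01, 3, 1e4)) {
    expect_equal(transition_matrix(graph(s * a))$matrix,
                 transition_matrix(graph(a))$matrix, tolerance = 1e-12)
  }
})

test_that("random-walk Laplacian is I - T with zero row sums", {
  t2 <- transition_matrix(graph(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(random_walk_laplacian(t2), matrix(c(1, -1, -1, 1), 2, 2))
  withr::with_seed(3, a <- random_symmetric_adjacency(7))
  l <- random_walk_laplacian(transition_matrix(graph(a)))
  expect_true(all(abs(rowSums(l)) < 1e-10))
})

test_that("diffusion convolution: identity, one-hop swap, and linearity", {
  t2 <- transition_matrix(graph(matrix(c(0, 1, 1, 0), 2, 2)))
  x <- c(3, -2)
  expect_equal(diffusion_convolve(x, t2, diffusion_filter(1)), x)
  expect_equal(diffusion_convolve(x, t2, diffusion_filter(c(0, 1))),
               c(-2, 3))
  # linearity of the spectral reference
  g <- graph(matrix(c(0, 1, 1, 0), 2, 2))
  f <- diffusion_filter(c(0.3, 0.7))
  z <- c(1, 5)
  expect_equal(spectral_convolve(2 * x + 3 * z, g, f),
               2 * spectral_convolve(x, g, f) + 3 * spectral_convolve(z, g, f))
  expect_equal(spectral_convolve(x, g, diffusion_filter(0.4)), 0.4 * x)
})

test_that("diffusion convolution matches the spectral oracle on symmetric operators", {
  withr::with_seed(101, {
    worst <- 0
    for (trial in 1:100) {
      n <- sample(3:8, 1)
      k <- sample(0:4, 1)
      a <- random_symmetric_adjacency(n)
      g <- graph(a)
      f <- diffusion_filter(stats::rnorm(k + 1))
      x <- stats::rnorm(n)
      y_spec <- spectral_convolve(x, g, f)
      tm_sym <- transition_matrix(g, normalization = "sym")
      y_diff <- diffusion_convolve(x, tm_sym, f)
      worst <- max(worst, max(abs(y_spec - y_diff)))
    }
    expect_lt(worst, 1e-8)
  })
})

test_that("K = 0 filters scale per node and K = 1 output is local", {
  withr::with_seed(9, a <- random_symmetric_adjacency(6, density = 0.4))
  tm <- transition_matrix(graph(a))
  x <- rnorm(6)
  expect_equal(diffusion_convolve(x, tm, diffusion_filter(2.5)), 2.5 * x)

  # zeroing a non-neighbor's input leaves node i unchanged at K = 1
  f1 <- diffusion_filter(c(0.5, 0.5), theta_rev = 0.2)
  nonedge <- which(a == 0 & !diag(6), arr.ind = TRUE)[1, ]
  i <- nonedge[1]; j <- nonedge[2]
  x2 <- x; x2[j] <- 0
  y <- diffusion_convolve(x, tm, f1)
  y2 <- diffusion_convolve(x2, tm, f1)
  expect_equal(y[i], y2[i])
  expect_false(isTRUE(all.equal(y[j], y2[j])))
})

test_that("stationary distribution matches geometric sums and the power-iteration oracle", {
  withr::with_seed(12, a <- random_symmetric_adjacency(5))
  tm <- transition_matrix(graph(a))
  expect_equal(stationary_distribution(tm, 0.3, 0), 0.3 * diag(5))
  p1 <- stationary_distribution(tm, 0.5, 1)
  expect_equal(rowSums(p1), rep(0.75, 5))

  # power-iteration oracle: explicit term-by-term accumulation
  alpha <- 0.1; kmax <- 200
  pk <- diag(5); oracle <- alpha * diag(5)
  for (k in 1:kmax) {
    pk <- pk %*% tm$matrix
    oracle <- oracle + alpha * (1 - alpha)^k * pk
  }
  expect_equal(stationary_distribution(tm, alpha, kmax), oracle,
               tolerance = 1e-12)
  expect_error(stationary_distribution(tm, 1.2, 5), "alpha")
})
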