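# Small deterministic builders used across test files.

random_symmetric_adjacency <- function(n, density = 0.7) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  on <- up[stats::runif(length(up)) < density]
  a[on] <- stats::runif(length(on), 0.2, 2)
  a <- a + t(a)
  # guard against isolated nodes in tiny draws
  for (i in which(rowSums(a) == 0)) {
    j <- if (i == 1) 2 else 1
    a[i, j] <- a[j, i] <- 1
  }
  a
}

tiny_model <- function(n = 5, order = 1, hidden = 4, layers = 2, seed = 11,
                       include_reverse = TRUE, adjacency = NULL) {
  if (is.null(adjacency)) {
    adjacency <- withr::with_seed(seed, random_symmetric_adjacency(n))
  }
  tm <- transition_matrix(graph(adjacency), include_reverse = include_reverse)
  dcrnn(tm, order = order, hidden_size = hidden, n_layers = layers,
        seed = seed)
}

zero_params <- function(model) {
  flat <- boldcast:::flatten_params(model$params)
  model$params <- boldcast:::unflatten_params(0 * flat, model$params)
  model
}

sine_signal <- function(freq_hz, tr = 0.72, t_n = 2000, n = 1) {
  tt <- (seq_len(t_n) - 1) * tr
  graph_signal(matrix(rep(sin(2 * pi * freq_hz * tt), each = n), n, t_n,
                      byrow = FALSE), tr)
}
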