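#' Construct a structural connectivity graph
#'
#' Wraps a weighted, symmetric adjacency matrix (e.g. normalized streamline
#' counts between parcels from diffusion tractography) together with optional
#' region labels. The graph is undirected: diffusion imaging cannot resolve
#' the direction of a white-matter tract, so the adjacency must be symmetric.
#'
#' @param adjacency square numeric matrix with nonnegative entries. Small
#'   asymmetries (below `tol`) are symmetrized with a warning; larger ones are
#'   an error.
#' @param node_labels optional character vector of region identifiers, one per
#'   row of `adjacency`.
#' @param tol tolerance for the symmetry check.
#' @return an object of class `bc_graph` with elements `adjacency`,
#'   `n_nodes` and `node_labels`.
#' @export
graph <- function(adjacency, node_labels = NULL, tol = 1e-8) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square, got ", nrow(adjacency), " x ", ncol(adjacency))
  }
  if (anyNA(adjacency) || any(!is.finite(adjacency))) {
    stop("adjacency contains NA or non-finite entries")
  }
  if (any(adjacency < 0)) stop("adjacency entries must be nonnegative")
  asym <- max(abs(adjacency - t(adjacency)))
  if (asym > tol) {
    stop("adjacency is asymmetric beyond tolerance (max |A - t(A)| = ",
         signif(asym, 3), "); structural graphs are undirected")
  }
  if (asym > 0) {
    if (asym > .Machine$double.eps * 100) {
      warning("adjacency symmetrized (max asymmetry ", signif(asym, 3), ")")
    }
    adjacency <- (adjacency + t(adjacency)) / 2
  }
  deg <- rowSums(adjacency)
  if (any(deg == 0)) {
    bad <- which(deg == 0)
    lab <- if (!is.null(node_labels)) node_labels[bad] else bad
    stop("isolated node(s) with zero degree: ", paste(lab, collapse = ", "))
  }
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != nrow(adjacency)) {
      stop("node_labels length must equal the number of nodes")
    }
  }
  structure(
    list(adjacency = adjacency, n_nodes = nrow(adjacency),
         node_labels = node_labels),
    class = "bc_graph"
  )
}

#' @export
print.bc_graph <- function(x, ...) {
  cat("<bc_graph> ", x$n_nodes, " nodes, ",
      sum(x$adjacency[upper.tri(x$adjacency)] > 0), " undirected edges\n",
      sep = "")
  invisible(x)
}

#' Random-walk (or symmetric) transition operator of a graph
#'
#' Builds the state-transition matrix that drives diffusion convolution. In
#' the random-walk normalization `T = D^-1 A` with `D = diag(A 1)`, each row
#' gives the normalized edge strengths out of one region and sums to one. The
#' symmetric normalization `D^-1/2 A D^-1/2` shares `T`'s spectrum (the two
#' are similar matrices) and admits an orthonormal eigen-decomposition, which
#' the spectral convolution reference path requires.
#'
#' @param g a [graph()].
#' @param normalization `"rw"` (row-stochastic random walk, default) or
#'   `"sym"` (symmetric).
#' @param include_reverse should filters built on this operator also use the
#'   transposed walk direction? Stored as a flag; with `"rw"` the transpose is
#'   the reverse diffusion process.
#' @return object of class `bc_transition` with elements `matrix`, `degree`,
#'   `normalization`, `include_reverse`.
#' @export
transition_matrix <- function(g, normalization = c("rw", "sym"),
                              include_reverse = TRUE) {
  stopifnot(inherits(g, "bc_graph"))
  normalization <- match.arg(normalization)
  deg <- rowSums(g$adjacency)
  m <- if (normalization == "rw") {
    g$adjacency / deg
  } else {
    d <- 1 / sqrt(deg)
    (d * g$adjacency) %*% diag(d, nrow = g$n_nodes)
  }
  if (normalization == "rw") {
    stopifnot(max(abs(rowSums(m) - 1)) < 1e-10)
  }
  structure(
    list(matrix = m, degree = deg, normalization = normalization,
         include_reverse = include_reverse, node_labels = g$node_labels),
    class = "bc_transition"
  )
}

#' Random-walk graph Laplacian
#'
#' `L = I - T`, the Laplacian of the random walk defined by the transition
#' operator. Its rows sum to zero for a row-stochastic `T`.
#'
#' @param t a [transition_matrix()].
#' @return an `N x N` matrix.
#' @export
random_walk_laplacian <- function(t) {
  stopifnot(inherits(t, "bc_transition"))
  diag(nrow(t$matrix)) - t$matrix
}

#' Diffusion filter coefficients
#'
#' A graph filter is the truncated polynomial `sum_k theta_k T^k` in the
#' transition operator, optionally augmented with the reverse walk direction
#' `sum_k theta_rev_k (T')^k` (orders 1..K; order 0 is already covered by the
#' forward term).
#'
#' @param theta numeric vector of length `K + 1`; `theta[k + 1]` weights walk
#'   order `k`.
#' @param theta_rev optional numeric vector of length `K` weighting reverse
#'   walk orders `1..K`.
#' @return object of class `bc_filter` with elements `theta`, `theta_rev`,
#'   `order`.
#' @export
diffusion_filter <- function(theta, theta_rev = NULL) {
  theta <- as.numeric(theta)
  if (length(theta) < 1 || any(!is.finite(theta))) {
    stop("theta must be a non-empty finite numeric vector")
  }
  K <- length(theta) - 1L
  if (!is.null(theta_rev)) {
    theta_rev <- as.numeric(theta_rev)
    if (length(theta_rev) != K || any(!is.finite(theta_rev))) {
      stop("theta_rev must be finite and of length K = ", K)
    }
  }
  structure(list(theta = theta, theta_rev = theta_rev, order = K),
            class = "bc_filter")
}

#' Apply a diffusion convolution
#'
#' Computes `y = sum_{k=0}^{K} theta_k T^k x` (plus the reverse-direction sum
#' when the filter carries reverse coefficients) by iterated mat-vec products;
#' matrix powers are never materialized, so cost grows linearly in `K`.
#'
#' @param x numeric vector of length `N` or an `N x F` matrix (each column
#'   filtered independently).
#' @param t a [transition_matrix()].
#' @param f a [diffusion_filter()].
#' @return filtered signal with the shape of `x`.
#' @export
diffusion_convolve <- function(x, t, f) {
  stopifnot(inherits(t, "bc_transition"), inherits(f, "bc_filter"))
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) != nrow(t$matrix)) {
    stop("x has ", nrow(x), " rows but the graph has ", nrow(t$matrix), " nodes")
  }
  y <- f$theta[1] * x
  xk <- x
  for (k in seq_len(f$order)) {
    xk <- t$matrix %*% xk
    y <- y + f$theta[k + 1] * xk
  }
  if (!is.null(f$theta_rev)) {
    tm <- base::t(t$matrix)
    xk <- x
    for (k in seq_len(f$order)) {
      xk <- tm %*% xk
      y <- y + f$theta_rev[k] * xk
    }
  }
  y <- as.matrix(y)
  if (vec_in) drop(y) else y
}

#' Spectral graph convolution (reference path)
#'
#' Evaluates the same polynomial filter through the graph Fourier transform:
#' `y = U diag(sum_k theta_k lambda^k) U' x`, with `U, lambda` the
#' eigen-system of the symmetrically normalized operator
#' `D^-1/2 A D^-1/2`. The symmetric variant is used because the row-stochastic
#' walk matrix of a non-regular graph is not symmetric and need not admit an
#' orthonormal eigenbasis. Intended as an independent check of
#' [diffusion_convolve()] on symmetric operators, not as a production path.
#'
#' @param x numeric vector of length `N`.
#' @param g a [graph()].
#' @param f a [diffusion_filter()] (forward coefficients only).
#' @return numeric vector of length `N`.
#' @export
spectral_convolve <- function(x, g, f) {
  stopifnot(inherits(g, "bc_graph"), inherits(f, "bc_filter"))
  x <- as.numeric(x)
  d <- 1 / sqrt(rowSums(g$adjacency))
  s <- (d * g$adjacency) %*% diag(d, nrow = g$n_nodes)
  es <- eigen((s + base::t(s)) / 2, symmetric = TRUE)
  lam <- es$values
  gain <- rep(0, length(lam))
  for (k in 0:f$order) gain <- gain + f$theta[k + 1] * lam^k
  drop(es$vectors %*% (gain * crossprod(es$vectors, x)))
}

#' Approximate stationary distribution of the graph random walk
#'
#' Partial geometric sum `P = sum_{k=0}^{k_max} alpha (1-alpha)^k T^k`, the
#' finite-K approximation of the restart-walk stationary distribution. Row `i`
#' describes the diffusion proximity of every region to region `i`. This is a
#' diagnostic/interpretation utility; the restart probability `alpha` must be
#' supplied explicitly.
#'
#' @param t a [transition_matrix()].
#' @param alpha restart probability in `[0, 1]`.
#' @param k_max maximum walk order (>= 0).
#' @return an `N x N` matrix.
#' @export
stationary_distribution <- function(t, alpha, k_max) {
  stopifnot(inherits(t, "bc_transition"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  k_max <- as.integer(k_max)
  if (k_max < 0) stop("k_max must be >= 0")
  n <- nrow(t$matrix)
  p <- alpha * diag(n)
  tk <- diag(n)
  for (k in seq_len(k_max)) {
    tk <- tk %*% t$matrix
    p <- p + alpha * (1 - alpha)^k * tk
  }
  p
}
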