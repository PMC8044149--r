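#' Diffusion-convolutional recurrent sequence-to-sequence model
#'
#' Builds an encoder-decoder forecaster whose recurrent cells are gated
#' recurrent units with all dense multiplications replaced by diffusion
#' convolutions on the structural graph. The encoder consumes `t_p` past
#' activity frames, its final hidden states seed the decoder, and the decoder
#' emits `t_f` future frames, starting from a zero "GO" input and feeding back
#' its own predictions when run free. Filter parameters are polynomial
#' coefficients per walk order and direction, so the parameter count is
#' independent of the number of regions `N`.
#'
#' @param transition a [transition_matrix()]; its `include_reverse` flag
#'   decides whether filters also use the transposed walk direction.
#' @param order maximum walk order `K` of the diffusion filters (`K = 0`
#'   disables all cross-region mixing).
#' @param hidden_size hidden features `Q` per region (default 64).
#' @param n_layers stacked recurrent layers in encoder and decoder (default 2).
#' @param input_features features per region per timepoint (scalar BOLD: 1).
#' @param seed optional seed for the Glorot-uniform weight initialization.
#' @return object of class `bc_dcrnn`.
#' @export
dcrnn <- function(transition, order = 2, hidden_size = 64, n_layers = 2,
                  input_features = 1, seed = NULL) {
  stopifnot(inherits(transition, "bc_transition"))
  order <- as.integer(order)
  if (order < 0) stop("order K must be >= 0")
  q <- as.integer(hidden_size)
  supports <- build_supports(transition)
  ndir <- length(supports)
  nsup <- 1L + ndir * order
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  make_cell <- function(fin) {
    nr <- nsup * (fin + q)
    list(Wr = glorot(nr, q), Wu = glorot(nr, q), Wc = glorot(nr, q),
         br = rep(1, q), bu = rep(1, q), bc = rep(0, q))
  }
  init <- function() {
    feats <- c(input_features, rep(q, n_layers - 1))
    lapply(feats, make_cell)
  }
  params <- if (is.null(seed)) {
    list(enc = init(), dec = init(),
         w = drop(glorot(q, 1)), b = 0)
  } else {
    withr::with_seed(seed, list(enc = init(), dec = init(),
                                w = drop(glorot(q, 1)), b = 0))
  }
  structure(
    list(params = params, supports = supports, order = order,
         hidden_size = q, n_layers = as.integer(n_layers),
         input_features = as.integer(input_features),
         include_reverse = transition$include_reverse,
         normalization = transition$normalization,
         node_labels = transition$node_labels,
         n_nodes = nrow(transition$matrix)),
    class = "bc_dcrnn"
  )
}

# Sparse support matrices for the C++ kernels: the transition operator and,
# when requested, its transpose (the reverse diffusion direction).
build_supports <- function(transition) {
  m <- Matrix::Matrix(transition$matrix, sparse = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (isTRUE(transition$include_reverse)) list(m, Matrix::t(m)) else list(m)
}

#' @export
print.bc_dcrnn <- function(x, ...) {
  cat("<bc_dcrnn> N = ", x$n_nodes, ", K = ", x$order, ", Q = ",
      x$hidden_size, ", layers = ", x$n_layers,
      if (x$include_reverse) ", bidirectional walks" else "", "\n", sep = "")
  cat("  parameters: ", n_params(x), " (independent of N)\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [dcrnn()].
#' @return integer count.
#' @export
n_params <- function(model) {
  length(unlist(model$params))
}

#' Single DCGRU cell update
#'
#' One recurrent step: reset and update gates and the candidate state are each
#' computed by a diffusion convolution over the concatenation of the input
#' frame with the previous hidden state, and the hidden state is blended by
#' the update gate. Exposed mainly for inspection and testing; [encode()],
#' [decode()] and [forecast()] run whole sequences.
#'
#' @param x_t `N x F` input frame (a length-`N` vector is taken as `F = 1`).
#' @param h_prev `N x Q` previous hidden state.
#' @param cell parameter list with `Wr, Wu, Wc, br, bu, bc` (e.g.
#'   `model$params$enc[[1]]`).
#' @param model the owning [dcrnn()] (provides supports and walk order).
#' @return the new `N x Q` hidden state.
#' @export
dcgru_step <- function(x_t, h_prev, cell, model) {
  stopifnot(inherits(model, "bc_dcrnn"))
  x_t <- as.matrix(x_t)
  h_prev <- as.matrix(h_prev)
  out <- dcgru_cell_forward_cpp(x_t, h_prev, cell, model$supports, model$order)
  if (any(!is.finite(out))) stop("non-finite activations in DCGRU step")
  out
}

#' Run the encoder over an input window
#'
#' @param model a [dcrnn()].
#' @param inputs `N x t_p` matrix of past activity frames.
#' @return list of final `N x Q` hidden states, one per layer.
#' @export
encode <- function(model, inputs) {
  stopifnot(inherits(model, "bc_dcrnn"))
  inputs <- as.matrix(inputs)
  if (nrow(inputs) != model$n_nodes) {
    stop("inputs have ", nrow(inputs), " rows; model graph has ", model$n_nodes)
  }
  seq2seq_encode_cpp(model$params, model$supports, model$order, inputs)
}

#' Run the decoder from encoder states
#'
#' The first decoder input is always the zero GO frame. At step `t > 1` the
#' input is the ground-truth frame `teacher[, t - 1]` where
#' `use_teacher[t - 1]` is `TRUE`, and the model's own previous prediction
#' otherwise (the free-running mode used for validation and testing).
#'
#' @param model a [dcrnn()].
#' @param init list of hidden states from [encode()].
#' @param t_f number of frames to generate.
#' @param teacher optional `N x t_f` ground-truth sequence.
#' @param use_teacher logical vector of per-step teacher-forcing decisions
#'   (length `t_f - 1`); default all `FALSE` (free running).
#' @return `N x t_f` matrix of predictions.
#' @export
decode <- function(model, init, t_f, teacher = NULL,
                   use_teacher = rep(FALSE, max(t_f - 1, 0))) {
  stopifnot(inherits(model, "bc_dcrnn"))
  t_f <- as.integer(t_f)
  if (t_f == 0) return(matrix(0, model$n_nodes, 0))
  if (any(use_teacher) && is.null(teacher)) {
    stop("use_teacher requests ground truth but no teacher sequence given")
  }
  seq2seq_decode_cpp(model$params, model$supports, model$order, init, t_f,
                     if (is.null(teacher)) NULL else as.matrix(teacher),
                     as.logical(use_teacher))
}

#' Forecast future activity from a past window
#'
#' Encodes `t_p` observed frames and decodes `t_f` future frames fully
#' free-running (each decoder step feeds on the previous prediction).
#' Deterministic given the model parameters.
#'
#' @param model a [dcrnn()].
#' @param inputs `N x t_p` matrix of observed activity.
#' @param t_f forecast horizon in timepoints (defaults to `ncol(inputs)`).
#' @return `N x t_f` matrix of predicted activity.
#' @export
forecast <- function(model, inputs, t_f = ncol(inputs)) {
  decode(model, encode(model, inputs), t_f)
}
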