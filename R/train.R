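#' Scheduled-sampling probability
#'
#' Inverse-sigmoid curriculum decay: at global iteration `i` the decoder is
#' fed the ground-truth previous frame with probability
#' `eps_i = tau / (tau + exp(i / tau))`, which starts near 1, crosses 1/2 at
#' `i = tau * log(tau)`, and decays to 0, so training moves gradually from
#' teacher forcing to free running.
#'
#' @param iteration global mini-batch counter `i >= 0`.
#' @param tau decay constant `> 0` (default 5000).
#' @return probability in `(0, 1]`, vectorized over `iteration`.
#' @export
scheduled_sampling_prob <- function(iteration, tau = 5000) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  stopifnot(all(iteration >= 0))
  tau / (tau + exp(iteration / tau))
}

#' Mean absolute error
#'
#' Mean over all timepoints, regions (and samples, when given lists of equal
#' shape) of `|truth - prediction|` -- the training and evaluation objective.
#'
#' @param truth,pred numeric arrays of identical shape, or parallel lists of
#'   such arrays.
#' @return a single number.
#' @export
mae <- function(truth, pred) {
  if (is.list(truth)) {
    stopifnot(is.list(pred), length(truth) == length(pred))
    return(mean(purrr::map2_dbl(truth, pred, mae)))
  }
  truth <- as.array(truth); pred <- as.array(pred)
  if (!identical(dim(truth), dim(pred)) || length(truth) != length(pred)) {
    stop("truth and pred shapes differ")
  }
  mean(abs(truth - pred))
}

#' Training configuration
#'
#' Defaults follow the reference recipe: 70 epochs of Adam on mini-batches of
#' 32 with initial learning rate 0.1, decayed by 0.1 at epochs 20, 40 and 60
#' or after 10 epochs without validation improvement (restoring the
#' best-validation weights before every decay), scheduled sampling with
#' `tau = 5000`, and fine-tuning at learning rate 0.001.
#'
#' @param epochs,batch_size,lr_init,lr_decay,decay_epochs,plateau_patience
#'   training-loop controls (see description).
#' @param tau scheduled-sampling decay constant.
#' @param clip_norm global gradient-norm clip (stability guard for
#'   backpropagation through time).
#' @param finetune_lr initial learning rate used by [finetune_dcrnn()].
#' @param seed RNG seed for batch shuffling and sampling decisions.
#' @return a `bc_train_config` list.
#' @export
train_config <- function(epochs = 70, batch_size = 32, lr_init = 0.1,
                         lr_decay = 0.1, decay_epochs = c(20, 40, 60),
                         plateau_patience = 10, tau = 5000, clip_norm = 5,
                         finetune_lr = 0.001, seed = 1) {
  stopifnot(epochs >= 0, batch_size >= 1, lr_init > 0, lr_decay > 0,
            plateau_patience >= 1, tau > 0, clip_norm > 0, finetune_lr > 0,
            !is.unsorted(decay_epochs))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_decay = lr_decay,
                 decay_epochs = as.integer(decay_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 tau = tau, clip_norm = clip_norm,
                 finetune_lr = finetune_lr, seed = as.integer(seed)),
            class = "bc_train_config")
}

# Flat-vector view of the parameter pytree, for Adam updates.
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  utils::relist(flat, skeleton)
}

# Free-running predictions for a list of input windows, run in stacked
# batches (chunked to bound memory).
predict_samples <- function(model, inputs, t_f, chunk = 256L) {
  out <- vector("list", length(inputs))
  for (ch in split(seq_along(inputs), ceiling(seq_along(inputs) / chunk))) {
    out[ch] <- seq2seq_forecast_batch_cpp(model$params, model$supports,
                                          model$order, inputs[ch],
                                          as.integer(t_f))
  }
  out
}

#' Validation-set mean absolute error (free running)
#'
#' @param model a [dcrnn()].
#' @param data a split [bc_windows][windowize()] dataset.
#' @param split which partition to score.
#' @return a single MAE value.
#' @export
validation_mae <- function(model, data, split = "val") {
  s <- sample_list(data, split)
  if (length(s$inputs) == 0) stop("partition '", split, "' is empty")
  mae(s$targets, predict_samples(model, s$inputs, data$t_f))
}

#' Train the graph sequence-to-sequence forecaster
#'
#' Backpropagation-through-time with Adam, scheduled sampling (one Bernoulli
#' draw per decoder step per mini-batch, probability
#' [scheduled_sampling_prob()] at the global iteration counter), global
#' gradient-norm clipping, and an annealing learning rate. Before each decay
#' -- whether scheduled or triggered by a validation plateau -- the weights
#' with the lowest validation error seen so far are restored, and those best
#' weights are also what the returned model carries.
#'
#' @param model a [dcrnn()].
#' @param data a [windowize()]d and [split_samples()]d dataset with non-empty
#'   train and val partitions.
#' @param config a [train_config()].
#' @param phase label stored in the history (`"train"` or `"finetune"`).
#' @return object of class `bc_dcrnn_fit`: `model` (best-validation
#'   parameters), `history` tibble (epoch, lr, sampling probability,
#'   train/val MAE), `best_epoch`, `config`.
#' @export
train_dcrnn <- function(model, data, config = train_config(),
                        phase = "train") {
  stopifnot(inherits(model, "bc_dcrnn"), inherits(data, "bc_windows"),
            inherits(config, "bc_train_config"))
  train <- sample_list(data, "train")
  if (config$epochs > 0 && length(train$inputs) == 0) stop("train partition is empty")

  history <- tibble::tibble(epoch = integer(), phase = character(),
                            lr = numeric(), sampling_prob = numeric(),
                            train_mae = numeric(), val_mae = numeric())
  if (config$epochs == 0) {
    return(structure(list(model = model, history = history,
                          best_epoch = NA_integer_, config = config),
                     class = "bc_dcrnn_fit"))
  }

  flat <- flatten_params(model$params)
  adam_m <- adam_v <- numeric(length(flat))
  adam_t <- 0L
  lr <- config$lr_init
  iter <- 0L
  best_val <- Inf
  best_flat <- flat
  best_epoch <- NA_integer_
  since_best <- 0L

  withr::local_seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(train$inputs))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    eps_epoch <- scheduled_sampling_prob(iter, config$tau)
    for (b in batches) {
      eps <- scheduled_sampling_prob(iter, config$tau)
      use_teacher <- stats::runif(max(data$t_f - 1, 0)) < eps
      res <- seq2seq_loss_grad_cpp(model$params, model$supports, model$order,
                                   train$inputs[b], train$targets[b],
                                   use_teacher)
      if (!is.finite(res$loss)) {
        stop("training diverged at epoch ", epoch, " (loss = ", res$loss,
             "); lower the learning rate")
      }
      g <- flatten_params(res$grads)
      gn <- sqrt(sum(g^2))
      if (gn > config$clip_norm) g <- g * (config$clip_norm / gn)
      adam_t <- adam_t + 1L
      adam_m <- 0.9 * adam_m + 0.1 * g
      adam_v <- 0.999 * adam_v + 0.001 * g^2
      mhat <- adam_m / (1 - 0.9^adam_t)
      vhat <- adam_v / (1 - 0.999^adam_t)
      flat <- flatten_params(model$params) -
        lr * mhat / (sqrt(vhat) + 1e-8)
      model$params <- unflatten_params(flat, model$params)
      epoch_loss <- epoch_loss + res$loss * length(b)
      iter <- iter + 1L
    }
    val <- validation_mae(model, data)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, phase = phase, lr = lr, sampling_prob = eps_epoch,
      train_mae = epoch_loss / length(train$inputs), val_mae = val))
    if (val < best_val) {
      best_val <- val; best_flat <- flat; best_epoch <- epoch; since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    decay_now <- epoch %in% config$decay_epochs ||
      since_best >= config$plateau_patience
    if (decay_now && epoch < config$epochs) {
      model$params <- unflatten_params(best_flat, model$params)  # restore best
      lr <- lr * config$lr_decay
      since_best <- 0L
    }
  }
  model$params <- unflatten_params(best_flat, model$params)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 config = config),
            class = "bc_dcrnn_fit")
}

#' Fine-tune a pretrained forecaster on a new dataset
#'
#' Continues training from the pretrained weights at a reduced learning rate
#' (`config$finetune_lr`). Because filter parameters are independent of the
#' number of regions, the target dataset may live on a different graph of the
#' same feature dimensionality: pass `transition` to re-anchor the filters to
#' the new structural connectivity.
#'
#' @param pretrained a `bc_dcrnn_fit` or [dcrnn()].
#' @param data the (typically small) target dataset, windowed and split.
#' @param config a [train_config()]; `lr_init` is replaced by `finetune_lr`.
#' @param transition optional [transition_matrix()] of the target graph.
#' @return a `bc_dcrnn_fit` with history tagged `"finetune"`.
#' @export
finetune_dcrnn <- function(pretrained, data, config = train_config(),
                           transition = NULL) {
  model <- if (inherits(pretrained, "bc_dcrnn_fit")) pretrained$model else pretrained
  stopifnot(inherits(model, "bc_dcrnn"))
  if (!is.null(transition)) {
    stopifnot(inherits(transition, "bc_transition"))
    if (transition$include_reverse != model$include_reverse) {
      stop("architecture mismatch: include_reverse differs between model and graph")
    }
    model$supports <- build_supports(transition)
    model$n_nodes <- nrow(transition$matrix)
    model$node_labels <- transition$node_labels
  }
  config$lr_init <- config$finetune_lr
  train_dcrnn(model, data, config, phase = "finetune")
}

#' Forecasting error by horizon
#'
#' Free-running test error at each forecast step 1..`t_f`, averaged over
#' samples and regions, plus the overall mean (the mean of the per-horizon
#' values).
#'
#' @param model a [dcrnn()] or `bc_dcrnn_fit`.
#' @param data a split [bc_windows][windowize()] dataset.
#' @param split partition to evaluate (default `"test"`).
#' @return tibble with columns `horizon` and `mae`, carrying the overall mean
#'   as attribute `"overall_mae"`.
#' @export
evaluate_horizons <- function(model, data, split = "test") {
  if (inherits(model, "bc_dcrnn_fit")) model <- model$model
  s <- sample_list(data, split)
  if (length(s$inputs) == 0) stop("partition '", split, "' is empty")
  preds <- predict_samples(model, s$inputs, data$t_f)
  abs_err <- purrr::map2(s$targets, preds, ~ abs(.x - .y))
  per_h <- Reduce(`+`, lapply(abs_err, colMeans)) / length(abs_err)
  out <- tibble::tibble(horizon = seq_len(data$t_f), mae = per_h)
  attr(out, "overall_mae") <- mean(per_h)
  out
}
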