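#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained forecaster's history
#'
#' @param x a `bc_dcrnn_fit`.
#' @param ... unused.
#' @return the per-epoch history tibble (epoch, phase, learning rate,
#'   sampling probability, train/val MAE).
#' @export
tidy.bc_dcrnn_fit <- function(x, ...) x$history

#' One-row summary of a trained forecaster
#'
#' @param x a `bc_dcrnn_fit`.
#' @param ... unused.
#' @return tibble with epochs run, best epoch, best validation MAE, final
#'   learning rate, and parameter count.
#' @export
glance.bc_dcrnn_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mae = if (nrow(x$history)) min(x$history$val_mae) else NA_real_,
    final_lr = if (nrow(x$history)) x$history$lr[nrow(x$history)] else NA_real_,
    n_params = n_params(x$model))
}

#' Tidy VAR coefficients
#'
#' @param x a `bc_var`.
#' @param ... unused.
#' @return tibble with one row per coefficient: `lag`, `target`, `source`,
#'   `estimate` (lag 0 rows are the intercepts).
#' @export
tidy.bc_var <- function(x, ...) {
  n <- nrow(x$coeffs[[1]])
  lags <- purrr::map_dfr(seq_along(x$coeffs), function(l) {
    a <- x$coeffs[[l]]
    tibble::tibble(lag = l, target = rep(seq_len(n), n),
                   source = rep(seq_len(n), each = n),
                   estimate = as.vector(a))
  })
  dplyr::bind_rows(
    tibble::tibble(lag = 0L, target = seq_len(n), source = NA_integer_,
                   estimate = x$intercept),
    lags)
}

#' One-row summary of a VAR fit
#'
#' @param x a `bc_var`.
#' @param ... unused.
#' @export
glance.bc_var <- function(x, ...) {
  n <- nrow(x$coeffs[[1]])
  tibble::tibble(n_series = n, lag_order = x$lag_order, method = x$method,
                 n_coefficients = x$lag_order * n^2 + n)
}

#' Tidy an influence map
#'
#' @param x a `bc_influence`.
#' @param ... unused.
#' @return the influence tibble (region, influence, source flag, and the
#'   0-100 normalized column when present).
#' @export
tidy.bc_influence <- function(x, ...) x$influence

#' Plot training history
#'
#' Train and validation MAE per epoch, with the scheduled-sampling
#' probability as a secondary trace.
#'
#' @param object a `bc_dcrnn_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bc_dcrnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_mae", "val_mae"),
                           names_to = "set", values_to = "mae")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mae, color = .data$set)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sampling_prob *
                                      max(h$mae, na.rm = TRUE)),
                       linetype = "dotted", color = "grey40") +
    ggplot2::labs(y = "MAE (dotted: scaled sampling probability)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot forecasting error by horizon
#'
#' @param object the tibble from [evaluate_horizons()].
#' @param ... further horizon tibbles to overlay, named (e.g.
#'   `VAR = var_horizons`).
#' @return a ggplot.
#' @export
plot_horizons <- function(object, ...) {
  extra <- list(...)
  object$model <- if (length(extra)) "model" else NA_character_
  for (nm in names(extra)) {
    e <- extra[[nm]]
    e$model <- nm
    object <- dplyr::bind_rows(object, e)
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$horizon, y = .data$mae))
  p <- if (length(extra)) {
    p + ggplot2::geom_line(ggplot2::aes(color = .data$model))
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "forecast horizon (timepoints)", y = "test MAE") +
    ggplot2::theme_minimal()
}

#' Plot an influence map
#'
#' Bar chart of per-region influence of the perturbed sources, strongest
#' first; source regions are highlighted.
#'
#' @param object a `bc_influence`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bc_influence <- function(object, ...) {
  d <- dplyr::arrange(object$influence, .data$influence)
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$influence, y = .data$region,
                                  fill = .data$is_source)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30",
                                          `TRUE` = "firebrick"),
                               labels = c("target", "source"), name = NULL) +
    ggplot2::labs(x = "influence of perturbed source(s)", y = NULL) +
    ggplot2::theme_minimal()
}
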