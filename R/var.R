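#' Fit a vector autoregression by ordinary least squares
#'
#' The order-`P` VAR `x(t) = b + A_1 x(t-1) + ... + A_P x(t-P) + u(t)` fitted
#' equation-by-equation by least squares over all usable timepoints. With a
#' list of sessions, lagged designs never cross session boundaries.
#'
#' @param x a [graph_signal()], numeric `N x T` matrix, or list of either
#'   (sessions).
#' @param p lag order `P >= 1`.
#' @return object of class `bc_var` with `lag_order`, `coeffs` (list of
#'   `N x N` matrices `A_1..A_P`), `intercept`, `method`.
#' @export
var_fit_ols <- function(x, p) {
  p <- as.integer(p)
  stopifnot(p >= 1)
  sessions <- var_sessions(x)
  n <- nrow(sessions[[1]])
  design <- lapply(sessions, function(m) {
    T_s <- ncol(m)
    if (T_s <= p) stop("session too short for lag order ", p)
    rows <- (p + 1):T_s
    z <- do.call(cbind, lapply(1:p, function(l) t(m[, rows - l, drop = FALSE])))
    list(y = t(m[, rows, drop = FALSE]), z = cbind(1, z))
  })
  y <- do.call(rbind, lapply(design, `[[`, "y"))
  z <- do.call(rbind, lapply(design, `[[`, "z"))
  if (nrow(z) <= ncol(z)) {
    stop("not enough timepoints (", nrow(z), ") to identify ", ncol(z),
         " coefficients per equation")
  }
  qz <- qr(z)
  if (qz$rank < ncol(z)) stop("singular lagged design (rank ", qz$rank,
                              " < ", ncol(z), ")")
  beta <- qr.coef(qz, y)                    # (1 + N*P) x N
  coeffs <- lapply(1:p, function(l) {
    t(beta[1 + ((l - 1) * n + 1):(l * n), , drop = FALSE])
  })
  new_bc_var(p, coeffs, drop(beta[1, ]), "ols")
}

var_sessions <- function(x) {
  if (inherits(x, "bc_signal")) x <- list(x)
  if (!is.list(x)) x <- list(x)
  lapply(x, function(s) if (inherits(s, "bc_signal")) s$data else as.matrix(s))
}

new_bc_var <- function(p, coeffs, intercept, method) {
  stopifnot(all(vapply(coeffs, function(a) all(is.finite(a)), TRUE)))
  structure(list(lag_order = p, coeffs = coeffs, intercept = intercept,
                 method = method),
            class = "bc_var")
}

#' @export
print.bc_var <- function(x, ...) {
  n <- nrow(x$coeffs[[1]])
  cat("<bc_var> N = ", n, ", P = ", x$lag_order, " (", x$method, " fit), ",
      x$lag_order * n^2 + n, " coefficients\n", sep = "")
  invisible(x)
}

#' Fit a VAR by stochastic gradient descent on iterated forecasts
#'
#' Mirrors the recurrent model's objective: from each windowed sample the VAR
#' is rolled forward `t_f` steps feeding back its own predictions, and the
#' mean absolute error against the target window is minimized by SGD with
#' batch size 1 and an annealing learning rate (start 0.005, cut by 0.1 after
#' epochs 70 and 90 of 100 by default).
#'
#' @param data a [windowize()]d and split dataset; the train partition is
#'   used; input windows must span at least `p` timepoints.
#' @param p lag order.
#' @param lr,epochs,decay_epochs,lr_decay SGD schedule.
#' @param seed RNG seed for the per-epoch sample permutation.
#' @param init optional `bc_var` used as starting point (zero otherwise).
#' @return a `bc_var` with `method = "sgd"`.
#' @export
var_fit_sgd <- function(data, p, lr = 0.005, epochs = 100,
                        decay_epochs = c(70, 90), lr_decay = 0.1, seed = 1,
                        init = NULL) {
  stopifnot(inherits(data, "bc_windows"))
  p <- as.integer(p)
  if (p > data$t_p) stop("lag order ", p, " exceeds input window length ", data$t_p)
  train <- sample_list(data, "train")
  s <- length(train$inputs)
  if (s == 0) stop("train partition is empty")
  n <- nrow(train$inputs[[1]])
  a0 <- matrix(0, n, n * p); b0 <- numeric(n)
  if (!is.null(init)) {
    stopifnot(inherits(init, "bc_var"), init$lag_order == p)
    a0 <- do.call(cbind, init$coeffs)
    b0 <- init$intercept
  }
  if (epochs == 0) {
    return(new_bc_var(p, split_lag_blocks(a0, n, p), b0, "sgd"))
  }
  ord <- withr::with_seed(seed, {
    t(vapply(seq_len(epochs), function(e) sample.int(s), integer(s)))
  })
  sched <- lr * lr_decay^findInterval(seq_len(epochs) - 1, decay_epochs)
  fit <- var_sgd_fit_cpp(a0, b0, train$inputs, train$targets,
                         matrix(as.integer(ord), nrow = epochs), sched)
  new_bc_var(p, split_lag_blocks(fit$A, n, p), drop(fit$b), "sgd")
}

split_lag_blocks <- function(a, n, p) {
  lapply(1:p, function(l) a[, ((l - 1) * n + 1):(l * n), drop = FALSE])
}

#' Iterated VAR forecast
#'
#' One-step predictions fed back recursively for `t_f` steps from the last
#' `P` columns of the supplied history.
#'
#' @param m a `bc_var`.
#' @param history `N x (>= P)` matrix of observed activity.
#' @param t_f forecast horizon.
#' @return `N x t_f` matrix.
#' @export
var_forecast <- function(m, history, t_f) {
  stopifnot(inherits(m, "bc_var"))
  history <- as.matrix(history)
  if (ncol(history) < m$lag_order) {
    stop("history has ", ncol(history), " timepoints; lag order needs ",
         m$lag_order)
  }
  var_forecast_cpp(do.call(cbind, m$coeffs), m$intercept, history,
                   as.integer(t_f))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root against stationarity using the regression
#' `diff(x)_t = a + g x_{t-1} + sum_i d_i diff(x)_{t-i} + e_t` (constant, no
#' trend). The augmentation lag is chosen by AIC up to `max_lag` (default
#' `trunc((T - 1)^(1/3))`). P-values interpolate the Dickey-Fuller tau_mu
#' finite-sample table; statistics beyond the tabulated 1% / 99% quantiles
#' are reported as 0.001 / 0.999 (outside the table's resolution).
#'
#' @param x numeric time series of length >= 20.
#' @param max_lag maximum augmentation lag.
#' @return list with `statistic`, `p_value`, `lag`.
#' @export
adf_test <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  t_n <- length(x)
  if (t_n < 20) stop("need at least 20 observations, got ", t_n)
  if (stats::sd(x) < .Machine$double.eps * 100) stop("constant series")
  if (is.null(max_lag)) max_lag <- trunc((t_n - 1)^(1 / 3))
  dx <- diff(x)
  fit_one <- function(k) {
    rows <- (k + 1):length(dx)
    z <- cbind(1, x[rows])                     # x_{t-1}
    if (k > 0) {
      z <- cbind(z, vapply(1:k, function(i) dx[rows - i], numeric(length(rows))))
    }
    y <- dx[rows]
    qz <- qr(z)
    beta <- qr.coef(qz, y)
    res <- y - z %*% beta
    sig2 <- sum(res^2) / (length(y) - ncol(z))
    se <- sqrt(diag(chol2inv(qr.R(qz))) * sig2)
    list(stat = beta[2] / se[2],
         aic = length(y) * log(sum(res^2) / length(y)) + 2 * ncol(z))
  }
  fits <- lapply(0:max_lag, fit_one)
  best <- which.min(vapply(fits, `[[`, numeric(1), "aic"))
  stat <- fits[[best]]$stat
  list(statistic = stat, p_value = adf_pvalue(stat, t_n), lag = best - 1L)
}

# Dickey-Fuller tau_mu table (constant, no trend), interpolated in both the
# statistic and the sample size, as is conventional for table-based p-values.
adf_pvalue <- function(stat, n) {
  tbl <- rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37,  0.00,  0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23, 0.60))
  sizes <- c(25, 50, 100, 250, 500, 1e9)
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  row <- vapply(seq_along(probs), function(j) {
    stats::approx(sizes, tbl[, j], xout = min(n, 1e9), rule = 2)$y
  }, numeric(1))
  if (stat < row[1]) return(0.001)
  if (stat > row[length(row)]) return(0.999)
  stats::approx(row, probs, xout = stat)$y
}

#' Stationarity screen for regional time courses
#'
#' Applies [adf_test()] to every region and reports which rows fail to reject
#' a unit root at level `alpha`. The screen is reported, not enforced: fits
#' proceed regardless, but the nonstationary fraction is part of the fit's
#' bookkeeping.
#'
#' @param x a [graph_signal()] (or `N x T` matrix).
#' @param alpha rejection level (default 0.01).
#' @return tibble with columns `region`, `statistic`, `p_value`, `lag`,
#'   `stationary`; the nonstationary fraction is attribute
#'   `"frac_nonstationary"`.
#' @export
adf_gate <- function(x, alpha = 0.01) {
  m <- if (inherits(x, "bc_signal")) x$data else as.matrix(x)
  labels <- if (inherits(x, "bc_signal") && !is.null(x$region_labels)) {
    x$region_labels
  } else {
    as.character(seq_len(nrow(m)))
  }
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    a <- adf_test(m[i, ])
    tibble::tibble(region = labels[i], statistic = a$statistic,
                   p_value = a$p_value, lag = a$lag,
                   stationary = a$p_value < alpha)
  })
  attr(res, "frac_nonstationary") <- mean(!res$stationary)
  res
}
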