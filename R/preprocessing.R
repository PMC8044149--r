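#' Regional activity time series
#'
#' Container for an `N x T` matrix of parcel-averaged activity (rows =
#' regions, columns = timepoints) sampled at a fixed repetition time.
#'
#' @param data numeric `N x T` matrix, finite, `T >= 2`.
#' @param tr_seconds sampling interval in seconds (e.g. 0.72 for HCP rs-fMRI).
#' @param region_labels optional character vector, one label per row.
#' @return object of class `bc_signal`.
#' @export
graph_signal <- function(data, tr_seconds, region_labels = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("signal matrix contains NA or non-finite values")
  }
  if (ncol(data) < 2) stop("need at least 2 timepoints, got ", ncol(data))
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be a positive number")
  }
  if (!is.null(region_labels) && length(region_labels) != nrow(data)) {
    stop("region_labels length must equal the number of rows")
  }
  structure(list(data = data, tr_seconds = tr_seconds,
                 region_labels = region_labels),
            class = "bc_signal")
}

#' @export
print.bc_signal <- function(x, ...) {
  cat("<bc_signal> ", nrow(x$data), " regions x ", ncol(x$data),
      " timepoints, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Filters every regional time course identically with a Butterworth
#' band-pass applied forward and backward (`signal::filtfilt`), so the output
#' has no phase shift. The default narrow band 0.04-0.07 Hz isolates the
#' low-frequency range commonly taken as functionally relevant gray-matter
#' BOLD fluctuation. Each output row is demeaned (DC lies outside any
#' passband).
#'
#' @param x a [graph_signal()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 * tr_seconds)`.
#' @param order Butterworth design order (default 5).
#' @return a filtered [graph_signal()].
#' @export
bandpass_filter <- function(x, low_hz = 0.04, high_hz = 0.07, order = 5) {
  stopifnot(inherits(x, "bc_signal"))
  nyq <- 1 / (2 * x$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band must satisfy 0 < low < high < Nyquist (", signif(nyq, 4), " Hz)")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  t_n <- ncol(x$data)
  # demean and reflect-pad before the forward-backward pass: filtfilt carries
  # no initial-condition estimate, so an unpadded step at the record edges
  # would ring far into the series
  pad <- min(t_n - 1, 200L)
  out <- t(apply(x$data, 1, function(row) {
    row <- row - mean(row)
    padded <- c(rev(row[seq_len(pad)]), row,
                rev(row[seq(t_n - pad + 1, t_n)]))
    signal::filtfilt(bf, padded)[(pad + 1):(pad + t_n)]
  }))
  out <- out - rowMeans(out)
  graph_signal(out, x$tr_seconds, x$region_labels)
}

#' Global signal regression
#'
#' Regresses every regional time course on the across-region mean time course
#' (with intercept) and keeps the residuals, removing global modulations so
#' that local interactions dominate. Each residual row is orthogonal to the
#' global signal.
#'
#' @param x a [graph_signal()] with at least 2 regions.
#' @return a [graph_signal()] of residuals.
#' @export
global_signal_regression <- function(x) {
  stopifnot(inherits(x, "bc_signal"))
  if (nrow(x$data) < 2) stop("global signal regression needs N >= 2 regions")
  g <- colMeans(x$data)
  if (stats::sd(g) < .Machine$double.eps * 100) {
    stop("global signal is constant; regression design is degenerate")
  }
  z <- cbind(1, g)                       # T x 2 design
  beta <- solve(crossprod(z), crossprod(z, t(x$data)))
  resid <- t(x$data) - z %*% beta
  graph_signal(t(resid), x$tr_seconds, x$region_labels)
}

#' Scale a session
#'
#' `minmax01` maps the session-wide minimum to 0 and maximum to 1 (the
#' model-input scaling); `zscore` maps the pooled values to mean 0, sd 1 (the
#' reporting scale). Scaling parameters are attached so the transform can be
#' inverted; the mean of the scaled data is stored as well since it is the
#' neutral value used when silencing a region's input.
#'
#' @param x a [graph_signal()] with non-constant data.
#' @param mode `"minmax01"` or `"zscore"`.
#' @return a scaled [graph_signal()] carrying a `"scaling"` attribute.
#' @export
scale_session <- function(x, mode = c("minmax01", "zscore")) {
  stopifnot(inherits(x, "bc_signal"))
  mode <- match.arg(mode)
  v <- x$data
  if (max(v) - min(v) < .Machine$double.eps * 100) {
    stop("cannot scale a constant session")
  }
  if (mode == "minmax01") {
    pars <- list(mode = mode, min = min(v), max = max(v))
    out <- (v - pars$min) / (pars$max - pars$min)
  } else {
    pars <- list(mode = mode, mean = mean(v), sd = stats::sd(as.vector(v)))
    out <- (v - pars$mean) / pars$sd
  }
  pars$scaled_mean <- mean(out)
  res <- graph_signal(out, x$tr_seconds, x$region_labels)
  attr(res, "scaling") <- pars
  res
}

#' Invert [scale_session()]
#'
#' @param x a scaled [graph_signal()] (or plain matrix).
#' @param scaling the scaling parameter list; taken from `attr(x, "scaling")`
#'   when omitted.
#' @return a [graph_signal()] on the original scale.
#' @export
unscale_session <- function(x, scaling = attr(x, "scaling")) {
  if (is.null(scaling)) stop("no scaling parameters available")
  v <- if (inherits(x, "bc_signal")) x$data else as.matrix(x)
  out <- if (scaling$mode == "minmax01") {
    v * (scaling$max - scaling$min) + scaling$min
  } else {
    v * scaling$sd + scaling$mean
  }
  if (inherits(x, "bc_signal")) {
    graph_signal(out, x$tr_seconds, x$region_labels)
  } else {
    out
  }
}

#' Slide forecasting windows over one or more sessions
#'
#' Every position `t` yields an input window of `t_p` consecutive timepoints
#' and the immediately following `t_f`-timepoint target, giving exactly
#' `T - t_p - t_f + 1` input-output pairs per session.
#'
#' @param sessions a [graph_signal()] or a list of them (one per scanning
#'   session).
#' @param t_p,t_f input and target window lengths.
#' @return object of class `bc_windows`: the session matrices, the window
#'   lengths, and a tibble `index` with one row per sample (columns `sample`,
#'   `session`, `start`, `split`).
#' @export
windowize <- function(sessions, t_p, t_f) {
  if (inherits(sessions, "bc_signal")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1, all(vapply(sessions, inherits, TRUE, "bc_signal")))
  t_p <- as.integer(t_p); t_f <- as.integer(t_f)
  stopifnot(t_p >= 1, t_f >= 1)
  idx <- purrr::map_dfr(seq_along(sessions), function(s) {
    T_s <- ncol(sessions[[s]]$data)
    n <- T_s - t_p - t_f + 1L
    if (n < 1) {
      stop("session ", s, " has T = ", T_s, " < t_p + t_f = ", t_p + t_f)
    }
    tibble::tibble(session = s, start = seq_len(n))
  })
  idx <- dplyr::mutate(idx, sample = dplyr::row_number(),
                       split = NA_character_, .before = 1)
  structure(
    list(sessions = lapply(sessions, `[[`, "data"),
         tr_seconds = sessions[[1]]$tr_seconds,
         t_p = t_p, t_f = t_f, index = idx),
    class = "bc_windows"
  )
}

#' @export
print.bc_windows <- function(x, ...) {
  cat("<bc_windows> ", nrow(x$index), " samples (", length(x$sessions),
      " session(s)), t_p = ", x$t_p, ", t_f = ", x$t_f, "\n", sep = "")
  if (!all(is.na(x$index$split))) {
    print(dplyr::count(x$index, .data$split))
  }
  invisible(x)
}

#' Chronological train/validation/test split
#'
#' Within each session, the first `floor(f_train * S)` window samples become
#' training data, the next `floor(f_val * S)` validation, and the following
#' `floor(f_test * S)` test data, preserving temporal order. Any remainder
#' after the three floored blocks is marked `"unused"`; this flooring rule is
#' what makes 1141 samples per session yield exactly 114 test samples.
#'
#' Because consecutive windows overlap, samples adjacent to a boundary share
#' timepoints with the other side. The default reproduces that design
#' (leakage identical for all compared models); `gap = TRUE` additionally
#' marks the first `t_p + t_f` samples of the validation and test blocks
#' `"unused"`, making the evaluation leakage-free at the cost of some
#' samples.
#'
#' @param ds a [windowize()]d dataset.
#' @param fractions length-3 numeric summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param gap drop boundary-straddling validation/test samples.
#' @return `ds` with the `split` column filled in.
#' @export
split_samples <- function(ds, fractions = c(0.8, 0.1, 0.1), gap = FALSE) {
  stopifnot(inherits(ds, "bc_windows"), length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  gap_n <- if (gap) ds$t_p + ds$t_f else 0L
  ds$index <- ds$index |>
    dplyr::group_by(.data$session) |>
    dplyr::mutate(split = {
      s <- dplyr::n()
      sizes <- floor(fractions * s)
      if (any(sizes <= gap_n)) {
        stop("a split partition is empty (", s, " samples in session)")
      }
      lab <- rep(c("train", "val", "test", "unused"),
                 c(sizes, s - sum(sizes)))
      if (gap_n > 0) {
        for (part in c("val", "test")) {
          lab[which(lab == part)[seq_len(gap_n)]] <- "unused"
        }
      }
      lab
    }) |>
    dplyr::ungroup()
  ds
}

#' Extract one input/target pair
#'
#' @param ds a `bc_windows` dataset.
#' @param i sample number (row of `ds$index`).
#' @return list with `input` (`N x t_p`) and `target` (`N x t_f`) matrices.
#' @export
get_sample <- function(ds, i) {
  stopifnot(inherits(ds, "bc_windows"))
  row <- ds$index[i, ]
  m <- ds$sessions[[row$session]]
  a <- row$start
  list(input = m[, a:(a + ds$t_p - 1), drop = FALSE],
       target = m[, (a + ds$t_p):(a + ds$t_p + ds$t_f - 1), drop = FALSE])
}

#' Materialize all samples of one split
#'
#' @param ds a `bc_windows` dataset.
#' @param split one of `"train"`, `"val"`, `"test"`, or `NULL` for all.
#' @return list with parallel lists `inputs` and `targets`.
#' @export
sample_list <- function(ds, split = NULL) {
  stopifnot(inherits(ds, "bc_windows"))
  ids <- if (is.null(split)) ds$index$sample else {
    ds$index$sample[!is.na(ds$index$split) & ds$index$split == split]
  }
  pairs <- lapply(ids, function(i) get_sample(ds, i))
  list(inputs = lapply(pairs, `[[`, "input"),
       targets = lapply(pairs, `[[`, "target"))
}
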