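#' Silence source regions in an input window
#'
#' Replaces the rows of the chosen source regions by the mean of the data
#' distribution -- 0 for z-scored data, or the stored scaled-session mean for
#' min-max scaled data -- removing all information those regions carry while
#' leaving every other row untouched.
#'
#' @param sample `N x t_p` input window.
#' @param sources integer indices (or labels, when `labels` given) of one or
#'   more regions to perturb jointly.
#' @param value replacement value (default 0, the z-scored mean).
#' @param labels optional region labels used to resolve character `sources`.
#' @return the perturbed `N x t_p` matrix.
#' @export
perturb_inputs <- function(sample, sources, value = 0, labels = NULL) {
  sample <- as.matrix(sample)
  sources <- resolve_sources(sources, nrow(sample), labels)
  sample[sources, ] <- value
  sample
}

resolve_sources <- function(sources, n, labels = NULL) {
  if (length(sources) == 0) stop("source set must not be empty")
  if (is.character(sources)) {
    if (is.null(labels)) stop("character sources need region labels")
    idx <- match(sources, labels)
    if (anyNA(idx)) stop("unknown region(s): ",
                         paste(sources[is.na(idx)], collapse = ", "))
    sources <- idx
  }
  sources <- unique(as.integer(sources))
  if (any(sources < 1 | sources > n)) stop("source index out of range 1..", n)
  sources
}

#' Perturbation-based causal influence of source regions
#'
#' For each sample the model forecasts once from the clean input and once
#' from the input with the source regions silenced; the influence of the
#' sources on region `n` is the mean absolute difference of the two forecasts
#' in that region, averaged over forecast steps and samples:
#' `I_n = (1/S) sum_s (1/T_f) sum_t |xhat_n(t) - xhat'_n(t)|`. A large value
#' means the past of the sources carries information the model uses to
#' predict `n`'s future -- a directed, Granger-style dependency read out of
#' the trained forecaster.
#'
#' @param model a trained [dcrnn()] or `bc_dcrnn_fit`.
#' @param samples list of `N x t_p` input windows (typically the test
#'   partition, via [sample_list()]), or a `bc_windows` dataset (its test
#'   split is used).
#' @param sources region indices or labels perturbed jointly.
#' @param t_f forecast horizon (defaults to the dataset's, else `t_p`).
#' @param perturb_value replacement value for the silenced rows.
#' @return object of class `bc_influence`: a tibble `influence` (columns
#'   `region`, `influence`, `is_source`) plus `sources` and `n_samples`.
#' @export
influence_map <- function(model, samples, sources, t_f = NULL,
                          perturb_value = 0) {
  if (inherits(model, "bc_dcrnn_fit")) model <- model$model
  stopifnot(inherits(model, "bc_dcrnn"))
  if (inherits(samples, "bc_windows")) {
    if (is.null(t_f)) t_f <- samples$t_f
    samples <- sample_list(samples, "test")$inputs
  }
  stopifnot(length(samples) >= 1)
  if (is.null(t_f)) t_f <- ncol(samples[[1]])
  src <- resolve_sources(sources, model$n_nodes, model$node_labels)
  clean <- predict_samples(model, samples, t_f)
  if (any(!vapply(clean, function(p) all(is.finite(p)), TRUE))) {
    stop("model produced non-finite forecasts")
  }
  pert <- predict_samples(
    model, lapply(samples, perturb_inputs, sources = src,
                  value = perturb_value), t_f)
  infl <- Reduce(`+`, purrr::map2(clean, pert, ~ rowMeans(abs(.x - .y)))) /
    length(samples)
  labels <- model$node_labels %||% as.character(seq_len(model$n_nodes))
  structure(
    list(influence = tibble::tibble(
           region = labels, influence = infl,
           is_source = seq_along(infl) %in% src),
         sources = src, n_samples = length(samples)),
    class = "bc_influence"
  )
}

#' @export
print.bc_influence <- function(x, ...) {
  cat("<bc_influence> sources {", paste(x$sources, collapse = ", "),
      "} over ", x$n_samples, " samples\n", sep = "")
  print(dplyr::arrange(x$influence, dplyr::desc(.data$influence)), n = 5)
  invisible(x)
}

#' Rescale an influence map to 0-100
#'
#' Affine rescaling of the influence vector so its minimum maps to 0 and its
#' maximum to 100 (the conventional display scale). By default the source
#' regions' self-influence is excluded from the scale -- self-influence
#' conflates self-prediction with causal effect and would otherwise dominate
#' -- and their normalized entries are set to `NA`.
#'
#' @param m a [influence_map()] result.
#' @param exclude_sources drop sources from the scaling (default `TRUE`).
#' @return `m` with a `normalized` column added.
#' @export
normalize_influence <- function(m, exclude_sources = TRUE) {
  stopifnot(inherits(m, "bc_influence"))
  v <- m$influence$influence
  keep <- if (exclude_sources) !m$influence$is_source else rep(TRUE, length(v))
  rng <- range(v[keep])
  if (diff(rng) < .Machine$double.eps * 100) {
    stop("influence vector is constant; nothing to normalize")
  }
  norm <- (v - rng[1]) / diff(rng) * 100
  norm[!keep] <- NA_real_
  m$influence$normalized <- norm
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Directed-edge recovery score of an influence analysis
#'
#' Computes influence maps for every region in turn, ranks all ordered region
#' pairs `(source -> target)` by influence, and scores how well the ranking
#' separates a set of known directed couplings from the remaining pairs (the
#' area under the ROC curve of planted vs non-planted pairs). A permutation
#' null -- reassigning the planted labels to random pairs -- gives the
#' chance-level reference.
#'
#' @param model trained [dcrnn()] or fit.
#' @param samples input windows or `bc_windows` (test split).
#' @param coupling `N x N` matrix; nonzero `[i, j]` marks a planted coupling
#'   `j -> i`.
#' @param n_perm permutation-null draws (default 200).
#' @param t_f forecast horizon.
#' @return list with `auc`, `null_q95`, `null_auc` (vector), and the pairs
#'   tibble.
#' @export
edge_recovery <- function(model, samples, coupling, n_perm = 200, t_f = NULL) {
  if (inherits(model, "bc_dcrnn_fit")) model <- model$model
  n <- model$n_nodes
  stopifnot(nrow(coupling) == n, ncol(coupling) == n)
  score <- matrix(NA_real_, n, n)  # [target, source]
  for (j in seq_len(n)) {
    im <- influence_map(model, samples, j, t_f = t_f)
    score[, j] <- im$influence$influence
  }
  off <- which(diag(n) == 0)
  pairs <- tibble::tibble(
    target = row(score)[off], source = col(score)[off],
    influence = score[off],
    planted = coupling[off] != 0)
  if (!any(pairs$planted) || all(pairs$planted)) {
    stop("coupling must mark some but not all off-diagonal pairs")
  }
  auc_of <- function(lab) {
    r <- rank(pairs$influence)
    n1 <- sum(lab); n0 <- sum(!lab)
    (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(pairs$planted)
  null_auc <- vapply(seq_len(n_perm), function(i) auc_of(sample(pairs$planted)),
                     numeric(1))
  list(auc = auc, null_q95 = stats::quantile(null_auc, 0.95, names = FALSE),
       null_auc = null_auc, pairs = pairs)
}
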