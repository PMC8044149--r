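# Desk-scale benchmark drivers on the synthetic generator.  These reproduce,
# at fixture scale, the study's qualitative comparisons: the value of spatial
# modeling (walk order K), the recurrent model vs the linear VAR baseline,
# directed-edge recovery from influence maps, and transfer across graphs.

#' Prepare a windowed fixture dataset
#'
#' Generates a synthetic dataset, min-max scales each session, windows and
#' splits it chronologically.
#'
#' @param cfg a [sim_config()].
#' @param t_p,t_f window lengths (fixture default 10/10).
#' @return list with `graph`, `truth`, `windows` (split `bc_windows`),
#'   `scaled` session list.
#' @export
fixture_dataset <- function(cfg = sim_config(), t_p = 10, t_f = 10) {
  data <- simulate_dataset(cfg)
  scaled <- lapply(data$sessions, scale_session, mode = "minmax01")
  ds <- split_samples(windowize(scaled, t_p, t_f))
  list(graph = data$graph, truth = data$truth, windows = ds, scaled = scaled)
}

#' Fixture-scale training configuration
#'
#' The benchmark runs are much smaller than a full imaging study (about a
#' thousand mini-batches instead of hundreds of thousands), so the curriculum
#' constant and learning rate are scaled to the run length: `tau = 40` puts
#' the scheduled-sampling midpoint `tau * log(tau) ~ 148` iterations inside a
#' 30-epoch run, mirroring the shape of the full-scale schedule, and Adam
#' starts at 0.01.
#'
#' @param epochs training epochs (default 30).
#' @param seed RNG seed.
#' @param ... overrides passed to [train_config()].
#' @return a [train_config()].
#' @export
fixture_train_config <- function(epochs = 30, seed = 1, ...) {
  train_config(epochs = epochs, lr_init = 0.01, tau = 40,
               decay_epochs = c(20, 40, 60), seed = seed, ...)
}

#' Spatial-modeling ablation against the VAR baseline
#'
#' For one generator seed: trains the graph-recurrent forecaster with walk
#' order `K = 1` and with `K = 0` (no cross-region mixing), fits the VAR
#' baseline by SGD on the identical windowed samples, and reports the
#' free-running test MAE of all three. With planted directed couplings the
#' expectation is `K = 1` < `K = 0` and `K = 1` < VAR.
#'
#' @param seed generator and training seed.
#' @param epochs training epochs per model.
#' @param hidden_size hidden features per region.
#' @param var_lag VAR lag order (defaults to the input window length).
#' @param cfg generator configuration ([sim_config()] with this `seed`).
#' @param t_p,t_f window lengths.
#' @return list with `mae` (named numeric: k1, k0, var), the fitted `k1`
#'   model, `dataset`, and per-model horizon tibbles.
#' @export
spatial_ablation_run <- function(seed, epochs = 30, hidden_size = 16,
                                 var_lag = NULL, cfg = sim_config(seed = seed),
                                 t_p = 10, t_f = 10) {
  fx <- fixture_dataset(cfg, t_p, t_f)
  tcfg <- fixture_train_config(epochs = epochs, seed = seed)
  tm <- transition_matrix(fx$graph)
  fit1 <- train_dcrnn(dcrnn(tm, order = 1, hidden_size = hidden_size,
                            seed = seed), fx$windows, tcfg)
  fit0 <- train_dcrnn(dcrnn(tm, order = 0, hidden_size = hidden_size,
                            seed = seed), fx$windows, tcfg)
  if (is.null(var_lag)) var_lag <- t_p
  vfit <- var_fit_sgd(fx$windows, var_lag, seed = seed)
  test <- sample_list(fx$windows, "test")
  vpred <- lapply(test$inputs, var_forecast, m = vfit, t_f = t_f)
  hz1 <- evaluate_horizons(fit1, fx$windows)
  hz0 <- evaluate_horizons(fit0, fx$windows)
  list(mae = c(k1 = attr(hz1, "overall_mae"),
               k0 = attr(hz0, "overall_mae"),
               var = mae(test$targets, vpred)),
       k1 = fit1, k0 = fit0, var = vfit, dataset = fx,
       horizons = list(k1 = hz1, k0 = hz0))
}

#' Directed-edge recovery from a trained fixture model
#'
#' Runs [edge_recovery()] on a trained run: influence maps for every region
#' as source, AUC of planted couplings vs non-edges, and the shuffled-label
#' null.
#'
#' @param run result of [spatial_ablation_run()].
#' @param n_samples number of test windows used (subsampled for speed).
#' @param n_perm permutation draws for the null.
#' @param seed seed for the subsample and permutations.
#' @return the [edge_recovery()] list.
#' @export
edge_recovery_run <- function(run, n_samples = 60, n_perm = 200, seed = 1) {
  test <- sample_list(run$dataset$windows, "test")$inputs
  withr::local_seed(seed)
  if (length(test) > n_samples) test <- test[sample(length(test), n_samples)]
  edge_recovery(run$k1, test, run$dataset$truth$coupling, n_perm = n_perm,
                t_f = run$dataset$windows$t_f)
}

#' Transfer-learning experiment across generator graphs
#'
#' Pretrains on one generator draw (or reuses a supplied pretrained fit),
#' then compares fine-tuning at the reduced learning rate on a second,
#' data-poor draw against training from scratch on that draw with the same
#' epoch budget.
#'
#' @param seed seed of the data-poor target draw.
#' @param pretrained a `bc_dcrnn_fit` from a source-graph run (e.g.
#'   `spatial_ablation_run(seed)$k1`); if `NULL`, one is trained.
#' @param epochs fine-tune / from-scratch epoch budget.
#' @param target_cfg generator config of the target dataset (default: one
#'   short session from an independent seed).
#' @param hidden_size hidden features per region.
#' @param t_p,t_f window lengths.
#' @return list with `mae` (named: finetune, scratch) and both fits.
#' @export
transfer_run <- function(seed, pretrained = NULL, epochs = 20,
                         target_cfg = sim_config(seed = seed + 500L,
                                                 n_sessions = 1,
                                                 n_timepoints = 200),
                         hidden_size = 16, t_p = 10, t_f = 10) {
  if (is.null(pretrained)) {
    src <- fixture_dataset(sim_config(seed = seed), t_p, t_f)
    tm_src <- transition_matrix(src$graph)
    pretrained <- train_dcrnn(dcrnn(tm_src, order = 1,
                                    hidden_size = hidden_size, seed = seed),
                              src$windows, fixture_train_config(seed = seed))
  }
  tgt <- fixture_dataset(target_cfg, t_p, t_f)
  tm <- transition_matrix(tgt$graph)
  ft <- finetune_dcrnn(pretrained, tgt$windows,
                       fixture_train_config(epochs = epochs, seed = seed),
                       transition = tm)
  hs <- if (inherits(pretrained, "bc_dcrnn_fit")) {
    pretrained$model$hidden_size
  } else {
    pretrained$hidden_size
  }
  scratch <- train_dcrnn(dcrnn(tm, order = 1, hidden_size = hs, seed = seed),
                         tgt$windows,
                         fixture_train_config(epochs = epochs, seed = seed))
  hz_ft <- evaluate_horizons(ft, tgt$windows)
  hz_sc <- evaluate_horizons(scratch, tgt$windows)
  list(mae = c(finetune = attr(hz_ft, "overall_mae"),
               scratch = attr(hz_sc, "overall_mae")),
       finetune = ft, scratch = scratch, dataset = tgt)
}
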