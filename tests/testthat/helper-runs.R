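# Benchmark runs on the synthetic fixture are expensive (tens of seconds per
# seed), so they are computed lazily and shared across test files.

.bc_run_cache <- new.env(parent = emptyenv())

ablation_run_cached <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.bc_run_cache[[key]])) {
    .bc_run_cache[[key]] <- spatial_ablation_run(seed, epochs = 30)
  }
  .bc_run_cache[[key]]
}

# A single small trained model for tests that need *a* trained forecaster
# but not the full benchmark (short run on a small draw).
small_trained_fit <- function() {
  if (is.null(.bc_run_cache$small_fit)) {
    cfg <- sim_config(n_nodes = 8, n_sessions = 1, n_timepoints = 300,
                      seed = 21)
    fx <- fixture_dataset(cfg, t_p = 8, t_f = 8)
    model <- dcrnn(transition_matrix(fx$graph), order = 1, hidden_size = 8,
                   seed = 21)
    .bc_run_cache$small_fit <- list(
      fit = train_dcrnn(model, fx$windows,
                        fixture_train_config(epochs = 6, seed = 21)),
      fx = fx, model0 = model)
  }
  .bc_run_cache$small_fit
}
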