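# boldcast

Forecasting regional brain activity on the anatomical network, and reading
directed (causal) connectivity out of the trained forecaster.

## What problem this solves

Functional MRI gives temporally resolved but undirected pictures of brain
activity; diffusion tractography gives the static anatomical wiring. This
package is for researchers who want to join the two: it models
parcel-averaged BOLD time series `X` (N regions × T timepoints) as signals
on the structural connectivity graph `A_w`, trains a sequence-to-sequence
forecaster whose spatial operations are constrained to anatomical
connections, and then uses perturbation analysis of the trained model as a
Granger-style measure of directed influence between regions.

The core model is a **diffusion-convolutional gated recurrent encoder–
decoder**. Spatial structure enters through graph filters that are
polynomials in the random-walk transition operator `T = D⁻¹A_w`,

    y = Σ_{k=0..K} θ_k Tᵏ x  +  Σ_{k=1..K} θ'_k (Tᵀ)ᵏ x,

evaluated by iterated sparse products (cost linear in the walk order K).
Temporal structure enters through GRU cells whose matrix multiplications are
replaced by these filters:

    r = σ(Θ_r ⋆ [x, H] + b_r)        u = σ(Θ_u ⋆ [x, H] + b_u)
    c = tanh(Θ_c ⋆ [x, r⊙H] + b_c)   H' = u⊙H + (1−u)⊙c

An encoder consumes `T_p` past frames; a decoder emits `T_f` future frames,
trained with scheduled sampling (teacher-forcing probability
`ε_i = τ/(τ + exp(i/τ))` at iteration `i`) under a mean-absolute-error
objective, and always free-running at test time. Filter parameters are
shared across regions, so the parameter count is independent of N and a
pretrained model can be fine-tuned on a different graph (transfer learning).

Around the model: the standard preprocessing chain (0.04–0.07 Hz zero-phase
band-pass, global signal regression, session scaling, sliding windows,
chronological 80/10/10 splits), a VAR baseline with OLS and SGD fits plus an
augmented Dickey–Fuller stationarity screen, perturbation-based influence
maps with directed-edge recovery scoring, and a synthetic generator of
graph-coupled band-limited signals with planted directed couplings that
gives every claim a ground truth.

## Worked example

Generate a synthetic dataset with known directed couplings, train the
forecaster, compare walk orders against the VAR baseline, and recover the
planted directions:

```r
library(boldcast)

run <- spatial_ablation_run(seed = 3, epochs = 30)
round(run$mae, 4)
#>     k1     k0    var
#> 0.0125 0.0138 0.0352
```

Free-running test MAE (min-max scaled units, 10-step horizon): the graph
model with one-hop diffusion filters (`k1`) beats both the same model with
all spatial mixing removed (`k0`, here by ~9%) and the lag-10 VAR fitted by
SGD on the identical windows (`var`, by ~64%) — the value of anatomy and of
nonlinearity, respectively.

```r
er <- edge_recovery_run(run, seed = 3)
round(c(auc = er$auc, null_q95 = er$null_q95), 3)
#>      auc null_q95
#>    0.916    0.631
```

Ranking ordered region pairs by the influence measure `I_i(j)` — how much
silencing region `j`'s input changes the forecast for region `i` — separates
the planted directed couplings from non-couplings with AUC 0.92, far above
the 95th percentile of the label-permutation null.

```r
tr <- transfer_run(seed = 3, pretrained = run$k1)
round(tr$mae, 4)
#> finetune  scratch
#>   0.0190   0.0843
```

Fine-tuning the pretrained model at learning rate 0.001 on an independent,
data-poor draw (one 200-timepoint session) beats from-scratch training with
the same epoch budget by a wide margin.

Fitted objects follow broom/ggplot2 conventions: `tidy(run$k1)` is the
per-epoch training history, `glance(run$k1)` a one-row summary,
`autoplot(run$k1)` the learning curves, `plot_horizons(...)` the
MAE-by-horizon comparison, and `autoplot(influence_map(...))` the influence
profile of a chosen source region.

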