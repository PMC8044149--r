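---
title: "Graph-constrained forecasting of regional brain activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-constrained forecasting of regional brain activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldcast)
```

## The problem

Resting-state fMRI yields, after parcellation, a matrix $X \in \mathbb{R}^{N
\times T}$ of regional BOLD time courses; diffusion tractography yields a
weighted, symmetric structural adjacency $A_w \in \mathbb{R}^{N \times N}$
between the same $N$ regions. `boldcast` treats the regional signals as a
time-varying graph signal on the anatomical network and asks how well the
future activity of every region can be forecast from the recent past of the
whole network — and, once a forecaster is trained, which regions' pasts carry
information about which regions' futures. That second question is a
Granger-style notion of *directed functional (causal) connectivity*: if
silencing region $n'$'s input degrades the forecast of region $n$, the model
has learned a dependency $n' \to n$.

## Spatial model: diffusion convolution

Information flow on the graph is modeled as a random walk with transition
matrix $T = D^{-1} A_w$, $D = \mathrm{diag}(A_w \mathbf{1})$, whose rows are
normalized edge strengths. A graph filter is a truncated polynomial in the
walk operator,
$$ y = \sum_{k=0}^{K} \theta_k T^k x \;+\; \sum_{k=1}^{K} \theta'_k (T^\top)^k x, $$
where the transposed term carries the reverse diffusion direction (on by
default, configurable). `diffusion_convolve()` evaluates this by iterated
sparse products — never by forming $T^k$ — so cost grows linearly in $K$ and
the filter at $K = 1$ touches only a node's graph neighbours. `K = 0`
degenerates to per-node scaling with no spatial mixing at all, which is the
ablation used throughout to quantify the value of anatomy.

Two normalizations are supported. The row-stochastic walk matrix of a
non-regular graph is *not* symmetric, so it need not admit an orthonormal
eigenbasis; the spectral reference path (`spectral_convolve()`) therefore
uses the symmetrized operator $D^{-1/2} A_w D^{-1/2}$, which is similar to
$T$ (same spectrum) and is the operator on which the
polynomial-filter-equals-spectral-filter identity
$y = U\,\mathrm{diag}(\sum_k \theta_k \lambda^k)\,U^\top x$ is tested to
$10^{-8}$. The trained model uses row normalization by default, with `"sym"`
available; the polynomial path needs no decomposition either way.

`stationary_distribution()` implements the restart-walk partial sum
$P = \sum_{k \le K} \alpha (1-\alpha)^k T^k$ as a diagnostic of diffusion
proximity; no default $\alpha$ is imposed because none is canonical — it
must be supplied.

## Temporal model: the DCGRU encoder–decoder

A DCGRU is a gated recurrent unit whose dense multiplications are replaced by
diffusion convolutions over the concatenation $[x(t), H(t-1)]$:
$$ r = \sigma(\Theta_r \star [x, H] + b_r), \quad
   u = \sigma(\Theta_u \star [x, H] + b_u), $$
$$ c = \tanh(\Theta_c \star [x, r \odot H] + b_c), \quad
   H' = u \odot H + (1-u) \odot c. $$
Filter parameters are shared across nodes, so the parameter count is
independent of $N$ — a model trained on one graph can be re-anchored to
another (`finetune_dcrnn(transition = ...)`).

The forecaster (`dcrnn()`) stacks two DCGRU layers in an encoder and two in
a decoder. The encoder consumes $T_p$ frames; its final hidden states seed
the decoder, whose first input is a zero "GO" frame and which, in validation
and test, always feeds back its own previous prediction (free running). The
output is a per-node linear projection $\mathbb{R}^Q \to \mathbb{R}$ of the
top layer's hidden state, shared across nodes — the natural choice that
preserves permutation equivariance where the published architecture family
leaves the readout unspecified. Hidden states are initialized at zero; weights use
Glorot-uniform initialization; gate biases start at 1 so early training
favours memory retention.

## Training

Training minimizes the mean absolute error of the decoded sequence by
backpropagation through time with Adam, mini-batches of 32, gradient-norm
clipping at 5 (BPTT through 60 steps can spike; the clip is configurable),
and an annealing learning rate: start 0.1, cut by 0.1 at epochs 20/40/60 of
70 or after 10 epochs without validation improvement, restoring the
best-validation weights before *every* cut and returning them at the end.

*Scheduled sampling.* During training the decoder receives the ground-truth
previous frame with probability $\epsilon_i = \tau / (\tau + e^{i/\tau})$ at
global mini-batch $i$ (one Bernoulli draw per decoder step per batch). The
curriculum starts at teacher forcing and crosses $1/2$ at $i = \tau \ln
\tau$; with the reference $\tau = 5000$ that midpoint sits inside a
multi-hundred-thousand-iteration run. Note the inverse-sigmoid form: the
decay must run from $\approx 1$ to $0$ as iterations grow, which pins the
denominator to $\tau + e^{i/\tau}$.

*Scaling.* Sessions are min-max scaled to $[0,1]$ for model input; a pooled
z-scoring mode is provided for reporting, and both transforms store their
parameters for exact inversion. Reported MAEs are in the units of whichever
scaling produced the windows being evaluated.

Implementation note: the forward and backward passes are written in C++
(RcppArmadillo), with a mini-batch stacked as one block-diagonal graph —
samples occupy disconnected components, so the math is unchanged while the
many small products become a few large ones. Gradient correctness is pinned
by central finite differences and by an independently coded scalar GRU
oracle in the tests.

## The VAR baseline and stationarity screen

The linear baseline is an order-$P$ vector autoregression
$x(t) = b + \sum_{p=1}^{P} A_p x(t-p) + u(t)$ with two fits:
equation-by-equation OLS on session time courses, and an SGD fit (batch 1,
learning rate 0.005 cut by 0.1 after epochs 70 and 90 of 100) that minimizes
the *iterated* multi-step forecast MAE on exactly the windowed samples the
recurrent model trains on. The iterated objective was chosen over one-step
fitting because both models are evaluated on iterated forecasts; it is also
the variant that performs better, and the one used in benchmark comparisons.
Multi-step evaluation always feeds predictions back recursively
(`var_forecast()`).

On strongly band-limited signals the lagged OLS design can be numerically
rank-deficient at high lag orders (nearby lags of a narrowband series are
almost collinear); this is reported as an explicit error rather than
silently regularized, and the SGD fit — which has no such failure mode — is
the default baseline in the synthetic benchmark at lag $P = 10$.

An augmented Dickey–Fuller screen (`adf_gate()`, constant term, AIC-chosen
augmentation lag, tau-table p-values) reports the fraction of regional
series that fail to reject a unit root at $\alpha = 0.01$; the screen is
advisory — fits proceed regardless, with the fraction kept as bookkeeping.

## Causal connectivity by perturbation

For sources $n'$ (one region or several jointly), `influence_map()` replaces
the source rows of each input window with the mean of the data distribution
— 0 in z-scored units, the stored scaled-session mean under min-max scaling
— forecasts from clean and perturbed inputs, and averages the absolute
forecast difference per target region over forecast steps and samples:
$$ I_n(n') = \frac{1}{S} \sum_s \frac{1}{T_f} \sum_t
   \bigl| \hat{x}_n^{(s)}(t) - \hat{x}_n'^{(s)}(t) \bigr|. $$
The test partition is the default sample set. Influence maps are normalized
to $[0, 100]$ for display *after* any averaging, with source self-entries
excluded from the scale by default (self-influence conflates
self-prediction with causal effect and would dominate the range).
`edge_recovery()` turns the all-sources influence matrix into a ranking of
ordered region pairs and scores planted directed couplings by AUC against a
label-permutation null.

## The synthetic generator

Real multi-modal MRI benchmarks are not desk-reproducible, so every claim
the package tests is grounded in a generator with known answers:
a connected weighted random graph (edge probability `graph_density`, weights
uniform on 0.5–1.5), a directed coupling matrix supported on its edges (each
edge coupled in one random direction), and dynamics
$$ x(t) = \tanh\!\bigl(\, s\, C\, x(t-\ell) + d\, x(t-1) \bigr) + \eta(t),
   \qquad \eta \sim \mathcal{N}(0, \sigma^2), $$
band-pass filtered to 0.04–0.07 Hz at TR = 0.72 s — the narrowband regime
conventional for gray-matter BOLD. The tanh makes couplings genuinely
nonlinear, which is what gives the recurrent model a representational edge
over the linear VAR.

Defaults ($N = 10$, 3 sessions of $T = 500$, lag $\ell = 2$, coupling gain
$s = 2$, self-memory $d = 0.4$, noise $\sigma = 0.2$) were set once, with
one consideration dominating: after narrowband filtering a region's own past
is already highly predictive, so couplings must be the dominant dynamical
term for the planted structure to be expressed in the data at all — a weak
coupling would leave the $K=1$ and $K=0$ models statistically
indistinguishable and the generator useless as ground truth. What the
generator does *not* emulate: hemodynamic convolution, measurement-level
(post-dynamics) noise, inter-subject variability, and the $\sim$36-fold
larger graphs of a whole-cortex parcellation. Passing benchmarks therefore
demonstrate that the pipeline recovers planted nonlinear lagged structure at
desk scale, not that it would do so on any particular empirical dataset.

## Windowing, splits, and leakage

Windows of $T_p$ inputs and $T_f$ targets slide by one timepoint, giving
$T - T_p - T_f + 1$ pairs per session; per session the first
$\lfloor 0.8 S \rfloor$ are training, the next $\lfloor 0.1 S \rfloor$
validation, the next $\lfloor 0.1 S \rfloor$ test, in temporal order, any
remainder unused. This flooring rule reproduces the canonical full-scale counts (1141
windows from $T = 1200$ at $T_p = T_f = 30$, of which exactly 114 are test;
540 test samples from ten $T = 600$ sessions). Consecutive overlapping
windows share timepoints across the split boundaries — a deliberate
reproduction of the reference design; evaluations are therefore of
short-horizon dynamics learned from the same session, not of
cross-session generalization. The split is deterministic, so the leakage is
identical for every model compared and does not favour one over another.

## Desk-scale benchmark choices

The bundled benchmark (`spatial_ablation_run()`, `edge_recovery_run()`,
`transfer_run()`) runs the full pipeline — generate, filter, scale, window,
train $K \in \{0, 1\}$, fit the VAR, evaluate free-running test MAE,
influence maps, transfer — in about a minute per seed on one CPU. Its scale
parameters are package choices, stated here once: windows $T_p = T_f = 10$
(the coupling lag 2 sits comfortably inside), hidden size $Q = 16$, 30
epochs, Adam at 0.01, VAR lag $P = 10$, and scheduled-sampling $\tau = 40$.
The last is the one parameter that *must* scale with run length: the
curriculum midpoint $\tau \ln \tau \approx 148$ mini-batches falls early in
a $\sim$1100-iteration run, mirroring where the reference $\tau = 5000$
midpoint falls in a $\sim 2 \times 10^5$-iteration run; keeping $\tau =
5000$ at desk scale would mean the decoder never trains free-running.
The transfer experiment reuses a trained benchmark model as the pretrained
source, fine-tunes at learning rate 0.001 on an independent, data-poor draw
(one session of 200 timepoints), and compares against from-scratch training
with the identical epoch budget.

## Numerical choices and degenerate inputs

* Zero-phase band-pass: order-5 Butterworth applied forward–backward.
  `signal::filtfilt` carries no initial-condition estimate, so rows are
  demeaned and reflect-padded (200 samples) before filtering; a constant
  row maps exactly to zero.
* Global signal regression solves the two-column normal equations directly
  and errors on a constant global signal.
* Isolated graph nodes are a hard error, not a silent self-loop — a
  self-loop would change $K = 1$ locality semantics.
* Asymmetric adjacencies are symmetrized below $10^{-8}$ (with a warning
  above exact zero) and rejected beyond.
* Min-max and z-score scaling refuse constant sessions; influence
  normalization refuses constant influence vectors.
* ADF p-values outside the tau-table range are truncated to 0.001/0.999;
  the table has no finer resolution there.
* Training aborts with a diagnostic on non-finite loss rather than
  continuing from a poisoned state.
* All file writes are temp-file-plus-rename, so interrupted runs never
  leave truncated outputs.

## Known limitations

Forecast skill on the synthetic benchmark is measured in min-max scaled
units and is not numerically comparable to errors on empirical data in
other units or at other graph sizes. The influence measure quantifies the
trained model's input–output sensitivity; it indicates, but does not
establish, causal mechanism — and it inherits any bias of the model,
including the tendency of graph-convolutional filters to spread sensitivity
along anatomical edges even when no dynamical coupling exists (the test
suite checks that *direction* discrimination, which that bias cannot
produce, stays at chance under zero coupling). Statistical comparison of
influence maps across subjects, surface rendering, and hemodynamic forward
modeling are out of scope.
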