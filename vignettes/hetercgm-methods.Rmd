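---
title: "Multi-patient CGM forecasting with hetercgm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-patient CGM forecasting with hetercgm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous glucose monitoring (CGM) sensors record blood glucose at a fixed
cadence (here 15 minutes). In a clinical cohort, the records form a
*heterogeneous* collection of time series: every patient is monitored for a
different duration, start and end times do not line up, and type 1 (T1DM) and
type 2 (T2DM) patients show markedly different volatility. A model that
forecasts all patients *simultaneously* must deal with three things at once:
unequal lengths, cross-patient correlation, and per-patient scale differences.

`hetercgm` implements a full pipeline for this setting:

1. **Alignment** — per-record min–max normalization, sliding-window
   segmentation, and *subsequence repetition* (SSR) to equalize the number of
   training windows per patient without truncating or padding.
2. **Relation graph** — pairwise dynamic time warping (DTW) distances between
   the raw (unequal-length) normalized records, a directed top-K
   nearest-neighbour adjacency, and the symmetric normalization
   $P = \tilde M^{-1/2}\tilde A \tilde M^{-1/2}$ used by graph convolutions.
3. **HETER network** — two stacked graph convolution (GCN) layers, a
   convolution filter along the patient axis, temporal attention, a GRU
   recurrent component over the attended window, and an output head whose
   nonlinear part is fused with a purely linear map of the input
   ($O = R_o + W_o X + b_o$).
4. **Training and evaluation** — Adam on an MSE loss in normalized units;
   MAE/MAPE/RMSE and Pearson correlation on de-normalized mg/dL predictions
   of the held-out most recent 36 h (144 points) per patient.

## Alignment

Each record $D^{(n)}$ is normalized by its own min and max
($\tilde D^{(n)} = (D^{(n)} - \min)/(\max - \min)$), and the parameters are
kept to invert predictions back to mg/dL. Normalization statistics are
computed **on the training portion only** and reused for the test tail; the
alternative (normalizing with full-record statistics) leaks future range
information into training. Constant records have no defined scale and are
rejected rather than silently mapped to zero.

Windows of `T` inputs and `s` targets slide with stride 1 (the maximally
overlapping choice, configurable), giving $B^{(n)} = L_n - T - s + 1$ pairs
per record. SSR then replicates each record's windows cyclically from the
first one until every record has $\beta = \max_n B^{(n)}$ windows: aligned
window $b$ is source window $((b-1) \bmod B^{(n)}) + 1$. Replication re-uses
real data, so — unlike zero padding — no artificial values enter the training
distribution, and — unlike truncation — no data are discarded. Whether the
replication should restart from the first window or repeat a trailing block
is not fully settled in the method's description; cyclic-from-first is
implemented as the plain reading of "sequentially replicated". Both baselines
are provided: `pad_align()` fills with all-zero windows (zero being the
conventional "artificial data" value), `tra_align()` cuts every record to
$\min_n B^{(n)}$ windows keeping the most recent ones (recency being the
forecasting-relevant end).

The test split reserves the trailing `test_points` observations of every
record as targets; the test series is prefixed with the last `T` training
points so that every test target has a complete input window. Test windows
therefore overlap training *inputs* but never training *targets*.

## The relation graph

DTW distance is the classic dynamic program with absolute-difference local
cost and step set {(1,0), (0,1), (1,1)}, computed on the normalized training
portions (distances on raw mg/dL would be dominated by level differences).
No Sakoe–Chiba band is applied by default, matching the method; a band is
available for long records. DTW is a semi-metric — symmetric, non-negative,
zero on identical inputs — but violates the triangle inequality, which is why
the test suite never asserts it. The hot loop is in C++ (`src/dtw.cpp`); an
independent pure-R memoized recursion serves as the oracle in the tests.

Each patient keeps directed edges to its `K` DTW-nearest neighbours (ties
broken by ascending node index so builds are reproducible). The adjacency is
binary by default; Gaussian-kernel distance weights are available as an
option since the formal definition only requires $A_{i,j} > 0$ on edges.
Self-loops are added on top of the `K` neighbours ($\tilde A = A + I$), and
the propagation matrix normalizes by node degree. The printed dimensions of
the degree matrix in the source description ($\tilde M \in
\mathbb{R}^{T\times T}$) cannot multiply an $N$-node adjacency; node-degree
normalization is the only dimensionally consistent reading and is what this
package implements.

## The HETER network

For a batch of aligned windows ($b \times N \times T$):

* **Graph module**: $R_g^{(1)} = P X W_g^{(1)} + b_g$, then
  $R_g^{(2)} = P\,\mathrm{Dropout}(\mathrm{ReLU}(R_g^{(1)}), p_g)\,W_g^{(2)}$.
  The second layer carries no bias (none is printed for it). Its output width
  is set back to `T` so the downstream temporal modules see a window of `T`
  steps; the original description does not state layer widths (its appendix
  is not available), so this is the package's own choice and the
  dimensionally simplest one.
* **Spatial convolution**: `conv_channels` filters of odd width
  `conv_kernel` slide along the *patient* axis with zero same-padding,
  followed by ReLU and dropout. Because the downstream attention and GRU need
  an $N \times T$ tensor, a learned $1\times1$ combination vector folds the
  channel axis back. With one channel and an identity kernel the component
  reduces exactly to `ReLU`, which the tests pin down.
* **Temporal attention**: a two-layer MLP over the time axis followed by a
  softmax *along time*, so each (window, patient) row is a probability
  distribution over the `T` steps. The softmax axis is chosen to match the
  component's stated purpose — highlighting key time steps within a period.
* **GRU**: the attended representation $R_{co} \odot S_{ta}$ feeds a GRU one
  scalar per patient and step, all patients sharing the cell parameters. The
  candidate activation is **sigmoid by default** because that is what the
  method prints, even though conventional GRUs use tanh; `heter_config(
  candidate_activation = "tanh")` switches to the convention. With a sigmoid
  candidate the hidden state stays in $(0,1)$, which is harmless here since
  targets are min–max normalized.
* **Output head**: a temporal MLP maps the final hidden state to the `s`
  horizon steps and a spatial MLP mixes across patients (both single hidden
  layer by default; depth is not specified in the source description).
  The result is added to the linear map $W_o X + b_o$ ($W_o: T \to s$).
  Zeroing the MLP weights reduces the whole network *exactly* to this linear
  model — a property the acceptance tests verify bit-for-bit — and it is why
  gradients cannot vanish entirely: the linear path is always one affine map
  away from the loss.

### A note on permutation equivariance

With a convolution of kernel width > 1 along the patient axis, the network is
*not* equivariant to re-ordering patients: the kernel couples patients that
happen to be adjacent in the node ordering. This is an inherent property of
the published architecture, not an implementation artifact. The test suite
verifies permutation consistency in the `conv_kernel = 1` configuration,
where the convolution is pointwise and equivariance holds exactly.

## Training

Adam minimizes the MSE between normalized predictions and targets over
shuffled mini-batches of aligned windows. All gradients are analytic
(hand-derived reverse mode, `R/heter-backprop.R`) and verified against
central differences in the test suite to 5e-4 relative tolerance. Training is
bit-deterministic given the seed: initialization, shuffling and dropout all
draw from one seeded stream.

Defaults: learning rate 0.03, batch size 16, 50 epochs, Xavier-uniform
initialization, dropout 0.2 on all three sites. The learning rate and batch
size were chosen by the package's own small grid search on synthetic
cohorts (the original protocol likewise tuned per-method hyperparameters by
grid search); network widths (GCN 64, 32 conv channels, GRU 64, MLP 16)
follow common practice for networks of this size since the source's
hyperparameter appendix is unavailable.

Grid search holds out the last 10% of training windows as a validation set
(no validation protocol is described in the source; a chronological tail is
the leakage-safe choice) and selects by validation MAE, first-in-order on
ties. Horizons are specified in minutes and converted to steps by exact
division by the resolution (15/30/60 min → 1/2/4 steps at 15-min cadence).

## The synthetic cohort generator

No hospital data ship with this package. `simulate_cohort()` emulates the
*structure* of the motivating two-hospital cohort so every stage is testable
offline: a small T1DM group and a large T2DM group (defaults 12 + 100),
record lengths drawn uniformly from 247–1339 points at 15-min resolution,
and per-type volatility with T2DM noisier than T1DM. Each trace is

* a per-patient baseline (Normal around 120 mg/dL for T1DM-like, 150 for
  T2DM-like records — simulator conventions, not claims about the disease),
* a 24-hour circadian sinusoid (96 steps at 15-min resolution, random phase,
  amplitude 10–30 mg/dL),
* postprandial spikes at Poisson times (default 3/day) with exponential
  decay (sharp rise, 1–2 h fall), matching the morphology of real CGM traces,
* AR(1) noise (coefficient 0.8) with type-specific innovation scale
  (defaults 6 mg/dL T1DM, 12 mg/dL T2DM), plus a slow random-walk drift for
  T2DM only,
* clipping to the 40–400 mg/dL sensor range.

What a green test on this generator does **not** establish: physiological
fidelity (no insulin–glucose dynamics, no meals tied to clock time, no sensor
dropout or calibration artifacts), nor the absolute error levels reported on
real hospital data. The generator's role is to provide a world with learnable
structure and realistic heterogeneity in which the pipeline's properties —
alignment invariants, graph correctness, gradient correctness, and "learning
beats persistence" — can be checked.

## Numerical choices and degenerate inputs

* Constant records → error at normalization (no defined scale).
* Records shorter than `T + s` → segmentation error; shorter than
  `test_points + T + s` → split error.
* MAPE errors on zero actuals by default; an explicit `eps` guard is opt-in.
  Glucose is bounded away from zero (sensor floor 40 mg/dL), so the guard is
  never needed on realistic data.
* Pearson correlation is undefined for constant inputs; the evaluation
  reports `NA` for degenerate (e.g. constant-prediction) models rather than
  failing the whole evaluation.
* Top-K ties broken by ascending node index; grid-search ties keep the first
  grid point; both make builds reproducible.
* ReLU subgradient at exactly 0 is taken as 0.
* Dropout is "inverted" (activations scaled by $1/(1-p)$ at train time), so
  evaluation needs no rescaling and eval mode is exactly deterministic.

## Known limitations

* The model is transductive: the spatial MLP and the graph are tied to the
  fixed training cohort. Forecasts for the same patients' future windows are
  supported; unseen patients are not.
* DTW cost is quadratic in record length; cohort-scale graph construction
  (~100 records of ~1000 points) takes seconds in the C++ kernel but full
  hospital-scale use would want the optional band.
* Training runs on one CPU in plain R; it is sized for cohorts of tens of
  patients and windows of tens of steps, not for GPU-scale experiments.
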