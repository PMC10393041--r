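# hetercgm

Simultaneous blood glucose forecasting for *cohorts* of diabetic patients
monitored by continuous glucose monitoring (CGM) sensors.

## The problem

CGM records sampled every 15 minutes arrive with unequal lengths (patients
are monitored for different durations), mixed diabetes types (a few volatile
T1DM records among many T2DM ones), and latent cross-patient correlation.
Classic per-patient forecasters ignore the cohort structure; naive pooling
breaks on the unequal lengths. `hetercgm` implements a graph-based
heterogeneous temporal representation (HETER) pipeline:

1. **SSR alignment** — each record is min–max normalized, cut into sliding
   windows of `T` inputs and `s` targets, and every patient's windows are
   *cyclically replicated* until all patients have β = max B⁽ⁿ⁾ windows
   (aligned window *b* ← source window ((b−1) mod B⁽ⁿ⁾)+1). Unlike padding
   (zeros) or truncation (data loss), replication re-uses only real data.
   `pad_align()` / `tra_align()` are provided as baselines.
2. **Sparse relation graph** — pairwise dynamic time warping (DTW) distances
   between the unequal-length normalized records; each patient keeps directed
   edges to its K nearest neighbours; self-loops and symmetric normalization
   give the propagation matrix P = M̃^(−1/2) Ã M̃^(−1/2).
3. **HETER network** — two stacked graph convolutions (R = P X W + b), a
   convolution filter along the patient axis, temporal attention
   (softmax over the T steps), a GRU over the attended window, and an output
   head fused with a linear residual: **O = R_o + W_o X + b_o**. Zeroing the
   nonlinear path reduces the network exactly to the linear model.
4. **Training / evaluation** — Adam on MSE with fully analytic gradients
   (verified against numerical differentiation in the tests); evaluation on
   the held-out most recent 36 h (144 points) per patient with MAE, MAPE
   (ratio), RMSE and Pearson correlation on de-normalized mg/dL values; a
   persistence baseline, grid search and T/K sensitivity sweeps.

A synthetic cohort generator (circadian sinusoid + postprandial spikes +
AR(1) noise, type-specific volatility) makes the whole pipeline testable
without any clinical data. See `vignettes/hetercgm-methods.Rmd` for the full
model description, parameter meanings and limitations.

## Worked example

```r
library(hetercgm)

spec <- cohort_spec(n_t1dm = 5, n_t2dm = 15, length_range = c(200, 400), seed = 1)
records <- simulate_cohort(spec)
cohort_summary(records)
#>   diabetes_type  n min_length mean_length max_length
#> 1          T1DM  5        242       312.8        366
#> 2          T2DM 15        206       285.4        386

al <- align_cohort(records, window = 8, horizon = 1, test_points = 144,
                   method = "ssr")
al$train
#> <aligned_dataset [train/ssr]: 234 segments x 20 samples x T=8, s=1>

graph <- cohort_srgraph(records, k = 5, test_points = 144, window = 8)
graph
#> <srgraph: 20 nodes, K=5, 100 directed edges, binary weights>

cfg <- heter_config(window = 8, horizon = 1, k = 5, seed = 1)
fit <- heter_train(al$train, graph, cfg, train_spec(epochs = 50, seed = 1))
tail(fit$loss_history, 1)   # training MSE: 0.3278 (epoch 1) -> 0.0112 (epoch 50)

heter_evaluate(fit$params, al$test, graph, al$norm_params, cfg)
#> <prediction_result [heter]: 144 segments x 20 samples x s=1>
#>       MAE       MAPE     RMSE       PCC
#>  10.65119 0.06360997 16.47903 0.9133774

persistence_baseline(al$test, al$norm_params)
#> <prediction_result [persistence]: 144 segments x 20 samples x s=1>
#>      MAE       MAPE   RMSE       PCC
#>  11.0618 0.06562392 16.696 0.9138012
```

Reading the numbers: on this synthetic 20-patient cohort the trained network
predicts the next 15-minute glucose value with a mean absolute error of
~10.7 mg/dL (MAPE ≈ 6.4%), beating the repeat-last-value persistence
baseline (~11.1 mg/dL). Errors are in mg/dL on the original scale; MAPE is a
ratio. Absolute values depend on the simulator's noise settings and are not
comparable to results on clinical data.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hetercgm", package = "hetercgm"))')
Rscript "$CLI" simulate --config config.json --out cohort.csv --seed 7
Rscript "$CLI" pipeline --config config.json --out-dir runs/demo
Rscript "$CLI" sweep --axis T --values 4,8,16 --config config.json
Rscript "$CLI" compare --alignments ssr,pad,tra --out-dir runs/cmp
```

`config.json` overrides the defaults of `default_run_config()` (cohort
shape, alignment method/window/horizon, graph K, network widths, training
schedule). Re-running a pipeline skips stages whose input hashes are
unchanged; identical config + seed reproduces results byte-for-byte.

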