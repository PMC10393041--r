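#' Training specification
#'
#' @param epochs Number of passes over the aligned training segments.
#' @param learning_rate Adam step size.
#' @param batch_size Segments per optimization step.
#' @param seed RNG seed controlling shuffling, dropout and initialization.
#' @param patience Optional early-stop patience (epochs without improvement
#'   of the training loss); `NULL` disables early stopping.
#' @return A `train_spec` list.
#' @export
train_spec <- function(epochs = 50L, learning_rate = 0.03, batch_size = 16L,
                       seed = 1L, patience = NULL) {
  if (epochs < 1L) stop("train_spec: epochs must be >= 1", call. = FALSE)
  if (learning_rate < 0) stop("train_spec: learning_rate must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 patience = if (is.null(patience)) NULL else as.integer(patience)),
            class = "train_spec")
}

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

subset_segments <- function(data, idx) {
  data$X <- data$X[idx, , , drop = FALSE]
  data$Y <- data$Y[idx, , , drop = FALSE]
  data
}

#' Train the HETER network with Adam on an MSE loss
#'
#' Minimizes the mean squared error between normalized predictions and
#' targets over shuffled mini-batches of aligned segments. Fully
#' deterministic given `spec$seed`. Training aborts with a diagnostic if the
#' loss diverges to NaN/Inf.
#'
#' @param train_data An `aligned_dataset` with role `"train"`.
#' @param graph An `srgraph` over the same samples.
#' @param config A [heter_config()].
#' @param spec A [train_spec()].
#' @param params Optional initial parameters (default: fresh
#'   [heter_init_params()] seeded from `spec$seed`).
#' @return List with `params` (fitted), `loss_history` (mean training MSE per
#'   epoch), `config`, `spec`.
#' @export
heter_train <- function(train_data, graph, config, spec, params = NULL) {
  stopifnot(inherits(train_data, "aligned_dataset"), inherits(graph, "srgraph"))
  N <- dim(train_data$X)[2]
  if (N != graph$n_nodes) stop("heter_train: node-count mismatch", call. = FALSE)
  if (is.null(params)) {
    cfg_seed <- config
    cfg_seed$seed <- spec$seed
    params <- heter_init_params(cfg_seed, N)
  }
  beta <- dim(train_data$X)[1]
  loss_history <- numeric(spec$epochs)
  withr::with_seed(spec$seed, {
    opt <- adam_init(params)
    best <- Inf; stale <- 0L
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample.int(beta)
      starts <- seq.int(1L, beta, by = spec$batch_size)
      tot <- 0
      for (st in starts) {
        idx <- perm[st:min(st + spec$batch_size - 1L, beta)]
        Xb <- train_data$X[idx, , , drop = FALSE]
        Yb <- train_data$Y[idx, , , drop = FALSE]
        lg <- heter_loss_grad(Xb, Yb, graph, params, config, mode = "train")
        if (!is.finite(lg$loss))
          stop(sprintf("heter_train: loss diverged (%.3g) at epoch %d; lower the learning rate",
                       lg$loss, epoch), call. = FALSE)
        tot <- tot + lg$loss * length(idx)
        upd <- adam_step(params, lg$grads, opt, spec$learning_rate)
        params <- upd$params; opt <- upd$state
      }
      loss_history[epoch] <- tot / beta
      if (!is.null(spec$patience)) {
        if (loss_history[epoch] < best - 1e-12) {
          best <- loss_history[epoch]; stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= spec$patience) {
            loss_history <- loss_history[seq_len(epoch)]
            break
          }
        }
      }
    }
  })
  list(params = params, loss_history = loss_history, config = config, spec = spec)
}

new_prediction_result <- function(pred_norm, data, norm_params, method) {
  d <- dim(pred_norm)  # (B, N, s)
  ids <- data$sample_order
  pred <- pred_norm; actual <- data$Y
  for (n in seq_len(d[2])) {
    np <- norm_params[[ids[n]]]
    pred[, n, ] <- denormalize(pred_norm[, n, , drop = FALSE], np)
    actual[, n, ] <- denormalize(data$Y[, n, , drop = FALSE], np)
  }
  overall <- metric_row(actual, pred)
  per_h <- do.call(rbind, lapply(seq_len(d[3]), function(t) {
    cbind(step = t, metric_row(actual[, , t], pred[, , t]))
  }))
  stopifnot(overall$RMSE >= overall$MAE - 1e-12)  # Jensen, asserted always
  structure(list(predictions = pred, actuals = actual,
                 metrics = overall, per_horizon = per_h,
                 method = method, sample_order = ids),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result [%s]: %d segments x %d samples x s=%d>\n",
              x$method, dim(x$predictions)[1], dim(x$predictions)[2],
              dim(x$predictions)[3]))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Evaluate fitted HETER parameters on a test set
#'
#' Runs the network in eval mode (dropout off, deterministic), de-normalizes
#' predictions and actuals with each sample's own min-max parameters, and
#' computes MAE, MAPE (ratio), RMSE and Pearson correlation overall and per
#' horizon step.
#'
#' @param params Fitted `heter_params`.
#' @param test_data An `aligned_dataset` (role `"test"`).
#' @param graph,config As in [heter_forward()].
#' @param norm_params Named list of per-sample `list(min, max)`.
#' @return A `prediction_result`.
#' @export
heter_evaluate <- function(params, test_data, graph, norm_params, config) {
  if (is.null(norm_params)) stop("heter_evaluate: missing norm params", call. = FALSE)
  fw <- heter_forward(test_data$X, graph, params, config, mode = "eval")
  new_prediction_result(fw$predictions, test_data, norm_params, "heter")
}

#' Naive persistence baseline
#'
#' Predicts the last observed input value for all `s` future steps, evaluated
#' with exactly the same de-normalization and metrics as [heter_evaluate()].
#'
#' @param test_data An `aligned_dataset`.
#' @param norm_params Named list of per-sample normalization parameters.
#' @param horizon Prediction steps `s`.
#' @return A `prediction_result`.
#' @export
persistence_baseline <- function(test_data, norm_params, horizon = NULL) {
  d <- dim(test_data$X)
  s <- if (is.null(horizon)) dim(test_data$Y)[3] else as.integer(horizon)
  last <- test_data$X[, , d[3], drop = FALSE]  # (B, N, 1)
  pred <- array(rep(last, s), dim = c(d[1], d[2], s))
  new_prediction_result(pred, test_data, norm_params, "persistence")
}

#' Grid search over HETER hyperparameters
#'
#' Trains one model per grid point on the first 90% of the aligned training
#' segments and scores de-normalized MAE on the held-out last 10% (the
#' validation protocol; the original experiments only state that grid search
#' was used). Ties keep the first grid point in enumeration order.
#'
#' @param grid Non-empty list of named lists; each entry overrides fields of
#'   `config` (e.g. `list(gcn_hidden = 32)`).
#' @param data Result of [align_cohort()] (training part is used).
#' @param graph An `srgraph`.
#' @param spec A [train_spec()].
#' @param config Base [heter_config()].
#' @return List with `best_config`, `best_index`, and `results` (one row per
#'   grid point with validation metrics).
#' @export
grid_search <- function(grid, data, graph, spec, config) {
  if (length(grid) == 0L) stop("grid_search: empty grid", call. = FALSE)
  beta <- dim(data$train$X)[1]
  n_val <- max(1L, floor(beta * 0.1))
  tr_idx <- seq_len(beta - n_val)
  if (length(tr_idx) == 0L) stop("grid_search: too few segments", call. = FALSE)
  val_idx <- seq.int(beta - n_val + 1L, beta)
  rows <- list(); configs <- list()
  for (i in seq_along(grid)) {
    cfg <- config
    for (nm in names(grid[[i]])) cfg[[nm]] <- grid[[i]][[nm]]
    validate_heter_config(cfg)
    configs[[i]] <- cfg
    fit <- heter_train(subset_segments(data$train, tr_idx), graph, cfg, spec)
    res <- heter_evaluate(fit$params, subset_segments(data$train, val_idx),
                          graph, data$norm_params, cfg)
    rows[[i]] <- cbind(grid_point = i,
                       as.data.frame(grid[[i]], stringsAsFactors = FALSE),
                       res$metrics)
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    # pad differing override columns across grid points
    r
  }))
  best <- which.min(vapply(rows, function(r) r$MAE, numeric(1)))
  list(best_config = configs[[best]], best_index = best, results = results)
}

#' Map a prediction horizon in minutes to steps
#'
#' @param horizon_minutes Horizon `H` in minutes (e.g. 15, 30, 60).
#' @param resolution_minutes Sampling resolution (15 for the standard CGM
#'   cadence), which must divide `H` exactly.
#' @return Integer step count `s` (1, 2, 4 for H = 15, 30, 60 at 15 min).
#' @export
horizon_to_steps <- function(horizon_minutes, resolution_minutes) {
  if (horizon_minutes %% resolution_minutes != 0)
    stop(sprintf("horizon %d min is not divisible by resolution %d min",
                 horizon_minutes, resolution_minutes), call. = FALSE)
  as.integer(horizon_minutes %/% resolution_minutes)
}

#' Sensitivity sweep over window size T or neighbour count K
#'
#' For each value the cohort is re-aligned (axis `"T"`) or the relation graph
#' rebuilt (axis `"K"`), a model is trained from scratch, and test metrics
#' are reported.
#'
#' @param axis `"T"` or `"K"`.
#' @param values Non-empty vector of window sizes / neighbour counts.
#' @param records Cohort (list of [cgm_record()]).
#' @param config Base [heter_config()].
#' @param spec A [train_spec()].
#' @param test_points Held-out trailing points per record.
#' @param method Alignment method for training data.
#' @return data.frame: one row per value with MAE, MAPE, RMSE, PCC.
#' @export
sensitivity_sweep <- function(axis = c("T", "K"), values, records, config,
                              spec, test_points = 144L, method = "ssr") {
  axis <- match.arg(axis)
  if (length(values) == 0L) stop("sensitivity_sweep: no values", call. = FALSE)
  N <- length(records)
  if (axis == "K" && any(values >= N))
    stop(sprintf("sensitivity_sweep: K must be < N = %d", N), call. = FALSE)
  rows <- lapply(values, function(v) {
    cfg <- config
    if (axis == "T") cfg$window <- as.integer(v) else cfg$k <- as.integer(v)
    validate_heter_config(cfg)
    data <- align_cohort(records, cfg$window, cfg$horizon, test_points, method)
    graph <- cohort_srgraph(records, cfg$k, test_points, cfg$window)
    fit <- heter_train(data$train, graph, cfg, spec)
    res <- heter_evaluate(fit$params, data$test, graph, data$norm_params, cfg)
    cbind(axis = axis, value = v, res$metrics)
  })
  do.call(rbind, rows)
}
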