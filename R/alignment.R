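#' Min-max normalization of a glucose series
#'
#' Scales a record to `[0, 1]` by its own minimum and maximum; the parameters
#' are retained so predictions can be mapped back to mg/dL with
#' [denormalize()]. Constant records are degenerate (zero range) and rejected.
#'
#' @param x Numeric series (length >= 2), or a [cgm_record()].
#' @return List with `values` (normalized series) and `params`
#'   (`list(min, max)`).
#' @export
minmax_normalize <- function(x) {
  if (inherits(x, "cgm_record")) x <- x$values
  if (length(x) < 2L) stop("minmax_normalize: need >= 2 points", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi == lo)
    stop("minmax_normalize: degenerate constant record (max == min)", call. = FALSE)
  list(values = (x - lo) / (hi - lo), params = list(min = lo, max = hi))
}

#' Invert min-max normalization
#'
#' @param values Normalized values.
#' @param params `list(min, max)` as returned by [minmax_normalize()].
#' @return Values on the original mg/dL scale.
#' @export
denormalize <- function(values, params) {
  stopifnot(is.list(params), params$max > params$min)
  values * (params$max - params$min) + params$min
}

#' Segment a series into sliding input/target window pairs
#'
#' Input windows cover `T` consecutive steps and the paired target window the
#' next `s` steps; windows slide by `stride` (default 1, maximally
#' overlapping). With stride 1 a series of length `L` yields
#' `B = L - T - s + 1` pairs.
#'
#' @param x Numeric series (normalized units).
#' @param window Input window length `T` (>= 1).
#' @param horizon Target steps `s` (>= 1).
#' @param stride Positive step between consecutive window starts.
#' @param record_id Optional id carried through to the segment set.
#' @return A `segment_set`: list with `record_id`, `inputs` (`B x T` matrix),
#'   `targets` (`B x s` matrix).
#' @export
segment_series <- function(x, window, horizon, stride = 1L, record_id = NA_character_) {
  window <- as.integer(window); horizon <- as.integer(horizon)
  stride <- as.integer(stride)
  stopifnot(window >= 1L, horizon >= 1L, stride >= 1L)
  L <- length(x)
  if (L < window + horizon)
    stop(sprintf("segment_series: series too short (%d < T + s = %d)",
                 L, window + horizon), call. = FALSE)
  starts <- seq.int(1L, L - window - horizon + 1L, by = stride)
  inputs <- t(vapply(starts, function(b) x[b:(b + window - 1L)], numeric(window)))
  targets <- t(vapply(starts, function(b) x[(b + window):(b + window + horizon - 1L)],
                      numeric(horizon)))
  structure(list(record_id = record_id,
                 inputs = matrix(inputs, ncol = window),
                 targets = matrix(targets, ncol = horizon)),
            class = "segment_set")
}

new_aligned_dataset <- function(X, Y, norm_params, sample_order, role, method) {
  structure(list(X = X, Y = Y, norm_params = norm_params,
                 sample_order = unname(sample_order), role = role,
                 method = method),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<aligned_dataset [%s/%s]: %d segments x %d samples x T=%d, s=%d>\n",
              x$role, x$method, d[1], d[2], d[3], dim(x$Y)[3]))
  invisible(x)
}

check_segment_sets <- function(segment_sets) {
  if (length(segment_sets) == 0L) stop("alignment: no segment sets", call. = FALSE)
  for (ss in segment_sets) {
    if (!inherits(ss, "segment_set") || nrow(ss$inputs) == 0L)
      stop("alignment: empty or invalid segment set", call. = FALSE)
  }
  invisible(TRUE)
}

stack_aligned <- function(segment_sets, pick_rows, n_out) {
  # pick_rows(B) -> source row indices of length n_out (NA = zero fill)
  N <- length(segment_sets)
  Tw <- ncol(segment_sets[[1]]$inputs)
  s <- ncol(segment_sets[[1]]$targets)
  X <- array(0, dim = c(n_out, N, Tw))
  Y <- array(0, dim = c(n_out, N, s))
  for (n in seq_len(N)) {
    idx <- pick_rows(nrow(segment_sets[[n]]$inputs))
    keep <- !is.na(idx)
    X[keep, n, ] <- segment_sets[[n]]$inputs[idx[keep], , drop = FALSE]
    Y[keep, n, ] <- segment_sets[[n]]$targets[idx[keep], , drop = FALSE]
  }
  list(X = X, Y = Y)
}

#' Align heterogeneous segment sets by subsequence repetition (SSR)
#'
#' Every sample's known segments are replicated cyclically from the first
#' segment until each sample reaches `beta = max B(n)` segments, so no sample
#' is truncated and no artificial values are introduced: aligned segment `b`
#' (1-based) is source segment `((b - 1) mod B(n)) + 1`.
#'
#' @param segment_sets List of `segment_set` objects (one per sample).
#' @param norm_params Optional list of per-sample normalization parameters,
#'   carried through for later de-normalization.
#' @param role `"train"` or `"test"` tag.
#' @return An `aligned_dataset` with `X` (`beta x N x T`) and `Y`
#'   (`beta x N x s`) arrays.
#' @export
ssr_align <- function(segment_sets, norm_params = NULL, role = "train") {
  check_segment_sets(segment_sets)
  beta <- max(vapply(segment_sets, function(ss) nrow(ss$inputs), integer(1)))
  parts <- stack_aligned(segment_sets,
                         function(B) ((seq_len(beta) - 1L) %% B) + 1L, beta)
  new_aligned_dataset(parts$X, parts$Y, norm_params,
                      vapply(segment_sets, `[[`, character(1), "record_id"),
                      role, "ssr")
}

#' Align segment sets by zero padding (PAD baseline)
#'
#' Samples with fewer than `beta = max B(n)` segments are completed with
#' all-zero input/target windows (zeros in normalized units — the
#' conventional "artificial data" fill).
#'
#' @inheritParams ssr_align
#' @return An `aligned_dataset`.
#' @export
pad_align <- function(segment_sets, norm_params = NULL, role = "train") {
  check_segment_sets(segment_sets)
  beta <- max(vapply(segment_sets, function(ss) nrow(ss$inputs), integer(1)))
  parts <- stack_aligned(segment_sets, function(B) {
    c(seq_len(B), rep(NA_integer_, beta - B))
  }, beta)
  new_aligned_dataset(parts$X, parts$Y, norm_params,
                      vapply(segment_sets, `[[`, character(1), "record_id"),
                      role, "pad")
}

#' Align segment sets by truncation (TRA baseline)
#'
#' All samples are cut down to `B_min = min B(n)` segments. Truncation keeps
#' the most recent segments (drops the series head), the forecasting-relevant
#' choice.
#'
#' @inheritParams ssr_align
#' @return An `aligned_dataset`.
#' @export
tra_align <- function(segment_sets, norm_params = NULL, role = "train") {
  check_segment_sets(segment_sets)
  bmin <- min(vapply(segment_sets, function(ss) nrow(ss$inputs), integer(1)))
  parts <- stack_aligned(segment_sets, function(B) seq.int(B - bmin + 1L, B), bmin)
  new_aligned_dataset(parts$X, parts$Y, norm_params,
                      vapply(segment_sets, `[[`, character(1), "record_id"),
                      role, "tra")
}

#' Split a record into training and test portions
#'
#' The last `test_points` observations are reserved as test targets (the
#' standard protocol holds out the most recent 36 h = 144 points at 15-min
#' resolution). The returned test series is prefixed with the trailing
#' `window` training points so every test target has a full input window;
#' no test target index ever appears among the training targets.
#'
#' @param record A [cgm_record()] or numeric series.
#' @param test_points Number of trailing observations held out.
#' @param window Input window length `T`.
#' @param horizon Prediction steps `s`.
#' @return List with `train` (first `L - test_points` values), `test`
#'   (last `test_points + window` values; `NULL` when `test_points` is 0) and
#'   `split_index` (last training index).
#' @export
train_test_split <- function(record, test_points, window, horizon = 1L) {
  x <- if (inherits(record, "cgm_record")) record$values else record
  test_points <- as.integer(test_points)
  L <- length(x)
  if (test_points < 0L) stop("train_test_split: test_points < 0", call. = FALSE)
  if (test_points == 0L)
    return(list(train = x, test = NULL, split_index = L))
  if (L <= test_points + window + horizon)
    stop(sprintf("train_test_split: record too short (%d <= %d)",
                 L, test_points + window + horizon), call. = FALSE)
  split <- L - test_points
  list(train = x[seq_len(split)],
       test = x[(split - window + 1L):L],
       split_index = split)
}

#' Normalize, segment, split and align a whole cohort
#'
#' Per record: split off the trailing `test_points` targets, compute min-max
#' parameters on the training portion only (reused for the test portion to
#' avoid leakage), segment both portions with stride-1 windows, then align
#' the training segment counts with the requested method. Test sets need no
#' alignment: every record contributes the same `test_points - s + 1`
#' segments by construction.
#'
#' @param records List of [cgm_record()] objects.
#' @param window Input window length `T`.
#' @param horizon Prediction steps `s`.
#' @param test_points Held-out trailing points per record (0 = no test set).
#' @param method Alignment method: `"ssr"`, `"pad"` or `"tra"`.
#' @param stride Training segmentation stride.
#' @return List with `train` and `test` `aligned_dataset`s (test `NULL` when
#'   `test_points` is 0), plus `norm_params` and `window`/`horizon`.
#' @export
align_cohort <- function(records, window, horizon = 1L, test_points = 0L,
                         method = c("ssr", "pad", "tra"), stride = 1L) {
  method <- match.arg(method)
  aligner <- switch(method, ssr = ssr_align, pad = pad_align, tra = tra_align)
  train_sets <- list(); test_sets <- list(); norm_params <- list()
  for (r in records) {
    sp <- train_test_split(r, test_points, window, horizon)
    nz <- minmax_normalize(sp$train)
    norm_params[[r$patient_id]] <- nz$params
    train_sets[[r$patient_id]] <-
      segment_series(nz$values, window, horizon, stride, r$patient_id)
    if (!is.null(sp$test)) {
      test_norm <- (sp$test - nz$params$min) / (nz$params$max - nz$params$min)
      test_sets[[r$patient_id]] <-
        segment_series(test_norm, window, horizon, 1L, r$patient_id)
    }
  }
  test <- if (length(test_sets)) {
    # identical segment counts across samples by construction; ssr is a no-op
    ssr_align(test_sets, norm_params, role = "test")
  } else NULL
  list(train = aligner(train_sets, norm_params, role = "train"),
       test = test, norm_params = norm_params,
       window = as.integer(window), horizon = as.integer(horizon))
}
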