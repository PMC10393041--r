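#' HETER network configuration
#'
#' Hyperparameters of the HETER forecasting network. The input to the network
#' is an aligned tensor of shape `segments x nodes x T`; the output predicts
#' `s` future steps per node and segment.
#'
#' @param window Input window length `T` (>= 2).
#' @param horizon Prediction steps `s` (>= 1).
#' @param k Graph neighbours `K` (metadata; the graph itself fixes it).
#' @param gcn_hidden Width of the first graph convolution layer.
#' @param conv_channels Number of convolution filters along the sample axis.
#' @param conv_kernel Odd kernel size of the spatial convolution.
#' @param att_hidden Hidden width of the temporal-attention MLP (default `T`).
#' @param gru_hidden GRU hidden-state width.
#' @param mlp_hidden Hidden width of the temporal and spatial output MLPs.
#' @param dropout_g,dropout_co,dropout_o Dropout probabilities after the first
#'   GCN, after the convolution, and before the output MLPs (`0 <= p < 1`).
#' @param candidate_activation GRU candidate-state activation: `"sigmoid"`
#'   (as the method prints it) or `"tanh"` (the conventional GRU).
#' @param seed Seed for parameter initialization.
#' @return A `heter_config` list.
#' @export
heter_config <- function(window = 8L, horizon = 1L, k = 25L,
                         gcn_hidden = 64L, conv_channels = 32L,
                         conv_kernel = 3L, att_hidden = NULL,
                         gru_hidden = 64L, mlp_hidden = 16L,
                         dropout_g = 0.2, dropout_co = 0.2, dropout_o = 0.2,
                         candidate_activation = c("sigmoid", "tanh"),
                         seed = 1L) {
  cfg <- list(window = as.integer(window), horizon = as.integer(horizon),
              k = as.integer(k), gcn_hidden = as.integer(gcn_hidden),
              conv_channels = as.integer(conv_channels),
              conv_kernel = as.integer(conv_kernel),
              att_hidden = as.integer(if (is.null(att_hidden)) window else att_hidden),
              gru_hidden = as.integer(gru_hidden),
              mlp_hidden = as.integer(mlp_hidden),
              dropout_g = dropout_g, dropout_co = dropout_co, dropout_o = dropout_o,
              candidate_activation = match.arg(candidate_activation),
              seed = as.integer(seed))
  class(cfg) <- "heter_config"
  validate_heter_config(cfg)
  cfg
}

validate_heter_config <- function(cfg) {
  with(cfg, {
    if (window < 2L) stop("heter_config: window T must be >= 2", call. = FALSE)
    if (horizon < 1L) stop("heter_config: horizon s must be >= 1", call. = FALSE)
    for (p in c(dropout_g, dropout_co, dropout_o))
      if (p < 0 || p >= 1) stop("heter_config: dropout must be in [0, 1)", call. = FALSE)
    if (any(c(gcn_hidden, conv_channels, gru_hidden, mlp_hidden, att_hidden) < 1L))
      stop("heter_config: widths must be >= 1", call. = FALSE)
    if (conv_kernel < 1L || conv_kernel %% 2L == 0L)
      stop("heter_config: conv_kernel must be odd and >= 1", call. = FALSE)
  })
  invisible(cfg)
}

xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize HETER parameters
#'
#' Xavier-uniform weights, zero biases; the spatial output MLP is sized to the
#' graph's node count, so parameters are tied to a fixed cohort (the model is
#' transductive: training nodes and test segments share node identities).
#'
#' @param config A [heter_config()].
#' @param n_nodes Number of graph nodes `N`.
#' @return A `heter_params` list of weight matrices and bias vectors.
#' @export
heter_init_params <- function(config, n_nodes) {
  N <- as.integer(n_nodes)
  withr::with_seed(config$seed, {
    p <- with(config, list(
      Wg1 = xavier(window, gcn_hidden), bg = numeric(gcn_hidden),
      Wg2 = xavier(gcn_hidden, window),
      Wco = xavier(conv_channels, conv_kernel),
      vco = as.numeric(xavier(conv_channels, 1L)),
      Wta2 = xavier(window, att_hidden), bta2 = numeric(att_hidden),
      Wta1 = xavier(att_hidden, window), bta1 = numeric(window),
      Ur = xavier(gru_hidden, gru_hidden), wr = xavier(1L, gru_hidden),
      br = numeric(gru_hidden),
      Uu = xavier(gru_hidden, gru_hidden), wu = xavier(1L, gru_hidden),
      bu = numeric(gru_hidden),
      Uc = xavier(gru_hidden, gru_hidden), wc = xavier(1L, gru_hidden),
      bc = numeric(gru_hidden),
      Wt1 = xavier(gru_hidden, mlp_hidden), bt1 = numeric(mlp_hidden),
      Wt2 = xavier(mlp_hidden, horizon), bt2 = numeric(horizon),
      Ws1 = xavier(N, mlp_hidden), bs1 = numeric(mlp_hidden),
      Ws2 = xavier(mlp_hidden, N), bs2 = numeric(N),
      Wo = xavier(window, horizon), bo = numeric(horizon)
    ))
    class(p) <- "heter_params"
    p
  })
}

## ---- internal tensor layout helpers -------------------------------------
## Canonical batched layout ("M-form"): matrix (N*b) x F, row index = node n
## fastest within each batch element b; arrays are (b, N, F).

to_m <- function(X) {
  d <- dim(X)  # (b, N, F)
  matrix(aperm(X, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

from_m <- function(M, b, N) {
  array(aperm(array(M, dim = c(N, b, ncol(M))), c(2, 1, 3)),
        dim = c(b, N, ncol(M)))
}

# Per batch element: P %*% M_b, done in one matmul across the batch.
apply_p <- function(M, P, N) {
  matrix(P %*% matrix(M, nrow = N), nrow = nrow(M), ncol = ncol(M))
}

# Shift rows along the node axis (within each batch block) by offset o,
# zero-filling outside 1..N.
shift_rows <- function(M, o, N) {
  if (o == 0L) return(M)
  m <- nrow(M)
  n_idx <- ((seq_len(m) - 1L) %% N) + 1L
  valid <- n_idx + o >= 1L & n_idx + o <= N
  out <- matrix(0, m, ncol(M))
  out[valid, ] <- M[seq_len(m)[valid] + o, , drop = FALSE]
  out
}

addb <- function(M, bvec) M + matrix(bvec, nrow(M), length(bvec), byrow = TRUE)

relu <- function(x) pmax(x, 0)
sigm <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(M) {
  E <- exp(M - apply(M, 1L, max))
  E / rowSums(E)
}

# Inverted dropout: returns a multiplier (matrix in training, scalar 1 in eval).
dropout_mask <- function(nr, nc, p, training) {
  if (!training || p == 0) return(1)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

## ---- exported components --------------------------------------------------

#' Single graph convolution layer
#'
#' Computes `P X W + b` where `P` is the symmetric-normalized propagation
#' matrix of the relation graph, for a single `N x T` feature matrix or a
#' batch array `b x N x T`.
#'
#' @param P `N x N` propagation matrix (see [build_srgraph()]).
#' @param X `N x F` matrix or `b x N x F` array of node features.
#' @param W `F x F'` weight matrix.
#' @param b Bias vector of length `F'` (may be 0).
#' @return Same layout as `X` with feature width `F'`.
#' @export
gcn_layer <- function(P, X, W, b = 0) {
  if (is.matrix(X)) {
    if (nrow(X) != nrow(P)) stop("gcn_layer: node-count mismatch", call. = FALSE)
    if (ncol(X) != nrow(W)) stop("gcn_layer: feature/weight mismatch", call. = FALSE)
    out <- P %*% X %*% W
    return(if (length(b) > 1L) addb(out, b) else out + b)
  }
  d <- dim(X)
  if (d[2] != nrow(P)) stop("gcn_layer: node-count mismatch", call. = FALSE)
  M <- to_m(X)
  out <- apply_p(M, P, d[2]) %*% W
  out <- if (length(b) > 1L) addb(out, b) else out + b
  from_m(out, d[1], d[2])
}

#' Stacked two-layer graph module
#'
#' `R_g1 = P X W_g1 + b_g`; `R_g2 = P Dropout(ReLU(R_g1), p_g) W_g2` (no bias
#' on the second layer). Dropout is active only in training mode.
#'
#' @param X `b x N x T` input array.
#' @param graph An `srgraph` whose node count matches `dim(X)[2]`.
#' @param params,config [heter_init_params()] / [heter_config()].
#' @param training Logical; enables dropout.
#' @return `b x N x T` array `R_g2`.
#' @export
graph_module <- function(X, graph, params, config, training = FALSE) {
  d <- dim(X)
  if (d[2] != graph$n_nodes) stop("graph_module: node-count mismatch", call. = FALSE)
  fw <- forward_graph_module(to_m(X), graph$P, d[2], params, config, training)
  from_m(fw$Rg2, d[1], d[2])
}

forward_graph_module <- function(M0, P, N, params, config, training) {
  Q0 <- apply_p(M0, P, N)
  Rg1 <- addb(Q0 %*% params$Wg1, params$bg)
  Zr <- relu(Rg1)
  mask_g <- dropout_mask(nrow(Zr), ncol(Zr), config$dropout_g, training)
  Z <- Zr * mask_g
  Q1 <- apply_p(Z, P, N)
  Rg2 <- Q1 %*% params$Wg2
  list(Q0 = Q0, Rg1 = Rg1, Zr = Zr, mask_g = mask_g, Z = Z, Q1 = Q1, Rg2 = Rg2)
}

#' Spatial convolution component
#'
#' Convolves along the sample (node) axis with `conv_channels` filters of odd
#' width `conv_kernel` and zero same-padding, applies ReLU and dropout, then
#' folds the channel axis back with a learned combination vector so the
#' output keeps the `b x N x T` shape.
#'
#' @param R `b x N x T` array (output of [graph_module()]).
#' @inheritParams graph_module
#' @return `b x N x T` array `R_co`.
#' @export
conv_component <- function(R, params, config, training = FALSE) {
  d <- dim(R)
  if (config$conv_kernel > d[2])
    stop("conv_component: kernel larger than the sample axis", call. = FALSE)
  fw <- forward_conv(to_m(R), d[2], params, config, training)
  from_m(fw$Rco, d[1], d[2])
}

forward_conv <- function(M, N, params, config, training) {
  if (config$conv_kernel > N)
    stop("conv_component: kernel larger than the sample axis", call. = FALSE)
  C <- config$conv_channels
  half <- (config$conv_kernel - 1L) %/% 2L
  offsets <- seq.int(-half, half)
  shifted <- lapply(offsets, shift_rows, M = M, N = N)
  pre <- vector("list", C); Zd <- vector("list", C); masks <- vector("list", C)
  Rco <- matrix(0, nrow(M), ncol(M))
  for (c in seq_len(C)) {
    acc <- matrix(0, nrow(M), ncol(M))
    for (j in seq_along(offsets))
      acc <- acc + params$Wco[c, j] * shifted[[j]]
    pre[[c]] <- acc
    mask <- dropout_mask(nrow(M), ncol(M), config$dropout_co, training)
    masks[[c]] <- mask
    Zd[[c]] <- relu(acc) * mask
    Rco <- Rco + params$vco[c] * Zd[[c]]
  }
  list(shifted = shifted, offsets = offsets, pre = pre, masks = masks,
       Zd = Zd, Rco = Rco)
}

#' Temporal attention scores
#'
#' `S_ta = softmax(ReLU(R W_ta2 + b_ta2) W_ta1 + b_ta1)` with the softmax
#' taken along the time axis, so each (segment, node) row is a probability
#' distribution over the `T` time steps.
#'
#' @param R `b x N x T` array or `rows x T` matrix.
#' @param params [heter_init_params()].
#' @return Attention scores with the same layout as `R`; strictly positive,
#'   rows summing to 1.
#' @export
temporal_attention <- function(R, params) {
  if (is.matrix(R)) return(forward_attention(R, params)$S)
  d <- dim(R)
  from_m(forward_attention(to_m(R), params)$S, d[1], d[2])
}

forward_attention <- function(M, params) {
  Ah_pre <- addb(M %*% params$Wta2, params$bta2)
  Ah <- relu(Ah_pre)
  logits <- addb(Ah %*% params$Wta1, params$bta1)
  list(Ah_pre = Ah_pre, Ah = Ah, logits = logits, S = softmax_rows(logits))
}

#' GRU recurrent component
#'
#' Iterates the gated recurrent unit over the `T` columns of the reweighted
#' representation (one scalar input per node and step, all nodes sharing the
#' cell parameters): reset gate `r_t`, update gate `u_t`, candidate `c_t`
#' (sigmoid as printed, or tanh via the config switch), and
#' `h_t = (1 - u_t) * h_{t-1} + u_t * c_t`.
#'
#' @param sequence `rows x T` matrix of scalar inputs (or `b x N x T` array).
#' @param params,config [heter_init_params()] / [heter_config()].
#' @param h0 Optional initial hidden state (`rows x gru_hidden`; default 0).
#' @return Final hidden state `h_T` (`rows x gru_hidden` matrix, or
#'   `b x N x gru_hidden` array for array input).
#' @export
gru_forward <- function(sequence, params, config, h0 = NULL) {
  if (is.matrix(sequence)) return(forward_gru(sequence, params, config, h0)$H)
  d <- dim(sequence)
  H <- forward_gru(to_m(sequence), params, config, h0)$H
  from_m(H, d[1], d[2])
}

forward_gru <- function(Gin, params, config, h0 = NULL) {
  m <- nrow(Gin); Tn <- ncol(Gin); dh <- ncol(params$Ur)
  act <- if (config$candidate_activation == "tanh") tanh else sigm
  H <- if (is.null(h0)) matrix(0, m, dh) else h0
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- Gin[, t, drop = FALSE]  # m x 1
    r <- sigm(addb(H %*% params$Ur + x %*% params$wr, params$br))
    u <- sigm(addb(H %*% params$Uu + x %*% params$wu, params$bu))
    rh <- r * H
    cc <- act(addb(rh %*% params$Uc + x %*% params$wc, params$bc))
    Hn <- (1 - u) * H + u * cc
    steps[[t]] <- list(x = x, hprev = H, r = r, u = u, rh = rh, cc = cc)
    H <- Hn
  }
  list(H = H, steps = steps)
}

#' Output head with linear residual fusion
#'
#' `R_o = SMLP(TMLP(Dropout(h_T, p_o)))` where the temporal MLP maps the GRU
#' state to `s` horizon steps and the spatial MLP mixes across the node axis;
#' the final prediction adds the linear input representation:
#' `O = R_o + X W_o + b_o` with `W_o` a `T -> s` affine map. Zeroing the MLP
#' weights therefore reduces the network exactly to the linear model.
#'
#' @param hT `b x N x gru_hidden` array of final hidden states.
#' @param X `b x N x T` network input (for the residual path).
#' @inheritParams graph_module
#' @return `b x N x s` prediction array in normalized units.
#' @export
output_head <- function(hT, X, params, config, training = FALSE) {
  d <- dim(X)
  fw <- forward_head(to_m(hT), to_m(X), d[1], d[2], params, config, training)
  from_m(fw$O, d[1], d[2])
}

# M-form (m x F) <-> S-form ((b*s) x N) for the spatial MLP
m_to_s <- function(M, b, N) {
  matrix(aperm(array(M, dim = c(N, b, ncol(M))), c(2, 3, 1)),
         nrow = b * ncol(M), ncol = N)
}
s_to_m <- function(S, b, N, s) {
  matrix(aperm(array(S, dim = c(b, s, N)), c(3, 1, 2)), nrow = N * b, ncol = s)
}

forward_head <- function(Hm, M0, b, N, params, config, training) {
  mask_o <- dropout_mask(nrow(Hm), ncol(Hm), config$dropout_o, training)
  Hd <- Hm * mask_o
  T1_pre <- addb(Hd %*% params$Wt1, params$bt1)
  T1 <- relu(T1_pre)
  T2 <- addb(T1 %*% params$Wt2, params$bt2)           # m x s
  Sm <- m_to_s(T2, b, N)                              # (b*s) x N
  S1_pre <- addb(Sm %*% params$Ws1, params$bs1)
  S1 <- relu(S1_pre)
  S2 <- addb(S1 %*% params$Ws2, params$bs2)           # (b*s) x N
  Ro <- s_to_m(S2, b, N, config$horizon)              # m x s
  Lin <- addb(M0 %*% params$Wo, params$bo)
  list(mask_o = mask_o, Hd = Hd, T1_pre = T1_pre, T1 = T1, T2 = T2,
       Sm = Sm, S1_pre = S1_pre, S1 = S1, S2 = S2, Ro = Ro, Lin = Lin,
       O = Ro + Lin)
}

#' Full HETER forward pass
#'
#' Composes graph module, spatial convolution, temporal attention, attention
#' reweighting, GRU, and the residual output head. Evaluation mode disables
#' all dropout and is fully deterministic.
#'
#' @param X `b x N x T` aligned input array (normalized units).
#' @param graph An `srgraph` over the `N` samples.
#' @param params,config [heter_init_params()] / [heter_config()].
#' @param mode `"eval"` (default) or `"train"` (dropout active; the caller
#'   controls the RNG state).
#' @param keep_cache Internal: retain intermediates for backpropagation.
#' @return List with `predictions` (`b x N x s` array) and `trace` (named
#'   intermediates: `Rg1`, `Rg2`, `Rco`, `Sta`, `hT`, `Ro`).
#' @export
heter_forward <- function(X, graph, params, config, mode = c("eval", "train"),
                          keep_cache = FALSE) {
  mode <- match.arg(mode)
  training <- mode == "train"
  d <- dim(X)
  if (length(d) != 3L) stop("heter_forward: X must be b x N x T", call. = FALSE)
  if (d[2] != graph$n_nodes) stop("heter_forward: node-count mismatch", call. = FALSE)
  if (d[3] != config$window) stop("heter_forward: window mismatch", call. = FALSE)
  b <- d[1]; N <- d[2]
  M0 <- to_m(X)
  g <- forward_graph_module(M0, graph$P, N, params, config, training)
  cv <- forward_conv(g$Rg2, N, params, config, training)
  at <- forward_attention(cv$Rco, params)
  Gin <- cv$Rco * at$S
  gr <- forward_gru(Gin, params, config)
  hd <- forward_head(gr$H, M0, b, N, params, config, training)
  trace <- list(Rg1 = from_m(g$Rg1, b, N), Rg2 = from_m(g$Rg2, b, N),
                Rco = from_m(cv$Rco, b, N), Sta = from_m(at$S, b, N),
                hT = from_m(gr$H, b, N), Ro = from_m(hd$Ro, b, N))
  out <- list(predictions = from_m(hd$O, b, N), trace = trace)
  if (keep_cache)
    out$cache <- list(M0 = M0, b = b, N = N, g = g, cv = cv, at = at,
                      Gin = Gin, gr = gr, hd = hd)
  out
}
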