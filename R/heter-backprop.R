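# Analytic reverse-mode gradients for the HETER forward pass. Every stage
# mirrors its forward counterpart in heter-model.R and consumes the cache
# produced by heter_forward(keep_cache = TRUE); correctness is pinned by a
# central-difference gradient check in the test suite.

zero_like_params <- function(params) {
  g <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  class(g) <- "heter_params"
  g
}

backward_head <- function(dO, hd, M0, b, N, s, params) {
  dWo <- crossprod(M0, dO); dbo <- colSums(dO)
  dS2 <- m_to_s(dO, b, N)
  dWs2 <- crossprod(hd$S1, dS2); dbs2 <- colSums(dS2)
  dS1 <- (dS2 %*% t(params$Ws2)) * (hd$S1_pre > 0)
  dWs1 <- crossprod(hd$Sm, dS1); dbs1 <- colSums(dS1)
  dSm <- dS1 %*% t(params$Ws1)
  dT2 <- s_to_m(dSm, b, N, s)
  dWt2 <- crossprod(hd$T1, dT2); dbt2 <- colSums(dT2)
  dT1 <- (dT2 %*% t(params$Wt2)) * (hd$T1_pre > 0)
  dWt1 <- crossprod(hd$Hd, dT1); dbt1 <- colSums(dT1)
  dHm <- (dT1 %*% t(params$Wt1)) * hd$mask_o
  list(grads = list(Wo = dWo, bo = dbo, Ws2 = dWs2, bs2 = dbs2,
                    Ws1 = dWs1, bs1 = dbs1, Wt2 = dWt2, bt2 = dbt2,
                    Wt1 = dWt1, bt1 = dbt1),
       dHm = dHm)
}

backward_gru <- function(dH, gr, params, config) {
  steps <- gr$steps
  d <- ncol(params$Ur)
  gUr <- matrix(0, d, d); gUu <- matrix(0, d, d); gUc <- matrix(0, d, d)
  gwr <- matrix(0, 1, d); gwu <- matrix(0, 1, d); gwc <- matrix(0, 1, d)
  gbr <- numeric(d); gbu <- numeric(d); gbc <- numeric(d)
  Tn <- length(steps)
  dGin <- matrix(0, nrow(dH), Tn)
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    du <- dH * (st$cc - st$hprev)
    dcc <- dH * st$u
    dh_prev <- dH * (1 - st$u)
    actp <- if (config$candidate_activation == "tanh") 1 - st$cc^2
            else st$cc * (1 - st$cc)
    dAc <- dcc * actp
    gUc <- gUc + crossprod(st$rh, dAc)
    gwc <- gwc + crossprod(st$x, dAc)
    gbc <- gbc + colSums(dAc)
    drh <- dAc %*% t(params$Uc)
    dr <- drh * st$hprev
    dh_prev <- dh_prev + drh * st$r
    dAr <- dr * st$r * (1 - st$r)
    dAu <- du * st$u * (1 - st$u)
    gUr <- gUr + crossprod(st$hprev, dAr)
    gwr <- gwr + crossprod(st$x, dAr)
    gbr <- gbr + colSums(dAr)
    gUu <- gUu + crossprod(st$hprev, dAu)
    gwu <- gwu + crossprod(st$x, dAu)
    gbu <- gbu + colSums(dAu)
    dh_prev <- dh_prev + dAr %*% t(params$Ur) + dAu %*% t(params$Uu)
    dGin[, t] <- dAr %*% t(params$wr) + dAu %*% t(params$wu) +
      dAc %*% t(params$wc)
    dH <- dh_prev
  }
  list(grads = list(Ur = gUr, wr = gwr, br = gbr, Uu = gUu, wu = gwu,
                    bu = gbu, Uc = gUc, wc = gwc, bc = gbc),
       dGin = dGin)
}

backward_attention <- function(dS, at, params) {
  dlogits <- at$S * (dS - rowSums(dS * at$S))
  dWta1 <- crossprod(at$Ah, dlogits); dbta1 <- colSums(dlogits)
  dAh <- (dlogits %*% t(params$Wta1)) * (at$Ah_pre > 0)
  dWta2_in <- dAh %*% t(params$Wta2)
  list(grads = list(Wta1 = dWta1, bta1 = dbta1,
                    Wta2 = NULL, bta2 = colSums(dAh)),
       dAh = dAh, dRco = dWta2_in)
}

backward_conv <- function(dRco, cv, N, params) {
  C <- nrow(params$Wco)
  offsets <- cv$offsets
  gWco <- matrix(0, C, length(offsets))
  gvco <- numeric(C)
  dM <- matrix(0, nrow(dRco), ncol(dRco))
  for (c in seq_len(C)) {
    gvco[c] <- sum(dRco * cv$Zd[[c]])
    dpre <- params$vco[c] * dRco * cv$masks[[c]] * (cv$pre[[c]] > 0)
    for (j in seq_along(offsets)) {
      gWco[c, j] <- sum(dpre * cv$shifted[[j]])
      dM <- dM + params$Wco[c, j] * shift_rows(dpre, -offsets[j], N)
    }
  }
  list(grads = list(Wco = gWco, vco = gvco), dM = dM)
}

backward_graph_module <- function(dRg2, g, P, N, params) {
  dWg2 <- crossprod(g$Q1, dRg2)
  dQ1 <- dRg2 %*% t(params$Wg2)
  dZ <- apply_p(dQ1, t(P), N)
  dRg1 <- dZ * g$mask_g * (g$Rg1 > 0)
  dWg1 <- crossprod(g$Q0, dRg1)
  dbg <- colSums(dRg1)
  list(grads = list(Wg2 = dWg2, Wg1 = dWg1, bg = dbg))
}

heter_backward <- function(cache, dO, graph, params, config) {
  b <- cache$b; N <- cache$N
  hd_bk <- backward_head(dO, cache$hd, cache$M0, b, N, config$horizon, params)
  gru_bk <- backward_gru(hd_bk$dHm, cache$gr, params, config)
  # reweight: Gin = Rco * S
  dRco <- gru_bk$dGin * cache$at$S
  dS <- gru_bk$dGin * cache$cv$Rco
  at_bk <- backward_attention(dS, cache$at, params)
  dRco <- dRco + at_bk$dRco
  at_bk$grads$Wta2 <- crossprod(cache$cv$Rco, at_bk$dAh)
  cv_bk <- backward_conv(dRco, cache$cv, N, params)
  g_bk <- backward_graph_module(cv_bk$dM, cache$g, graph$P, N, params)
  grads <- zero_like_params(params)
  for (part in list(hd_bk$grads, gru_bk$grads, at_bk$grads,
                    cv_bk$grads, g_bk$grads)) {
    for (nm in names(part)) grads[[nm]] <- part[[nm]]
  }
  # keep parameter orientation (wr/wu/wc are 1 x d, biases plain vectors)
  for (nm in names(grads)) {
    if (!is.matrix(params[[nm]])) grads[[nm]] <- as.numeric(grads[[nm]])
    else if (is.matrix(grads[[nm]]) &&
             !all(dim(grads[[nm]]) == dim(params[[nm]])))
      stop("heter_backward: gradient shape mismatch for ", nm, call. = FALSE)
  }
  grads
}

#' MSE loss and analytic parameter gradients for one batch
#'
#' Runs a forward pass (training mode enables dropout; the caller controls
#' the RNG state) and backpropagates the mean-squared-error loss between the
#' normalized predictions and targets through every stage of the network.
#'
#' @param X `b x N x T` input array; `Y` `b x N x s` target array.
#' @param graph,params,config As in [heter_forward()].
#' @param mode `"train"` or `"eval"` (dropout off).
#' @param Y Target array.
#' @return List with `loss` (scalar MSE) and `grads` (a `heter_params`-shaped
#'   list of gradients).
#' @export
heter_loss_grad <- function(X, Y, graph, params, config, mode = "train") {
  fw <- heter_forward(X, graph, params, config, mode = mode, keep_cache = TRUE)
  Ym <- to_m(Y)
  O <- fw$cache$hd$O
  err <- O - Ym
  loss <- mean(err^2)
  dO <- 2 * err / length(err)
  grads <- heter_backward(fw$cache, dO, graph, params, config)
  list(loss = loss, grads = grads, predictions = fw$predictions)
}
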