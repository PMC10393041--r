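# Independent oracles and tiny fixtures shared across the suite. The oracles
# deliberately use different algorithms from the implementation: recursive
# memoization for DTW, explicit dense linear algebra for the graph layers.

# Pure-R memoized-recursion DTW (absolute-difference cost, steps
# (1,0),(0,1),(1,1)); independent of the C++ dynamic program.
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- abs(a[i] - b[j])
    val <- if (i == 1 && j == 1) cost
           else cost + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[i, j] <<- val
    val
  }
  rec(n, m)
}

# Dense two-layer GCN oracle: explicit D^{-1/2}(A+I)D^{-1/2} per batch element.
gcn_oracle <- function(X, A, Wg1, bg, Wg2) {
  N <- nrow(A)
  At <- A + diag(N)
  Dh <- diag(1 / sqrt(rowSums(At)))
  P <- Dh %*% At %*% Dh
  out <- array(0, dim = c(dim(X)[1], N, ncol(Wg2)))
  for (b in seq_len(dim(X)[1])) {
    R1 <- P %*% X[b, , ] %*% Wg1 + matrix(bg, N, length(bg), byrow = TRUE)
    out[b, , ] <- P %*% pmax(R1, 0) %*% Wg2
  }
  out
}

tiny_cohort <- function(n = 6L, lmin = 60L, lmax = 100L, seed = 3L) {
  simulate_cohort(cohort_spec(n_t1dm = max(1L, n %/% 3L),
                              n_t2dm = n - max(1L, n %/% 3L),
                              length_range = c(lmin, lmax), seed = seed))
}

tiny_config <- function(...) {
  defaults <- list(window = 6L, horizon = 2L, k = 2L, gcn_hidden = 5L,
                   conv_channels = 2L, conv_kernel = 3L, gru_hidden = 4L,
                   mlp_hidden = 3L, dropout_g = 0, dropout_co = 0,
                   dropout_o = 0)
  do.call(heter_config, utils::modifyList(defaults, list(...)))
}

random_graph <- function(N, K, seed = 1L) {
  withr::with_seed(seed, {
    G <- matrix(runif(N * N), N, N)
    G <- (G + t(G)) / 2
    diag(G) <- 0
    build_srgraph(topk_adjacency(G, K), K)
  })
}
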