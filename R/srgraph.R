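#' Dynamic time warping distance between two series
#'
#' Classic dynamic-programming DTW with absolute-difference local cost, step
#' moves (1,0), (0,1), (1,1), and boundary alignment of the first and last
#' points of both series; returns the minimal cumulative cost over all
#' alignment paths. Symmetric and zero on identical inputs; reduces to the L1
#' distance for two length-1 series. DTW is a semi-metric: the triangle
#' inequality does not hold in general.
#'
#' @param a,b Non-empty numeric series (lengths may differ).
#' @param band Optional Sakoe-Chiba band half-width (index units); `NULL`
#'   (default) runs the full dynamic program, as the method prescribes.
#' @return Non-negative distance in the units of the inputs.
#' @export
dtw_distance <- function(a, b, band = NULL) {
  if (length(a) == 0L || length(b) == 0L)
    stop("dtw_distance: empty series", call. = FALSE)
  .dtw_dp(as.numeric(a), as.numeric(b),
          if (is.null(band)) -1L else as.integer(band))
}

#' Pairwise DTW distance matrix over a cohort
#'
#' @param series List (>= 2) of numeric series, typically per-record min-max
#'   normalized training portions; names become row/column names.
#' @param band Optional Sakoe-Chiba band passed to [dtw_distance()].
#' @return Symmetric `N x N` matrix with zero diagonal.
#' @export
distance_matrix <- function(series, band = NULL) {
  N <- length(series)
  if (N < 2L) stop("distance_matrix: need >= 2 records", call. = FALSE)
  G <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      G[i, j] <- G[j, i] <- dtw_distance(series[[i]], series[[j]], band)
    }
  }
  dimnames(G) <- list(names(series), names(series))
  G
}

#' Top-K nearest-neighbour adjacency from a distance matrix
#'
#' For each row (sample) the `K` smallest off-diagonal distances are selected
#' as outgoing edges, so every row of the returned binary matrix sums to `K`.
#' The graph is directed: selection is per row and need not be symmetric.
#' Distance ties are broken by ascending node index for deterministic builds.
#'
#' @param G Symmetric non-negative distance matrix with zero diagonal.
#' @param k Number of neighbours, `1 <= k <= N - 1`.
#' @return `N x N` binary adjacency matrix `A` (zero diagonal).
#' @export
topk_adjacency <- function(G, k) {
  N <- nrow(G)
  k <- as.integer(k)
  if (k < 1L || k > N - 1L)
    stop(sprintf("topk_adjacency: K must be in [1, N-1] = [1, %d]", N - 1L),
         call. = FALSE)
  A <- matrix(0, N, N, dimnames = dimnames(G))
  for (i in seq_len(N)) {
    d <- G[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(N))[seq_len(k)]  # ties -> smaller index first
    A[i, nb] <- 1
  }
  A
}

#' Build a sparse relation graph with self-loops and symmetric normalization
#'
#' Adds self-loops to the adjacency (`A_tilde = A + I`), forms the diagonal
#' degree matrix `M_tilde` of row degrees of `A_tilde`, and the propagation
#' matrix `P = M_tilde^{-1/2} A_tilde M_tilde^{-1/2}` used by the graph
#' convolution layers. Optionally the binary edges can be weighted by a
#' Gaussian kernel of the DTW distance before normalization.
#'
#' @param A Binary `N x N` adjacency with zero diagonal (from
#'   [topk_adjacency()]).
#' @param k Number of neighbours used to build `A` (stored as metadata).
#' @param G Optional distance matrix; required when `weighting = "gaussian"`.
#' @param weighting `"binary"` (default) or `"gaussian"` edge weights
#'   `exp(-d^2 / (2 sigma^2))` with `sigma` = mean off-diagonal distance.
#' @return An `srgraph`: list with `n_nodes`, `k`, `edges` (two-column
#'   matrix), `A`, `A_tilde`, `degrees`, `P`.
#' @export
build_srgraph <- function(A, k, G = NULL, weighting = c("binary", "gaussian")) {
  weighting <- match.arg(weighting)
  N <- nrow(A)
  if (!isTRUE(all(A %in% c(0, 1))))
    stop("build_srgraph: adjacency must be binary", call. = FALSE)
  if (any(diag(A) != 0))
    stop("build_srgraph: adjacency diagonal must be zero", call. = FALSE)
  W <- A
  if (weighting == "gaussian") {
    if (is.null(G)) stop("build_srgraph: gaussian weighting needs G", call. = FALSE)
    sigma <- mean(G[upper.tri(G)])
    if (sigma <= 0) sigma <- 1
    W <- A * exp(-G^2 / (2 * sigma^2))
  }
  A_tilde <- W + diag(N)
  deg <- rowSums(A_tilde)
  inv_sqrt <- 1 / sqrt(deg)
  P <- A_tilde * (inv_sqrt %o% inv_sqrt)  # D^{-1/2} A~ D^{-1/2}
  edges <- which(A > 0, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("src", "dst")
  structure(list(n_nodes = N, k = as.integer(k), edges = edges, A = A,
                 A_tilde = A_tilde, degrees = deg, P = P,
                 weighting = weighting, node_ids = rownames(A)),
            class = "srgraph")
}

#' @export
print.srgraph <- function(x, ...) {
  cat(sprintf("<srgraph: %d nodes, K=%d, %d directed edges, %s weights>\n",
              x$n_nodes, x$k, nrow(x$edges), x$weighting))
  invisible(x)
}

#' Construct the relation graph straight from a cohort's training series
#'
#' Convenience wrapper: per-record min-max normalization of the training
#' portions, pairwise DTW, top-K selection, normalized propagation matrix.
#'
#' @param records List of [cgm_record()] objects.
#' @param k Neighbours per node.
#' @param test_points Trailing points excluded from the graph (test horizon).
#' @param window Window length used by the matching split (history prefix).
#' @param weighting,band Passed to [build_srgraph()] / [distance_matrix()].
#' @return An `srgraph`.
#' @export
cohort_srgraph <- function(records, k, test_points = 0L, window = 1L,
                           weighting = "binary", band = NULL) {
  series <- lapply(records, function(r) {
    tr <- train_test_split(r, test_points, window)$train
    minmax_normalize(tr)$values
  })
  names(series) <- vapply(records, `[[`, character(1), "patient_id")
  G <- distance_matrix(series, band)
  build_srgraph(topk_adjacency(G, k), k, G = G, weighting = weighting)
}

#' Persist / load a relation graph as edge-list TSV + metadata JSON
#'
#' The edge list (`src`, `dst`, `weight` columns) and a JSON sidecar
#' (`<path>.meta.json`: N, K, weighting, node ids) round-trip the graph.
#'
#' @param graph An `srgraph`.
#' @param path TSV file path.
#' @return `write_srgraph`: the path, invisibly; `read_srgraph`: an `srgraph`.
#' @export
write_srgraph <- function(graph, path) {
  w <- graph$A_tilde - diag(graph$n_nodes)
  df <- data.frame(src = graph$edges[, 1], dst = graph$edges[, 2],
                   weight = w[graph$edges])
  con <- file(path, "w")
  writeLines(artifact_header(), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  meta <- list(n_nodes = graph$n_nodes, k = graph$k,
               weighting = graph$weighting,
               node_ids = if (is.null(graph$node_ids)) NULL else graph$node_ids)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_srgraph
#' @export
read_srgraph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  N <- meta$n_nodes
  A <- matrix(0, N, N)
  A[cbind(df$src, df$dst)] <- 1
  if (!is.null(meta$node_ids)) dimnames(A) <- list(meta$node_ids, meta$node_ids)
  g <- build_srgraph(A, meta$k, weighting = "binary")
  if (meta$weighting == "gaussian") {
    W <- matrix(0, N, N)
    W[cbind(df$src, df$dst)] <- df$weight
    A_tilde <- W + diag(N)
    deg <- rowSums(A_tilde)
    inv_sqrt <- 1 / sqrt(deg)
    g$A_tilde <- A_tilde
    g$degrees <- deg
    g$P <- A_tilde * (inv_sqrt %o% inv_sqrt)
    g$weighting <- "gaussian"
  }
  g
}
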