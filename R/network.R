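#' Build the per-second adjacency matrix from shared frequencies
#'
#' Channels i and j (i != j) are connected iff their significant-frequency
#' sets for that second intersect. The diagonal entry of a channel is 1 iff
#' at least one oscillation was detected in it that second, 0 otherwise.
#'
#' @param peaks a `peak_set` from [significant_frequencies()].
#' @param window window (second) index.
#' @return 19 x 19 binary matrix in montage order, class `adjacency_matrix`.
#' @export
build_adjacency <- function(peaks, window = 1) {
  P <- peaks[window, , , drop = TRUE] * 1L       # channel x bin
  if (is.null(dim(P))) P <- matrix(P, nrow = dim(peaks)[2])
  S <- P %*% t(P)
  adj <- (S > 0) * 1L
  diag(adj) <- as.integer(rowSums(P) > 0)
  dimnames(adj) <- list(dimnames(peaks)[[2]], dimnames(peaks)[[2]])
  class(adj) <- c("adjacency_matrix", class(adj))
  adj
}

#' Adjacency matrices for every second of an epoch
#'
#' @param peaks a `peak_set`.
#' @return List of [build_adjacency()] matrices, one per window.
#' @export
adjacency_series <- function(peaks) {
  lapply(seq_len(dim(peaks)[1]), function(w) build_adjacency(peaks, w))
}

# nodes "present in a network": >= 1 off-diagonal connection
.present_nodes <- function(adj) {
  A <- unclass(adj) * 1
  diag(A) <- 0
  which(rowSums(A) > 0)
}

#' Network size
#'
#' Number of electrodes present in the network, i.e. with at least one
#' inter-electrode connection. A lone oscillating electrode (diagonal entry
#' only) is not part of a network.
#'
#' @param adj an adjacency matrix.
#' @return Integer count in 0..19.
#' @export
network_size <- function(adj) length(.present_nodes(adj))

#' Count connections
#'
#' Number of nonzero entries of the full matrix (ordered pairs plus
#' diagonal; maximum 361 for 19 channels), matching the published counting.
#' The undirected edge count m = (count - trace) / 2 feeds the graph
#' algorithms and the random reference.
#'
#' @param adj an adjacency matrix.
#' @return List with `n_connections` (full count) and `m` (undirected edges).
#' @export
count_connections <- function(adj) {
  A <- unclass(adj) * 1
  total <- sum(A != 0)
  tr <- sum(diag(A) != 0)
  list(n_connections = total, m = (total - tr) / 2)
}

#' Clustering coefficient (Watts-Strogatz, present-node average)
#'
#' For each present node with degree k >= 2, the fraction of its k(k-1)/2
#' neighbour pairs that are themselves connected; nodes with k < 2 contribute
#' 0. The average is taken over present nodes only. Degenerate networks
#' (size < 2) return 0.
#'
#' @param adj an adjacency matrix (diagonal ignored).
#' @return C_raw in [0, 1].
#' @export
clustering_coefficient <- function(adj) {
  p <- .present_nodes(adj)
  if (length(p) < 2) return(0)
  A <- unclass(adj) * 1
  diag(A) <- 0
  A <- A[p, p, drop = FALSE]
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  loc <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  mean(loc)
}

# all-pairs shortest paths by vectorized Floyd-Warshall; fine for n <= 19
.shortest_paths <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

#' Average path length (reachable present-node pairs)
#'
#' Mean shortest-path distance over all ordered pairs of present nodes,
#' excluding unreachable pairs (disconnected components). Degenerate
#' networks (size < 2) return 1 by convention.
#'
#' @param adj an adjacency matrix (diagonal ignored).
#' @return L_raw >= 1, or the degenerate convention value 1.
#' @export
average_path_length <- function(adj) {
  p <- .present_nodes(adj)
  if (length(p) < 2) return(1)
  A <- unclass(adj) * 1
  diag(A) <- 0
  D <- .shortest_paths(A[p, p, drop = FALSE])
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(1)
  mean(d)
}

#' Random-graph reference for C and L
#'
#' Averages the clustering coefficient and average path length over `n_rand`
#' graphs drawn uniformly from G(n, m) — all graphs with exactly n nodes and
#' m edges — using the same present-node conventions as the raw metrics.
#' Seeded and reproducible.
#'
#' @param n node count (>= 2).
#' @param m undirected edge count (0 <= m <= n(n-1)/2).
#' @param n_rand number of random graphs.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return Named vector `c(C = mean C_rand, L = mean L_rand)`.
#' @export
random_reference <- function(n, m, n_rand = 50, seed = NULL) {
  if (!.is_count(n) || n < 2) .stopf("random reference requires n >= 2")
  n_pairs <- n * (n - 1) / 2
  if (!.is_count(m) || m > n_pairs)
    .stopf("impossible edge count m = %s for n = %d nodes", format(m), n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  .with_seed(seed, {
    cs <- ls <- numeric(n_rand)
    for (r in seq_len(n_rand)) {
      A <- matrix(0L, n, n)
      if (m > 0) {
        e <- pairs[sample.int(n_pairs, m), , drop = FALSE]
        A[e] <- 1L
        A[e[, c(2, 1), drop = FALSE]] <- 1L
      }
      cs[r] <- clustering_coefficient(A)
      ls[r] <- average_path_length(A)
    }
    c(C = mean(cs), L = mean(ls))
  })
}

#' All network metrics of one adjacency matrix
#'
#' Computes size, connection counts, raw C and L, their ratios to the G(n,m)
#' random reference, and both small-world indices: SWI = C_rel / L_rel
#' (random-graph normalized) and SWI_raw = C_raw / L_raw. Conventions:
#' degenerate networks (size < 2) give C_raw = 0, L_raw = 1, SWI = SWI_raw
#' = 0, with C_rel and L_rel flagged missing (no reference exists); C_rel is
#' also missing when the reference clustering averages 0.
#'
#' @param adj an adjacency matrix.
#' @param n_rand random graphs per reference.
#' @param seed seed for the reference draw.
#' @param cache optional environment memoising references by (n, m); pass the
#'   same environment across seconds of an epoch to reuse draws.
#' @return Object of class `network_metrics` (named list).
#' @export
network_metrics <- function(adj, n_rand = 50, seed = NULL, cache = NULL) {
  cc <- count_connections(adj)
  size <- network_size(adj)
  C_raw <- clustering_coefficient(adj)
  L_raw <- average_path_length(adj)
  if (size < 2) {
    out <- list(network_size = size, n_connections = cc$n_connections,
                m = cc$m, C_raw = 0, L_raw = 1, C_rel = NA_real_,
                L_rel = NA_real_, SWI = 0, SWI_raw = 0)
    class(out) <- "network_metrics"
    return(out)
  }
  key <- sprintf("%d_%d", size, cc$m)
  ref <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
    r <- random_reference(size, cc$m, n_rand = n_rand, seed = seed)
    if (!is.null(cache)) cache[[key]] <- r
    r
  }
  C_rel <- if (ref["C"] > 0) C_raw / ref["C"] else NA_real_
  L_rel <- if (ref["L"] > 0) L_raw / ref["L"] else NA_real_
  out <- list(network_size = size, n_connections = cc$n_connections,
              m = cc$m, C_raw = C_raw, L_raw = L_raw,
              C_rel = unname(C_rel), L_rel = unname(L_rel),
              SWI = unname(if (is.na(C_rel) || is.na(L_rel)) NA_real_
                           else C_rel / L_rel),
              SWI_raw = C_raw / L_raw)
  class(out) <- "network_metrics"
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> size %s, connections %s (m = %s)\n  C_raw %.3f  L_raw %.3f  C_rel %.3f  L_rel %.3f  SWI %.3f  SWI_raw %.3f\n",
    format(x$network_size), format(x$n_connections), format(x$m),
    x$C_raw, x$L_raw, x$C_rel, x$L_rel, x$SWI, x$SWI_raw))
  invisible(x)
}

.metric_names <- c("network_size", "n_connections", "m", "C_raw", "L_raw",
                   "C_rel", "L_rel", "SWI", "SWI_raw")

#' Average per-second metrics over an epoch
#'
#' Arithmetic mean of each metric over the seconds of the epoch, skipping
#' flagged-missing values metric by metric; a metric missing in every second
#' stays missing for the epoch.
#'
#' @param metric_list list of `network_metrics`, one per second.
#' @return One-row data.frame of epoch-mean metrics.
#' @export
epoch_metrics <- function(metric_list) {
  stopifnot(length(metric_list) >= 1)
  M <- vapply(metric_list, function(m) unlist(m[.metric_names]),
              numeric(length(.metric_names)))
  means <- rowMeans(M, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  as.data.frame(as.list(means))
}

#' Analyze one epoch end-to-end
#'
#' Spectra, significance criteria, per-second adjacency and metrics, epoch
#' averaging — the per-epoch core of the pipeline.
#'
#' @param rec an [eeg_recording()] epoch.
#' @param criteria a [criteria_config()].
#' @param n_rand random graphs per reference.
#' @param seed seed for reference draws.
#' @param cache optional memoisation environment (see [network_metrics()]).
#' @return One-row data.frame of epoch-mean metrics.
#' @export
analyze_epoch <- function(rec, criteria = criteria_config(), n_rand = 50,
                          seed = NULL, cache = NULL) {
  sp <- windowed_spectra(rec)
  pk <- significant_frequencies(sp, criteria)
  adjs <- adjacency_series(pk)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ms <- lapply(adjs, network_metrics, n_rand = n_rand, seed = seed,
               cache = cache)
  epoch_metrics(ms)
}
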