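# Independent, loop-based oracles used to cross-check the vectorized
# implementations. Deliberately naive.

# Watts-Strogatz clustering by explicit neighbour-pair counting over nodes
# with at least one connection; nodes with degree < 2 contribute 0.
oracle_clustering <- function(adj) {
  A <- unclass(adj) * 1
  diag(A) <- 0
  present <- which(rowSums(A) > 0)
  if (length(present) < 2) return(0)
  vals <- numeric(0)
  for (i in present) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { vals <- c(vals, 0); next }
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) links <- links + 1
    vals <- c(vals, links / (k * (k - 1) / 2))
  }
  mean(vals)
}

# average shortest path over reachable ordered present-node pairs by
# breadth-first search; 1 for degenerate networks
oracle_path_length <- function(adj) {
  A <- unclass(adj) * 1
  diag(A) <- 0
  present <- which(rowSums(A) > 0)
  if (length(present) < 2) return(1)
  dists <- numeric(0)
  for (s in present) {
    d <- rep(NA_real_, nrow(A))
    d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] > 0))
        if (is.na(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
      frontier <- nxt
    }
    for (t in setdiff(present, s)) if (!is.na(d[t])) dists <- c(dists, d[t])
  }
  if (length(dists) == 0) return(1)
  mean(dists)
}

# loop-based evaluation of the three significance criteria on a raw
# amplitude array (window x channel x bin over freqs 0..fmax)
oracle_criteria <- function(A, freqs, ratio_local = 0.05, ratio_max = 0.5,
                            neighborhood_s = 2, floor = 0) {
  sel <- which(freqs >= 1 & freqs <= 25)
  n_win <- dim(A)[1]; n_ch <- dim(A)[2]
  out <- array(FALSE, dim = c(n_win, n_ch, length(sel)))
  for (t in seq_len(n_win)) for (c in seq_len(n_ch)) {
    wmax <- max(A[t, c, sel])
    for (bi in seq_along(sel)) {
      b <- sel[bi]
      nb_t <- max(1, t - neighborhood_s):min(n_win, t + neighborhood_s)
      ca <- A[t, c, b] >= ratio_local * max(A[nb_t, c, b])
      cb <- A[t, c, b] >= ratio_max * wmax
      cc <- A[t, c, b] > A[t, c, b - 1] && A[t, c, b] > A[t, c, b + 1] &&
            A[t, c, b] > A[t, c, b - 2] && A[t, c, b] > A[t, c, b + 2]
      cf <- floor <= 0 || A[t, c, b] >= floor
      out[t, c, bi] <- ca && cb && cc && cf
    }
  }
  out
}

# adjacency by explicit pairwise set intersection
oracle_adjacency <- function(freq_sets) {
  n <- length(freq_sets)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) adj[i, i] <- as.integer(length(freq_sets[[i]]) > 0)
    else if (length(intersect(freq_sets[[i]], freq_sets[[j]])) > 0)
      adj[i, j] <- 1L
  }
  adj
}

# all undirected graphs on n nodes as adjacency matrices (2^choose(n,2))
enumerate_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  lapply(0:(2^np - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(np)]
    A <- matrix(0L, n, n)
    on <- which(bits == 1L)
    A[pairs[on, , drop = FALSE]] <- 1L
    A[pairs[on, c(2, 1), drop = FALSE]] <- 1L
    A
  })
}

# build a peak_set array from a list of per-channel frequency vectors
# (one window), repeated over n_win windows
make_peaks <- function(freq_by_channel, n_win = 1) {
  labs <- montage_1020()
  freqs <- seq(1, 25, by = 0.5)
  pk <- array(FALSE, dim = c(n_win, 19, length(freqs)),
              dimnames = list(NULL, labs, freqs))
  for (ch in names(freq_by_channel)) {
    pk[, ch, match(freq_by_channel[[ch]], freqs)] <- TRUE
  }
  structure(pk, freqs = freqs, class = "peak_set")
}

# random small adjacency matrix (possibly with isolated nodes)
random_adj <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A), arr.ind = TRUE)
  on <- up[stats::runif(nrow(up)) < p, , drop = FALSE]
  A[on] <- 1L
  A[on[, c(2, 1), drop = FALSE]] <- 1L
  A
}
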