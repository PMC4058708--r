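adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1L; A[e[2], e[1]] <- 1L }
  A
}

test_that("shared frequencies build the documented adjacency matrices", {
  # channels A,B share 10 Hz; C oscillates alone at 4 Hz
  pk <- make_peaks(list(Fp1 = 10, Fp2 = 10, F7 = 4))
  adj <- build_adjacency(pk, 1)
  cc <- count_connections(adj)
  expect_equal(cc$n_connections, 5)    # A-B both directions + 3 diagonals
  expect_equal(cc$m, 1)
  expect_equal(network_size(adj), 2)   # the lone oscillator is not a network
  expect_equal(adj["Fp1", "Fp2"], 1L)
  expect_equal(adj["F7", "F7"], 1L)
  expect_equal(sum(adj), 5)

  full <- build_adjacency(make_peaks(
    setNames(rep(list(10), 19), montage_1020())), 1)
  expect_equal(count_connections(full)$n_connections, 361)
  expect_equal(network_size(full), 19)

  empty <- build_adjacency(make_peaks(list()), 1)
  expect_true(all(empty == 0))
  expect_equal(network_size(empty), 0)
})

test_that("adjacency construction matches brute-force set intersection", {
  set.seed(5)
  labs <- montage_1020()
  for (rep in 1:10) {
    sets <- lapply(seq_len(19), function(i)
      sample(seq(1, 25, 0.5), rpois(1, 1.5)))
    names(sets) <- labs
    pk <- make_peaks(sets[lengths(sets) > 0])
    expect_equal(unname(unclass(build_adjacency(pk, 1))) * 1L,
                 oracle_adjacency(sets))
  }
})

test_that("clustering coefficient follows the neighbour-of-neighbour definition", {
  tri <- adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(clustering_coefficient(tri), 1)
  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(clustering_coefficient(star), 0)
  g5 <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5)))
  expect_equal(clustering_coefficient(g5), oracle_clustering(g5))
})

test_that("average path length averages reachable pairs and honours conventions", {
  expect_equal(average_path_length(adj_from_edges(4, list(c(1,2), c(1,3),
    c(1,4), c(2,3), c(2,4), c(3,4)))), 1)              # complete
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(average_path_length(path3), 4 / 3)      # bfs hand computation
  expect_equal(average_path_length(matrix(0L, 5, 5)), 1)  # degenerate
  # two disconnected edges: unreachable pairs excluded
  two <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  expect_equal(average_path_length(two), 1)
})

test_that("metrics are invariant under channel relabeling", {
  set.seed(8)
  for (rep in 1:10) {
    A <- random_adj(12, 0.3)
    p <- sample(12)
    B <- A[p, p]
    expect_equal(clustering_coefficient(A), clustering_coefficient(B))
    expect_equal(average_path_length(A), average_path_length(B))
    expect_equal(network_size(A), network_size(B))
    expect_equal(count_connections(A), count_connections(B))
  }
})

test_that("raw metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:20) {
    A <- random_adj(10, 0.35)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    present <- which(igraph::degree(g) > 0)
    if (length(present) < 2) next
    # igraph local transitivity on present nodes, NaN (deg<2) -> 0
    loc <- igraph::transitivity(g, type = "local", vids = present)
    loc[is.nan(loc)] <- 0
    expect_equal(clustering_coefficient(A), mean(loc))
    D <- igraph::distances(g)[present, present]
    d <- D[row(D) != col(D)]
    expect_equal(average_path_length(A), mean(d[is.finite(d)]))
  }
})

test_that("the random reference reproduces known closed-form cases", {
  expect_equal(unname(random_reference(5, 10, n_rand = 5, seed = 1)), c(1, 1))
  expect_equal(unname(random_reference(4, 0, n_rand = 5, seed = 1)), c(0, 1))
  expect_error(random_reference(1, 0), "n >= 2")
  expect_error(random_reference(4, 7), "impossible")
  r1 <- random_reference(8, 12, n_rand = 20, seed = 3)
  r2 <- random_reference(8, 12, n_rand = 20, seed = 3)
  expect_identical(r1, r2)
})

test_that("the random reference converges to the exhaustive G(n,m) average", {
  # exhaustive oracle: average C and L over all graphs with 6 nodes, 7 edges
  pairs <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  combos <- utils::combn(nrow(pairs), 7)
  cs <- ls <- numeric(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    A <- matrix(0L, 6, 6)
    e <- pairs[combos[, i], , drop = FALSE]
    A[e] <- 1L; A[e[, c(2, 1)]] <- 1L
    cs[i] <- oracle_clustering(A)
    ls[i] <- oracle_path_length(A)
  }
  ref <- random_reference(6, 7, n_rand = 400, seed = 7)
  expect_equal(unname(ref["C"]), mean(cs), tolerance = 0.05)
  expect_equal(unname(ref["L"]), mean(ls), tolerance = 0.05)
})

test_that("normalized metrics honour the degenerate and self-normalizing cases", {
  lone <- matrix(0L, 19, 19); lone[1, 1] <- 1L
  m <- network_metrics(lone, seed = 1)
  expect_equal(m$network_size, 0)
  expect_equal(m$C_raw, 0)
  expect_equal(m$L_raw, 1)
  expect_equal(m$SWI, 0)
  expect_equal(m$SWI_raw, 0)
  expect_true(is.na(m$C_rel) && is.na(m$L_rel))

  # complete graph: its own random reference
  K6 <- adj_from_edges(6, utils::combn(6, 2, simplify = FALSE))
  mk <- network_metrics(K6, n_rand = 10, seed = 2)
  expect_equal(mk$C_rel, 1)
  expect_equal(mk$L_rel, 1)
  expect_equal(mk$SWI, 1)
  expect_equal(mk$SWI_raw, 1)
  expect_equal(mk$SWI_raw, mk$C_raw / mk$L_raw)
})

test_that("epoch averaging skips missing values metric by metric", {
  full <- build_adjacency(make_peaks(
    setNames(rep(list(10), 19), montage_1020())), 1)
  zero <- matrix(0L, 19, 19)
  mf <- network_metrics(full, n_rand = 5, seed = 1)
  mz <- network_metrics(zero, n_rand = 5, seed = 1)

  same <- epoch_metrics(list(mf, mf, mf))
  expect_equal(same$network_size, 19)
  expect_equal(same$C_rel, mf$C_rel)

  alt <- epoch_metrics(list(mf, mz, mf, mz))
  expect_equal(alt$network_size, 9.5)
  expect_equal(alt$SWI, mean(c(mf$SWI, 0, mf$SWI, 0)))
  expect_equal(alt$C_rel, mf$C_rel)     # degenerate seconds skipped

  only <- epoch_metrics(c(list(mf), rep(list(mz), 9)))
  expect_equal(only$C_rel, mf$C_rel)
  allz <- epoch_metrics(list(mz, mz))
  expect_true(is.na(allz$C_rel))
  expect_equal(allz$SWI, 0)
})

test_that("reference-normalized metrics are calibrated on G(n,m) draws", {
  set.seed(31)
  crels <- lrels <- numeric(40)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(40)) {
    A <- adj_from_edges(12, sample(utils::combn(12, 2, simplify = FALSE), 20))
    m <- network_metrics(A, n_rand = 100, seed = 17, cache = cache)
    crels[i] <- m$C_rel; lrels[i] <- m$L_rel
  }
  expect_equal(mean(crels, na.rm = TRUE), 1, tolerance = 0.15)
  expect_equal(mean(lrels, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("noise-free planted epochs recover their expected adjacency", {
  spec <- pattern_spec("normal", list(
    oscillator_spec(6, 30, c("Fp1", "Fp2", "F3")),
    oscillator_spec(10, 30, c("O1", "O2")),
    oscillator_spec(8.5, 25, c("C3", "C4", "Cz"))),
    noise_sd = 0, duration = 12, seed = 1)
  ep <- generate_epoch(spec)
  pk <- significant_frequencies(windowed_spectra(ep$recording))
  hits <- vapply(adjacency_series(pk), function(a)
    identical(unname(unclass(a)) * 1L,
              unname(ep$truth$expected_adjacency)), logical(1))
  expect_gte(mean(hits), 0.99)
})
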