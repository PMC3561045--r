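test_that("nearest-neighbour sets are correct on hand-checkable cases", {
  # collinear birds at x = 0, 1, 3: distances force N = {2}, {1}, {2}
  line <- flock_snapshot(cbind(c(0, 1, 3), 0, 0))
  kn <- knn_neighbors(line, 1)
  expect_identical(as.vector(kn$idx), c(2L, 1L, 2L))
  expect_equal(as.vector(kn$dist), c(1, 1, 2))

  # m = N-1: every node's set is all the others
  snap <- random_snapshot(8, seed = 2)
  kn <- knn_neighbors(snap, 7)
  for (i in 1:8) expect_setequal(kn$idx[i, ], setdiff(1:8, i))
})

test_that("k-NN matches a brute-force all-pairs oracle", {
  snap <- random_snapshot(100, seed = 5)
  x <- snap$positions
  kn <- knn_neighbors(snap, 7)
  for (i in c(1, 17, 50, 100)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    d[i] <- Inf
    expect_identical(kn$idx[i, ], order(d)[1:7])
  }
  # no non-neighbour may be closer than the furthest chosen neighbour
  d_all <- as.matrix(dist(x))
  for (i in 1:100) {
    rest <- setdiff(1:100, c(i, kn$idx[i, ]))
    expect_lte(kn$dist[i, 7], min(d_all[i, rest]))
  }
})

test_that("k-NN input validation", {
  snap <- random_snapshot(10, seed = 1)
  expect_error(knn_neighbors(snap, 10), "m exceeds N-1")
  expect_error(knn_neighbors(snap, 0), "at least 1")
  dup <- flock_snapshot(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(2, 1, 0)))
  expect_error(knn_neighbors(dup, 1), "coincident positions")
})

test_that("edge weighting schemes are normalised and match closed forms", {
  expect_equal(as.vector(edge_weights(matrix(runif(4), 1), "equal")),
               rep(0.25, 4))
  expect_equal(as.vector(edge_weights(matrix(c(1, 3), 1), "inverse_distance")),
               c(0.75, 0.25))
  # order-linear, m = 3: weights 2(m+1-k)/(m(m+1)) = 1/2, 1/3, 1/6
  expect_equal(as.vector(edge_weights(matrix(c(0.5, 1, 7), 1), "order_linear")),
               c(1/2, 1/3, 1/6))
  # per-node sums are 1 under every scheme
  dm <- withr::with_seed(3, matrix(runif(50, 0.1, 2), 10))
  for (s in c("equal", "inverse_distance", "order_linear"))
    expect_equal(rowSums(edge_weights(dm, s)), rep(1, 10), tolerance = 1e-12)
  expect_error(edge_weights(matrix(c(0, 1), 1), "inverse_distance"),
               "zero distance")
})

test_that("Laplacian assembly satisfies its defining identities", {
  # two birds sensing each other with weight 1
  pair <- flock_snapshot(rbind(c(0, 0, 0), c(1, 0, 0)))
  L <- graph_laplacian(sensing_graph(pair, 1))
  expect_equal(L, rbind(c(1, -1), c(-1, 1)))

  snap <- random_snapshot(40, seed = 9)
  g <- sensing_graph(snap, 5, "inverse_distance")
  L <- graph_laplacian(g)
  expect_equal(rowSums(L), rep(0, 40), tolerance = 1e-12)
  offdiag <- L - diag(diag(L))
  expect_true(all(offdiag <= 0))

  # complete graph N = 5, equal weights: eigenvalues {0, 1.25 x4}
  c5 <- random_snapshot(5, seed = 4)
  ev <- sort(eigen(graph_laplacian(sensing_graph(c5, 4)),
                   only.values = TRUE)$values)
  expect_equal(Re(ev), c(0, rep(1.25, 4)), tolerance = 1e-10)
})

test_that("the disagreement projector Q is a valid orthonormal completion", {
  for (n in c(2, 3, 17, 100)) {
    q <- consensus_projector(n)
    expect_equal(q %*% t(q), diag(n - 1), tolerance = 1e-12)
    expect_equal(as.vector(q %*% rep(1, n)), rep(0, n - 1),
                 tolerance = 1e-12)
  }
})

test_that("consensus feasibility follows directed reachability", {
  # two far-apart mutual pairs: two sink components, infeasible
  pairs <- flock_snapshot(rbind(c(0, 0, 0), c(1, 0, 0),
                                c(50, 0, 0), c(51, 0, 0)))
  expect_false(is_consensus_feasible(sensing_graph(pairs, 1)))

  # star: everyone senses node 1 -> node 1 commonly reachable
  star <- matrix(0, 6, 6)
  star[2:6, 1] <- 1
  expect_true(is_consensus_feasible(star))

  # collinear 0, 1, 3 with m = 1: edges 1->2, 2->1, 3->2; sink SCC {1,2}
  line <- flock_snapshot(cbind(c(0, 1, 3), 0, 0))
  expect_true(is_consensus_feasible(sensing_graph(line, 1)))
})

test_that("graph-theoretic and spectral feasibility tests agree", {
  n_checked <- 0L
  for (s in 1:60) {
    n <- withr::with_seed(s, sample(4:12, 1))
    p <- withr::with_seed(s + 1000, runif(1, 0.08, 0.35))
    a <- random_digraph_adjacency(n, p, s)
    graph_test <- is_consensus_feasible(a)
    spec_test <- is_hurwitz_stable(laplacian_system(laplacian_of_adjacency(a)))
    expect_identical(graph_test, spec_test)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 60L)
})

test_that("neighbour sets are invariant under rigid motion and scaling", {
  snap <- random_snapshot(60, seed = 12, box = c(1, 0.7, 0.3))
  kn0 <- knn_neighbors(snap, 6)
  r <- random_rotation(3)
  moved <- flock_snapshot(sweep(snap$positions %*% t(r), 2, -c(5, 5, 5)) * 3)
  expect_identical(knn_neighbors(moved, 6)$idx, kn0$idx)
})

test_that("relabelling birds permutes the graph consistently", {
  snap <- random_snapshot(30, seed = 21)
  perm <- withr::with_seed(22, sample(30))
  permuted <- flock_snapshot(snap$positions[perm, ])
  g0 <- sensing_graph(snap, 4)
  g1 <- sensing_graph(permuted, 4)
  # edge i -> j in the permuted graph corresponds to perm[i] -> perm[j]
  inv <- order(perm)
  for (i in 1:30)
    expect_identical(perm[g1$neighbors[i, ]], g0$neighbors[perm[i], ])
  expect_identical(is_consensus_feasible(g0), is_consensus_feasible(g1))
})
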