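# Fixtures built in code: random point clouds, random graphs, and small
# independent oracles used across the suite.

random_snapshot <- function(n, seed, box = c(1, 1, 1), id = NULL) {
  id <- if (is.null(id)) paste0("rand_", seed) else id
  if (n >= 4)
    return(generate_flock(
      synthetic_flock_config(n_birds = n, distribution = "uniform",
                             box = box, seed = seed),
      snapshot_id = id))
  pts <- withr::with_seed(seed, matrix(runif(3 * n), n) %*% diag(box))
  flock_snapshot(pts, snapshot_id = id)
}

# Random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qrd <- qr(matrix(rnorm(9), 3, 3))
    r <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
    if (det(r) < 0) r[, 1] <- -r[, 1]
    r
  })
}

# Symmetric weighted Laplacian of a random connected undirected graph:
# a random spanning tree plus random extra edges, weights U(0.1, 1).
random_connected_laplacian <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    perm <- sample(n)
    for (k in 2:n) {
      i <- perm[k]
      j <- perm[sample(k - 1L, 1L)]
      a[i, j] <- a[j, i] <- runif(1, 0.1, 1)
    }
    extra <- which(upper.tri(a) & a == 0)
    pick <- extra[runif(length(extra)) < 0.2]
    a[pick] <- runif(length(pick), 0.1, 1)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    diag(rowSums(a)) - a
  })
}

# Random weighted directed adjacency matrix (possibly disconnected).
random_digraph_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n, 0.2, 1) * (runif(n * n) < p), n, n)
    diag(a) <- 0
    a
  })
}

laplacian_of_adjacency <- function(a) diag(rowSums(a)) - a

# Independent small-n Lyapunov oracle: vec(X) from the Kronecker normal
# equations for A X + X A' = C. O(n^6); use only for tiny systems.
lyap_kron <- function(A, C = diag(nrow(A))) {
  n <- nrow(A)
  K <- diag(n) %x% A + A %x% diag(n)
  matrix(solve(K, as.vector(C)), n, n)
}

# Closed-form nodal robustness of the equal-weight complete graph.
complete_graph_robustness <- function(n) sqrt(2) * n / (n - 1)

# Alternative orthonormal completion of the all-ones direction, from a QR
# decomposition seeded independently of the package's Householder choice.
alt_projector <- function(n, seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(cbind(rep(1, n), matrix(rnorm(n * (n - 1)), n))))
    t(q[, 2:n, drop = FALSE])
  })
}
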