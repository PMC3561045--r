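test_that("the robustness curve matches small-N oracles at every m", {
  # 4 birds at square corners; at m = 3 the graph is complete so
  # rpn = (sqrt(2) * 4/3) / 3; every m checked against a Kronecker solve
  sq <- flock_snapshot(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  cu <- robustness_curve(sq, m_values = 1:3)
  expect_equal(cu$rpn[3], complete_graph_robustness(4) / 3, tolerance = 1e-10)
  for (k in 1:3) {
    g <- sensing_graph(sq, k)
    if (!is_consensus_feasible(g)) {
      expect_identical(cu$rpn[k], 0)
      next
    }
    sys <- build_laplacian(g)
    rob <- sqrt(4) / sqrt(sum(diag(lyap_kron(sys$L_reduced))))
    expect_equal(cu$rpn[k], rob / k, tolerance = 1e-10)
  }
  expect_equal(cu$peak, max(cu$rpn))
  expect_true(cu$band_90[1] <= cu$m_star && cu$m_star <= cu$band_90[2])
})

test_that("an all-infeasible snapshot yields a flagged degenerate curve", {
  pairs <- flock_snapshot(rbind(c(0, 0, 0), c(1, 0, 0),
                                c(50, 0, 0), c(51, 0, 0)))
  cu <- robustness_curve(pairs, m_values = 1L)
  expect_true(cu$degenerate)
  expect_identical(cu$rpn, 0)
  expect_identical(cu$m_star, 1L)
})

test_that("the 90% band contains m* and the peak survives grid extension", {
  snap <- random_snapshot(80, seed = 14, box = c(1, 1, 0.5))
  short <- robustness_curve(snap, m_values = 1:8)
  long <- robustness_curve(snap, m_values = 1:12)
  expect_true(short$band_90[1] <= short$m_star &&
              short$m_star <= short$band_90[2])
  if (short$m_star < 8) {
    expect_identical(long$m_star, short$m_star)
    expect_equal(long$peak, short$peak, tolerance = 1e-12)
  }
})

test_that("argmax ties break toward the smaller m", {
  cu <- flocknet:::new_robustness_curve("tie", 1:4, c(0, 0.3, 0.3, 0.1))
  expect_identical(cu$m_star, 2L)
  expect_identical(cu$band_90, c(2L, 3L))
})

test_that("aggregation modes weight flocks versus snapshots as defined", {
  mk <- function(id, vals) flocknet:::new_robustness_curve(id, 1:3, vals)
  curves <- list(mk("a_1", c(0, 1, 2)), mk("b_1", c(0, 3, 6)),
                 mk("b_2", c(0, 5, 10)), mk("b_3", c(0, 7, 14)))
  flocks <- c("a", "b", "b", "b")
  pooled <- aggregate_curves(curves, "snapshot_pooled")
  by_flock <- aggregate_curves(curves, "flock_average", flocks = flocks)
  # pooled mean at m=2: (1+3+5+7)/4 = 4; flock mean: (1 + 5)/2 = 3
  expect_equal(pooled$mean, c(0, 4, 8))
  expect_equal(by_flock$mean, c(0, 3, 6))
  expect_identical(pooled$n_units, 4L)
  expect_identical(by_flock$n_units, 2L)
  expect_equal(pooled$se, pooled$sd / 2, tolerance = 1e-12)
  # identical curves: zero spread, mean equals the curve
  same <- aggregate_curves(list(mk("x", c(1, 2, 3)), mk("y", c(1, 2, 3))))
  expect_equal(same$mean, c(1, 2, 3))
  expect_equal(same$sd, c(0, 0, 0))
  # equal-sized flocks: the two modes coincide exactly
  eq <- aggregate_curves(curves[2:4][c(1, 2)], "flock_average",
                         flocks = c("u", "v"))
  eq2 <- aggregate_curves(curves[2:4][c(1, 2)], "snapshot_pooled")
  expect_equal(eq$mean, eq2$mean)
  expect_error(aggregate_curves(list(mk("a", c(1, 2, 3)),
                                     flocknet:::new_robustness_curve("b", 1:4, rep(1, 4)))),
               "mismatched m grids")
})

test_that("linear_fit reproduces closed-form least squares", {
  # hand-derived: {(0,0), (1,1), (2,1)} -> slope 1/2, intercept 1/6, R2 3/4
  f <- linear_fit(c(0, 1, 2), c(0, 1, 1))
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(f$r_squared, 0.75, tolerance = 1e-12)

  col <- linear_fit(1:5, 2 * (1:5) - 3)
  expect_equal(col$r_squared, 1, tolerance = 1e-12)
  flat <- linear_fit(1:4, rep(2.5, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_identical(flat$r_squared, 0)

  # normal-equations oracle on random data
  for (s in 1:5) {
    d <- withr::with_seed(s, list(x = rnorm(20), y = rnorm(20)))
    f <- linear_fit(d$x, d$y)
    X <- cbind(1, d$x)
    beta <- solve(crossprod(X), crossprod(X, d$y))
    expect_equal(c(f$intercept, f$slope), as.vector(beta), tolerance = 1e-10)
  }
  expect_error(linear_fit(rep(1, 5), 1:5), "constant x")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("size_experiment composes linear fits over (N, m*, peak) triples", {
  triples <- data.frame(n_birds = c(100, 200, 300, 400),
                        m_star = c(6, 6, 6, 6),
                        peak = c(0.1, 0.12, 0.11, 0.13))
  fits <- size_experiment(triples)
  expect_equal(fits$m_star_fit$slope, 0, tolerance = 1e-12)
  expect_identical(fits$m_star_fit$r_squared, 0)
  oracle <- linear_fit(triples$n_birds, triples$peak)
  expect_equal(fits$peak_fit$slope, oracle$slope, tolerance = 1e-12)
  expect_error(size_experiment(data.frame(a = 1)), "columns")
})

test_that("speed per neighbour of a complete graph is 1/(N-1)", {
  snap <- random_snapshot(9, seed = 77)
  sp <- speed_curve(snap, m_values = c(4L, 8L))
  expect_equal(sp$speed_pn[2], 1 / 8, tolerance = 1e-10)
  pairs <- flock_snapshot(rbind(c(0, 0, 0), c(1, 0, 0),
                                c(50, 0, 0), c(51, 0, 0)))
  expect_identical(speed_curve(pairs, m_values = 1L)$speed_pn, 0)
})

test_that("a full shape-experiment run is deterministic", {
  r1 <- shape_experiment(0.4, n_birds = 60, n_replicates = 3,
                         m_values = 1:6, seed = 9)
  r2 <- shape_experiment(0.4, n_birds = 60, n_replicates = 3,
                         m_values = 1:6, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(c("m_star", "peak", "band_lo", "band_hi") %in% names(r1)))
  expect_identical(nrow(attr(r1, "per_replicate")), 3L)
})
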