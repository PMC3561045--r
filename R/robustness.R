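# H2 steady-state disagreement and derived robustness metrics.
#
# Model: every bird integrates the weighted differences to its sensed
# neighbours plus i.i.d. white noise, x' = -L x + nu * xi. Projected onto
# the disagreement subspace (y = Q x) this is y' = -Lbar y + nu * Q xi.
# When -Lbar is Hurwitz the stationary covariance Sigma solves
#   Lbar Sigma + Sigma Lbar' = I        (unit noise intensity)
# and the steady-state disagreement (H2 norm) is nu * sqrt(trace(Sigma)).

#' Solve the Lyapunov equation A X + X A' = C
#'
#' Dense exact solve by the Schur (Bartels–Stewart) method via LAPACK.
#'
#' @param A square coefficient matrix with spectrum in the open right
#'   half-plane for a positive-definite stationary covariance.
#' @param C right-hand side; defaults to the identity.
#' @return The solution matrix X.
#' @export
lyap_solve <- function(A, C = diag(nrow(A))) {
  lyap_solve_cpp(as.matrix(A), as.matrix(C))
}

#' Steady-state disagreement (H2 norm) of noisy consensus dynamics
#'
#' Computes the stationary covariance of the disagreement vector by solving
#' the Lyapunov equation on the reduced Laplacian, and from it the H2 norm
#' (expected steady-state distance from consensus), the per-individual
#' disagreement, and its inverse, the nodal robustness. An infeasible
#' (disconnected) graph yields infinite disagreement and robustness exactly
#' 0.
#'
#' @param system a [laplacian_system()].
#' @param noise_intensity noise amplitude \eqn{\nu > 0} per bird; the H2 norm
#'   scales linearly in it. Default 1.
#' @param feasible optional logical short-circuit: pass the result of
#'   [is_consensus_feasible()] when the graph is available to skip the
#'   spectral stability test; `NULL` (default) decides via
#'   [is_hurwitz_stable()].
#' @return Object of class `disagreement_solution`: list with `sigma`
#'   (stationary covariance, `NULL` when infeasible), `h2_norm`,
#'   `nodal_disagreement` (= h2/sqrt(N)), `nodal_robustness`
#'   (= sqrt(N)/h2, 0 when infeasible), `noise_intensity`, `feasible`,
#'   `n_nodes`.
#' @examples
#' # complete graph on 4 nodes, equal weights: robustness = sqrt(2)*4/3
#' snap <- flock_snapshot(matrix(rnorm(12), ncol = 3))
#' sys <- build_laplacian(sensing_graph(snap, m = 3))
#' h2_disagreement(sys)$nodal_robustness
#' @export
h2_disagreement <- function(system, noise_intensity = 1, feasible = NULL) {
  if (!inherits(system, "laplacian_system"))
    stop("expected a 'laplacian_system'; see build_laplacian()")
  if (!is.numeric(noise_intensity) || noise_intensity <= 0)
    stop("noise_intensity must be a positive scalar")
  if (is.null(feasible)) feasible <- is_hurwitz_stable(system)
  n <- system$n_nodes
  if (!feasible) {
    return(new_disagreement(NULL, Inf, noise_intensity, FALSE, n))
  }
  lbar <- system$L_reduced
  sigma <- lyap_solve(lbar)
  resid <- lbar %*% sigma + sigma %*% t(lbar) - diag(nrow(lbar))
  if (max(abs(resid)) > 1e-6)
    stop("Lyapunov solve is ill-conditioned: residual ",
         format(max(abs(resid)), digits = 3),
         " despite a stable spectrum; reduced Laplacian is near-singular")
  sigma <- (sigma + t(sigma)) / 2
  h2 <- noise_intensity * sqrt(sum(diag(sigma)))
  new_disagreement(sigma, h2, noise_intensity, TRUE, n)
}

new_disagreement <- function(sigma, h2, nu, feasible, n) {
  structure(
    list(sigma = sigma, h2_norm = h2,
         nodal_disagreement = h2 / sqrt(n),
         nodal_robustness = if (feasible) sqrt(n) / h2 else 0,
         noise_intensity = nu, feasible = feasible, n_nodes = n),
    class = "disagreement_solution"
  )
}

#' @export
print.disagreement_solution <- function(x, ...) {
  cat("<disagreement_solution> N = ", x$n_nodes,
      ", feasible = ", x$feasible,
      ", H2 = ", format(x$h2_norm, digits = 6),
      ", nodal robustness = ", format(x$nodal_robustness, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Nodal robustness of an m-nearest-neighbour strategy
#'
#' Composes graph construction, Laplacian assembly and the Lyapunov solve:
#' the nodal robustness of the strategy "sense your m nearest neighbours
#' under the given weighting scheme" evaluated on one snapshot. Returns 0
#' when the sensing graph cannot support consensus (disconnected).
#'
#' @inheritParams sensing_graph
#' @param noise_intensity noise amplitude per bird (default 1).
#' @return A single non-negative number.
#' @export
nodal_robustness_for_strategy <- function(snapshot, m, scheme = "equal",
                                          noise_intensity = 1) {
  graph <- sensing_graph(snapshot, m, scheme)
  if (!is_consensus_feasible(graph)) return(0)
  h2_disagreement(build_laplacian(graph), noise_intensity,
                  feasible = TRUE)$nodal_robustness
}

#' Robustness per neighbour
#'
#' Nodal robustness divided by the number of neighbours m — the
#' cost-adjusted figure of merit whose maximiser over m is m*. Zero whenever
#' the sensing graph is disconnected.
#'
#' @inheritParams nodal_robustness_for_strategy
#' @return A single non-negative number.
#' @export
robustness_per_neighbor <- function(snapshot, m, scheme = "equal",
                                    noise_intensity = 1) {
  nodal_robustness_for_strategy(snapshot, m, scheme, noise_intensity) / m
}

#' Normalised convergence speed to consensus
#'
#' The exponential convergence rate of noise-free consensus is the real part
#' of the second-smallest Laplacian eigenvalue (the smallest is always 0);
#' equivalently the smallest real part of the reduced Laplacian's spectrum.
#' It is reported normalised by the complete-graph rate N/(N-1) under
#' sum-to-one weights, so that all-to-all sensing gives exactly 1.
#' Infeasible graphs return 0.
#'
#' @param system a [laplacian_system()].
#' @param feasible optional logical short-circuit as in [h2_disagreement()].
#' @return A single number in `[0, 1]` (0 when disconnected).
#' @export
convergence_speed <- function(system, feasible = NULL) {
  ev <- eigen(system$L_reduced, only.values = TRUE)$values
  scale <- max(abs(ev))
  rate <- min(Re(ev))
  if (is.null(feasible)) feasible <- scale > 0 && rate > 1e-9 * scale
  if (!feasible) return(0)
  n <- system$n_nodes
  rate / (n / (n - 1))
}
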