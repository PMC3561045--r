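# Sweeps over the number of neighbours m, curve aggregation and the
# size/shape ensemble experiments.

#' Robustness-per-neighbour curve of one snapshot
#'
#' Evaluates robustness per neighbour over a grid of m values (default 1-11)
#' and extracts the optimum m* (argmax, ties broken toward smaller m: fewer
#' neighbours cost less at equal robustness), the peak value, and the 90%
#' band — the smallest and largest m whose robustness per neighbour is
#' within 90% of the peak. Nearest-neighbour sets are computed once at the
#' largest m and reused (the m nearest neighbours are a prefix of the
#' max(m)-nearest ordering).
#'
#' @inheritParams nodal_robustness_for_strategy
#' @param m_values strictly increasing integer grid, all `< N`.
#' @param include_speed also compute normalised convergence speed per
#'   neighbour at each m (costs one eigendecomposition per feasible m).
#' @return Object of class `robustness_curve`: list with `snapshot_id`,
#'   `m_values`, `rpn` (robustness per neighbour), `speed_pn` (or `NULL`),
#'   `m_star`, `peak`, `band_90` (c(lo, hi)), `degenerate` (`TRUE` when the
#'   curve is all zero, i.e. no m in the grid gives a connected graph).
#'   Coerce with `as.data.frame()`.
#' @export
robustness_curve <- function(snapshot, m_values = 1:11, scheme = "equal",
                             noise_intensity = 1, include_speed = FALSE) {
  assert_snapshot(snapshot)
  m_values <- as.integer(m_values)
  if (is.unsorted(m_values, strictly = TRUE))
    stop("m_values must be strictly increasing")
  n <- n_birds(snapshot)
  if (max(m_values) > n - 1L) stop("m exceeds N-1")
  kn <- knn_internal(snapshot$positions, max(m_values))
  Q <- consensus_projector(n)
  rpn <- numeric(length(m_values))
  speed <- if (include_speed) numeric(length(m_values)) else NULL
  for (k in seq_along(m_values)) {
    m <- m_values[k]
    graph <- new_sensing_graph(kn$idx[, seq_len(m), drop = FALSE],
                               kn$dist[, seq_len(m), drop = FALSE],
                               scheme, snapshot$snapshot_id)
    if (!is_consensus_feasible(graph)) next
    sys <- laplacian_system(graph_laplacian(graph), Q = Q)
    sol <- h2_disagreement(sys, noise_intensity, feasible = TRUE)
    rpn[k] <- sol$nodal_robustness / m
    if (include_speed)
      speed[k] <- convergence_speed(sys, feasible = TRUE) / m
  }
  new_robustness_curve(snapshot$snapshot_id, m_values, rpn, speed)
}

new_robustness_curve <- function(snapshot_id, m_values, rpn,
                                 speed_pn = NULL) {
  peak <- max(rpn)
  i_star <- which.max(rpn)            # ties -> smallest m
  band <- if (peak > 0) range(m_values[rpn >= 0.9 * peak])
          else range(m_values)
  structure(
    list(snapshot_id = snapshot_id, m_values = m_values, rpn = rpn,
         speed_pn = speed_pn, m_star = m_values[i_star], peak = peak,
         band_90 = band, degenerate = peak <= 0),
    class = "robustness_curve"
  )
}

#' @export
as.data.frame.robustness_curve <- function(x, ...) {
  df <- data.frame(snapshot_id = x$snapshot_id, m = x$m_values,
                   rpn = x$rpn, stringsAsFactors = FALSE)
  if (!is.null(x$speed_pn)) df$speed_pn <- x$speed_pn
  df
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("<robustness_curve> '", x$snapshot_id, "': m = ",
      min(x$m_values), "..", max(x$m_values),
      if (x$degenerate) ", degenerate (all zero)" else
        paste0(", m* = ", x$m_star, ", peak = ", signif(x$peak, 5),
               ", 90% band = [", x$band_90[1L], ", ", x$band_90[2L], "]"),
      "\n", sep = "")
  invisible(x)
}

#' Aggregate robustness curves across snapshots or flocks
#'
#' Two averaging modes mirror the two natural units of observation:
#' `snapshot_pooled` treats every curve as an independent observation;
#' `flock_average` first averages the curves within each flock, then
#' averages the per-flock means (so flocks with many snapshots are not
#' over-weighted).
#'
#' @param curves list of [robustness_curve()]s sharing one m grid.
#' @param mode `"snapshot_pooled"` or `"flock_average"`.
#' @param flocks for `flock_average`, a vector of flock labels, one per
#'   curve.
#' @return Object of class `aggregate_curve`: list with `m_values`, `mean`,
#'   `sd`, `se` (= sd/sqrt(n_units)), `mode`, `n_units`.
#' @export
aggregate_curves <- function(curves,
                             mode = c("snapshot_pooled", "flock_average"),
                             flocks = NULL) {
  mode <- match.arg(mode)
  if (length(curves) < 1L) stop("no curves to aggregate")
  m_values <- curves[[1L]]$m_values
  same <- vapply(curves, function(cu) identical(cu$m_values, m_values),
                 logical(1L))
  if (!all(same)) stop("mismatched m grids across curves")
  mat <- vapply(curves, `[[`, numeric(length(m_values)), "rpn")
  mat <- matrix(mat, nrow = length(m_values))
  if (mode == "flock_average") {
    if (is.null(flocks) || length(flocks) != length(curves))
      stop("flock_average requires one flock label per curve")
    groups <- split(seq_along(curves), flocks)
    mat <- vapply(groups, function(ix)
      rowMeans(mat[, ix, drop = FALSE]), numeric(length(m_values)))
    mat <- matrix(mat, nrow = length(m_values))
  }
  k <- ncol(mat)
  sds <- apply(mat, 1L, stats::sd)
  structure(
    list(m_values = m_values, mean = rowMeans(mat), sd = sds,
         se = sds / sqrt(k), mode = mode, n_units = k),
    class = "aggregate_curve"
  )
}

#' @export
as.data.frame.aggregate_curve <- function(x, ...) {
  data.frame(m = x$m_values, mean = x$mean, sd = x$sd, se = x$se)
}

#' Ordinary least-squares line with R-squared
#'
#' @param x,y numeric vectors (at least 3 points; `x` must not be
#'   constant).
#' @return Object of class `linear_fit`: list with `slope`, `intercept`,
#'   `r_squared` (defined as 0 when y has no variance).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (diff(range(x)) == 0) stop("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit> slope = ", signif(x$slope, 6),
      ", intercept = ", signif(x$intercept, 6),
      ", R^2 = ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Shape experiment: m* and peak robustness versus flock thickness
#'
#' For each target thickness, generates an ensemble of synthetic flocks in a
#' box of that aspect ratio, computes each replicate's
#' robustness-per-neighbour curve, averages the curves across replicates,
#' and reports the optimum m*, peak and 90% band of the averaged curve plus
#' the standard deviation of per-replicate peaks.
#'
#' @param thickness_grid target thickness values in (0, 1].
#' @param distribution,n_birds,grid_noise_sd see
#'   [synthetic_flock_config()].
#' @param n_replicates flocks per thickness (100 at full scale).
#' @param m_values m grid (default 1:11).
#' @param scheme edge-weighting scheme.
#' @param width_ratio box width ratio (default 1).
#' @param seed base seed; each thickness uses an offset block of seeds.
#' @return data.frame with one row per thickness: `thickness_target`,
#'   `thickness_measured` (ensemble mean), `m_star`, `band_lo`, `band_hi`,
#'   `peak`, `peak_sd`, `n_replicates`, `degenerate`. The per-replicate m*
#'   and peak values are attached as attribute `"per_replicate"`.
#' @export
shape_experiment <- function(thickness_grid,
                             distribution = "uniform",
                             n_birds = 1200, n_replicates = 100,
                             m_values = 1:11, scheme = "equal",
                             width_ratio = 1, grid_noise_sd = 0.3,
                             seed = 1) {
  thickness_grid <- as.numeric(thickness_grid)
  if (any(thickness_grid <= 0 | thickness_grid > 1))
    stop("thickness grid must lie in (0, 1]")
  rows <- vector("list", length(thickness_grid))
  detail <- vector("list", length(thickness_grid))
  for (ti in seq_along(thickness_grid)) {
    t <- thickness_grid[ti]
    cfg <- synthetic_flock_config(
      n_birds = n_birds, distribution = distribution,
      box = box_for_thickness(t, width_ratio),
      grid_noise_sd = grid_noise_sd,
      seed = seed + 100000L * (ti - 1L))
    flocks <- replicate_ensemble(cfg, n_replicates)
    curves <- lapply(flocks, robustness_curve, m_values = m_values,
                     scheme = scheme)
    mat <- vapply(curves, `[[`, numeric(length(m_values)), "rpn")
    mat <- matrix(mat, nrow = length(m_values))
    avg <- new_robustness_curve(paste0("t", t), m_values, rowMeans(mat))
    rows[[ti]] <- data.frame(
      thickness_target = t,
      thickness_measured = mean(vapply(flocks, flock_thickness, numeric(1L))),
      m_star = avg$m_star, band_lo = avg$band_90[1L],
      band_hi = avg$band_90[2L], peak = avg$peak,
      peak_sd = stats::sd(apply(mat, 2L, max)),
      n_replicates = n_replicates, degenerate = avg$degenerate)
    detail[[ti]] <- data.frame(
      thickness_target = t,
      replicate = seq_len(n_replicates),
      m_star = vapply(curves, `[[`, numeric(1L), "m_star"),
      peak = vapply(curves, `[[`, numeric(1L), "peak"))
  }
  out <- do.call(rbind, rows)
  attr(out, "per_replicate") <- do.call(rbind, detail)
  out
}

#' Size experiment: does the optimum depend on flock size?
#'
#' Ordinary least-squares fits of m* and of peak robustness per neighbour
#' against flock size N, over per-snapshot observations.
#'
#' @param triples data.frame with columns `n_birds`, `m_star`, `peak`.
#' @return List with `m_star_fit` and `peak_fit`, both [linear_fit()]s.
#' @export
size_experiment <- function(triples) {
  req <- c("n_birds", "m_star", "peak")
  if (!all(req %in% names(triples)))
    stop("triples must have columns: ", paste(req, collapse = ", "))
  list(m_star_fit = linear_fit(triples$n_birds, triples$m_star),
       peak_fit = linear_fit(triples$n_birds, triples$peak))
}

#' Convergence-speed-per-neighbour curve
#'
#' Normalised convergence speed (see [convergence_speed()]) divided by m,
#' over a grid of m values. Unlike robustness per neighbour, this quantity
#' keeps increasing with m (no interior optimum), which is why sensing cost
#' trades off against robustness rather than responsiveness.
#'
#' @inheritParams robustness_curve
#' @return data.frame with columns `snapshot_id`, `m`, `speed_pn`.
#' @export
speed_curve <- function(snapshot, m_values = 1:11, scheme = "equal") {
  assert_snapshot(snapshot)
  m_values <- as.integer(m_values)
  n <- n_birds(snapshot)
  if (max(m_values) > n - 1L) stop("m exceeds N-1")
  kn <- knn_internal(snapshot$positions, max(m_values))
  Q <- consensus_projector(n)
  sp <- numeric(length(m_values))
  for (k in seq_along(m_values)) {
    m <- m_values[k]
    graph <- new_sensing_graph(kn$idx[, seq_len(m), drop = FALSE],
                               kn$dist[, seq_len(m), drop = FALSE],
                               scheme, snapshot$snapshot_id)
    if (!is_consensus_feasible(graph)) next
    sys <- laplacian_system(graph_laplacian(graph), Q = Q)
    sp[k] <- convergence_speed(sys, feasible = TRUE) / m
  }
  data.frame(snapshot_id = snapshot$snapshot_id, m = m_values,
             speed_pn = sp, stringsAsFactors = FALSE)
}
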