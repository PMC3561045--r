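#' Equivalent inertia-ellipsoid semi-axes of a flock
#'
#' Treats every bird as an equal unit point mass and returns the semi-axes of
#' the uniform solid ellipsoid having the same principal moments of inertia
#' as the flock. If the centred position covariance (1/N normalisation) has
#' eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}, the semi-axes are
#' \eqn{\sqrt{5\lambda_i}} — a uniform ellipsoid of semi-axis a has position
#' variance a^2/5 along that axis, so axis ratios equal
#' \eqn{\sqrt{\lambda_i/\lambda_1}} regardless of the factor 5.
#'
#' @param snapshot a [flock_snapshot()].
#' @return Numeric vector `c(a, b, c)` with `a >= b >= c >= 0` (metres).
#' @seealso [flock_thickness()], [flock_width()], [flock_geometry()]
#' @examples
#' cube <- flock_snapshot(as.matrix(expand.grid(0:1, 0:1, 0:1)))
#' equivalent_ellipsoid_axes(cube)  # a = b = c by symmetry
#' @export
equivalent_ellipsoid_axes <- function(snapshot) {
  assert_snapshot(snapshot)
  x <- snapshot$positions
  if (nrow(unique(x)) < 2L)
    stop("degenerate point cloud: fewer than 2 distinct positions")
  xc <- sweep(x, 2L, colMeans(x))
  cv <- crossprod(xc) / nrow(x)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(5 * pmax(ev, 0))
}

#' Flock thickness and width
#'
#' Shape descriptors from the equivalent inertia ellipsoid: `thickness` is
#' the ratio of smallest to largest semi-axis (0 for a planar flock, 1 for an
#' isotropic one) and `width` the ratio of intermediate to largest. Both are
#' dimensionless, invariant under rigid motions and uniform scaling, and
#' satisfy `0 <= thickness <= width <= 1`.
#'
#' @inheritParams equivalent_ellipsoid_axes
#' @return A single number in `[0, 1]`.
#' @examples
#' flat <- flock_snapshot(cbind(runif(50), runif(50), 0))
#' flock_thickness(flat)  # exactly 0
#' @export
flock_thickness <- function(snapshot) {
  ax <- equivalent_ellipsoid_axes(snapshot)
  if (ax[1L] <= 0) stop("all points coincident: largest axis is zero")
  ax[3L] / ax[1L]
}

#' @rdname flock_thickness
#' @export
flock_width <- function(snapshot) {
  ax <- equivalent_ellipsoid_axes(snapshot)
  if (ax[1L] <= 0) stop("all points coincident: largest axis is zero")
  ax[2L] / ax[1L]
}

#' Summarise flock geometry
#'
#' @inheritParams equivalent_ellipsoid_axes
#' @return An object of class `geometry_summary`: list with `snapshot_id`,
#'   `n_birds`, `centroid`, `axes` (a >= b >= c), `thickness`, `width`.
#'   Coerce with `as.data.frame()` for tabular output.
#' @export
flock_geometry <- function(snapshot) {
  ax <- equivalent_ellipsoid_axes(snapshot)
  if (ax[1L] <= 0) stop("all points coincident: largest axis is zero")
  structure(
    list(snapshot_id = snapshot$snapshot_id,
         n_birds = n_birds(snapshot),
         centroid = colMeans(snapshot$positions),
         axes = ax,
         thickness = ax[3L] / ax[1L],
         width = ax[2L] / ax[1L]),
    class = "geometry_summary"
  )
}

#' @export
as.data.frame.geometry_summary <- function(x, ...) {
  data.frame(snapshot_id = x$snapshot_id, n = x$n_birds,
             a = x$axes[1L], b = x$axes[2L], c = x$axes[3L],
             thickness = x$thickness, width = x$width,
             stringsAsFactors = FALSE)
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("<geometry_summary> '", x$snapshot_id, "': N = ", x$n_birds,
      ", semi-axes = (", paste(signif(x$axes, 4), collapse = ", "),
      "), thickness = ", signif(x$thickness, 4),
      ", width = ", signif(x$width, 4), "\n", sep = "")
  invisible(x)
}
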