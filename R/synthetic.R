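# Synthetic flock generators.
#
# Point clouds inside an anisotropic rectangular prism emulate the bulk
# statistics of stereo-reconstructed flock snapshots: a few hundred to a few
# thousand birds, thickness (smallest/largest inertia-ellipsoid axis ratio)
# roughly 0.1-1. Three spatial distributions span an ordering gradient:
# perturbed grid (most ordered) < Halton quasi-random < uniform.

#' Configuration for a synthetic flock
#'
#' @param n_birds number of individuals (default 1200, the ensemble size
#'   used for the shape experiments).
#' @param distribution `"uniform"` (i.i.d. uniform in the box), `"halton"`
#'   (3-D Halton sequence, bases 2/3/5, optionally rotated per seed), or
#'   `"perturbed_grid"` (regular lattice plus isotropic Gaussian jitter).
#' @param box side lengths `c(Lx, Ly, Lz)` with `Lx >= Ly >= Lz > 0`
#'   (dimensionless); see [box_for_thickness()].
#' @param grid_noise_sd perturbed-grid jitter standard deviation as a
#'   fraction of the lattice spacing (default 0.3: clearly more ordered than
#'   Halton yet not a pure lattice).
#' @param seed integer seed; `NULL` uses the session RNG (and leaves the
#'   Halton sequence unrotated).
#' @return Object of class `synthetic_flock_config`.
#' @export
synthetic_flock_config <- function(n_birds = 1200,
                                   distribution = c("uniform", "halton",
                                                    "perturbed_grid"),
                                   box = c(1, 1, 1),
                                   grid_noise_sd = 0.3,
                                   seed = NULL) {
  distribution <- match.arg(distribution)
  n_birds <- as.integer(n_birds)
  if (n_birds < 4L) stop("n_birds must be at least 4")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0))
    stop("box must be three positive side lengths")
  if (is.unsorted(rev(box)))
    stop("box sides must be ordered Lx >= Ly >= Lz > 0")
  if (grid_noise_sd < 0) stop("grid_noise_sd must be >= 0")
  structure(
    list(n_birds = n_birds, distribution = distribution, box = box,
         grid_noise_sd = grid_noise_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synthetic_flock_config"
  )
}

#' Box side lengths for a target thickness
#'
#' A uniform flock in a box `(1, w, t)` has expected thickness t and
#' expected width w, since the uniform-box position covariance has
#' eigenvalues proportional to the squared side lengths.
#'
#' @param t target thickness, `0 < t <= 1`.
#' @param width_ratio target width w with `t <= w <= 1`; default 1 (square
#'   cross-section — flock shape effects are driven by thickness, not
#'   width).
#' @return `c(1, width_ratio, t)`.
#' @export
box_for_thickness <- function(t, width_ratio = 1) {
  if (t <= 0 || t > 1) stop("thickness target must be in (0, 1]")
  if (width_ratio < t || width_ratio > 1)
    stop("width_ratio must satisfy t <= width_ratio <= 1")
  c(1, width_ratio, t)
}

# Radical-inverse (van der Corput) digits of 1..n in the given base; the
# 3-D Halton sequence pairs bases 2, 3 and 5.
radical_inverse <- function(i, base) {
  r <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

halton_points <- function(n, bases = c(2, 3, 5)) {
  vapply(bases, function(b) radical_inverse(seq_len(n), b), numeric(n))
}

#' Generate one synthetic flock
#'
#' Draws a point cloud per the configuration (see
#' [synthetic_flock_config()]):
#' * `uniform` — i.i.d. uniform inside the box;
#' * `halton` — the first `n_birds` points of the 3-D Halton sequence
#'   (bases 2, 3, 5) scaled to the box; when a seed is given, a seed-keyed
#'   Cranley–Patterson rotation (random shift modulo 1) decorrelates
#'   replicates while preserving low discrepancy;
#' * `perturbed_grid` — a regular lattice whose per-axis point counts are
#'   proportional to the box sides (product as close to `n_birds` as
#'   rounding allows), each point jittered by isotropic Gaussian noise with
#'   sd `grid_noise_sd` times the mean lattice spacing (jittered points may
#'   fall slightly outside the box).
#'
#' Output is deterministic given the configuration, and the session RNG
#' state is left untouched when a seed is supplied.
#'
#' @param config a [synthetic_flock_config()].
#' @param snapshot_id label; default derived from the configuration.
#' @return A [flock_snapshot()].
#' @export
generate_flock <- function(config, snapshot_id = NULL) {
  if (!inherits(config, "synthetic_flock_config"))
    stop("expected a 'synthetic_flock_config'")
  if (is.null(snapshot_id))
    snapshot_id <- paste0(config$distribution, "_s",
                          if (is.null(config$seed)) "NA" else config$seed)
  n <- config$n_birds
  box <- config$box
  draw <- function(expr) {
    if (is.null(config$seed)) expr() else withr::with_seed(config$seed, expr())
  }
  pts <- switch(config$distribution,
    uniform = draw(function()
      matrix(stats::runif(3L * n), ncol = 3L) %*% diag(box)),
    halton = {
      h <- halton_points(n)
      if (!is.null(config$seed)) {
        shift <- withr::with_seed(config$seed, stats::runif(3L))
        h <- (h + matrix(shift, n, 3L, byrow = TRUE)) %% 1
      }
      h %*% diag(box)
    },
    perturbed_grid = {
      scale <- (n / prod(box))^(1 / 3)
      counts <- pmax(1L, as.integer(round(box * scale)))
      spacing <- box / counts
      grid <- as.matrix(expand.grid(
        (seq_len(counts[1L]) - 0.5) * spacing[1L],
        (seq_len(counts[2L]) - 0.5) * spacing[2L],
        (seq_len(counts[3L]) - 0.5) * spacing[3L]))
      sdev <- config$grid_noise_sd * exp(mean(log(spacing)))
      if (sdev > 0) {
        jitter <- draw(function()
          matrix(stats::rnorm(length(grid), sd = sdev), ncol = 3L))
        grid <- grid + jitter
      }
      dimnames(grid) <- NULL
      grid
    }
  )
  flock_snapshot(pts, snapshot_id = snapshot_id)
}

#' Generate an ensemble of replicate flocks
#'
#' Replicate i uses seed `config$seed + i`, so ensembles are deterministic
#' given the base seed and Halton replicates receive distinct rotations.
#'
#' @param config a [synthetic_flock_config()] with a non-`NULL` seed.
#' @param n_replicates number of flocks to generate.
#' @return List of [flock_snapshot()]s with ids `<distribution>_s<seed>_r<i>`.
#' @export
replicate_ensemble <- function(config, n_replicates) {
  if (!inherits(config, "synthetic_flock_config"))
    stop("expected a 'synthetic_flock_config'")
  if (is.null(config$seed))
    stop("replicate_ensemble requires a base seed in the config")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    generate_flock(cfg, snapshot_id = paste0(config$distribution, "_s",
                                             config$seed, "_r", i))
  })
}
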