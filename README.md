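# flocknet

Consensus robustness of nearest-neighbour flock interaction networks.

## The scientific problem

Birds in a flock agree on a common direction of travel even though each
individual attends to only a handful of neighbours and every observation
is noisy. Attending to more neighbours suppresses noise but costs
attention. This package asks: **given the 3-D positions of a flock, how
many nearest neighbours `m` should each bird sense so that robustness of
consensus per unit of sensing cost is maximised?** It also quantifies how
that optimum `m*` and the achievable robustness depend on the flock's
shape (thickness) and spatial ordering.

## Core model

Each bird `i` carries a scalar state `x_i` (a component of its heading)
and relaxes toward a weighted average of its `m` nearest neighbours under
white noise of intensity ν:

    dx/dt = −L x + ν ξ

`L` is the Laplacian of the directed sensing graph (edge `i → j` means
"`i` senses `j`"), with each row's weights summing to 1. Consensus is
feasible iff the condensation of the graph into strongly connected
components has a single sink; then the disagreement `y = Qx` (projection
orthogonal to the consensus line `span(1)`) is stationary with covariance
`Σ` solving the Lyapunov equation for the reduced Laplacian
`L̄ = Q L Qᵀ`:

    L̄ Σ + Σ L̄ᵀ = I,   ‖H‖₂² = ν² tr Σ

Reported quantities:

- **nodal robustness** `√N / (ν √tr Σ)` — inverse RMS per-bird deviation
  from consensus (0 when infeasible);
- **robustness per neighbour** — nodal robustness / m; its maximiser
  over m is `m*`, with a 90%-of-peak band;
- **convergence speed** — `min Re eig(L̄)` normalised so the all-to-all
  network scores 1;
- **thickness / width** — ratios of the flock's equivalent
  inertia-ellipsoid semi-axes (smallest/largest, middle/largest).

Closed-form anchors: the equal-weight complete graph has nodal robustness
`√2·N/(N−1)` and speed exactly 1.

## Worked example

Generate a synthetic flock of 300 birds with thickness 0.25, measure its
shape, and sweep m = 1..11:

```r
library(flocknet)

cfg  <- synthetic_flock_config(n_birds = 300, distribution = "uniform",
                               box = box_for_thickness(0.25), seed = 42)
snap <- generate_flock(cfg)
flock_geometry(snap)
#> <geometry_summary> 'uniform_s42': N = 300, semi-axes = (0.6619, 0.65, 0.1563), thickness = 0.2362, width = 0.9821

curve <- robustness_curve(snap, m_values = 1:11)
curve
#> <robustness_curve> 'uniform_s42': m = 1..11, m* = 7, peak = 0.10694, 90% band = [6, 8]

as.data.frame(curve)
#>    snapshot_id  m     rpn
#> 1  uniform_s42  1 0.00000
#> 2  uniform_s42  2 0.00000
#> 3  uniform_s42  3 0.00000
#> 4  uniform_s42  4 0.04544
#> 5  uniform_s42  5 0.07951
#> 6  uniform_s42  6 0.10596
#> 7  uniform_s42  7 0.10694
#> 8  uniform_s42  8 0.09808
#> 9  uniform_s42  9 0.09604
#> 10 uniform_s42 10 0.09210
#> 11 uniform_s42 11 0.08591

nodal_robustness_for_strategy(snap, curve$m_star)
#> [1] 0.7485965
```

The curve shows the characteristic structure: zero robustness while the
graph is disconnected (m ≤ 3 here), a steep rise at the connectivity
onset, an interior optimum (m* = 7), and a slow decline as extra
neighbours add cost faster than benefit.

Ensemble experiments over shape and ordering:

```r
shape_experiment(c(0.15, 0.5, 0.85), n_birds = 300, n_replicates = 20,
                 seed = 1)          # m* and peak vs thickness
speed_curve(snap, m_values = 3:11)  # convergence speed per neighbour
```

A command-line interface is installed at `inst/cli/flocknet`
(subcommands `geometry`, `graph`, `robustness`, `sweep`, `synth`,
`shape`, `size`, `fit`); run it without arguments for usage.

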