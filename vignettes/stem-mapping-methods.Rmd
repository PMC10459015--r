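---
title: "Methods: direct stereo odometry, GNSS fusion and stem mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct stereo odometry, GNSS fusion and stem mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Terrestrial stem mapping asks for the UTM position of every tree stem a
camera rig passes while being carried (or driven) through a stand. A
consumer-grade GNSS receiver under canopy is good to roughly 4--12 m;
visual odometry (VO) from a stereo camera is locally far more precise but
drifts without bound. `stemmapr` fuses the two and then uses the tree
detections themselves as landmarks: VO supplies locally rigid motion, GPS
pins the trajectory globally, and repeated stem observations tie distant
poses together during a final joint refinement.

The pipeline has three stages:

1. **Direct visual odometry** -- frame-to-frame se(3) egomotion from
   photometric alignment of rectified stereo frames with known disparity.
2. **Global alignment** -- a planar (se(2)) pose graph with odometry edges
   and GPS position constraints, plus a single *global orientation* angle
   `phi` that rotates the odometry frame onto the UTM frame; optimized by
   sparse Levenberg--Marquardt (LM).
3. **Local refinement** -- stem detections are mapped to world
   coordinates, clustered into individual stems with DBSCAN, and poses
   and stem centers are optimized jointly.

# Direct visual odometry

## Model

Each pixel `p` of the reference frame with depth `z(p)` is warped into
the input frame by `W(p; xi) = pi(T(xi) pi^-1(p, z))`, where `T(xi) =
exp(xi^)` is the SE(3) exponential of a six-parameter twist (rotation
first, translation last) and `pi` is the pinhole projection. The twist is
estimated by minimizing the sum of squared intensity differences over a
selected pixel set.

We use the inverse-compositional (IC) formulation: the incremental warp
is solved on the reference image, so the 6-column Jacobian of intensity
with respect to the twist and its Gauss--Newton Hessian are computed
**once per reference frame**; each iteration only resamples the input
image, reweights, solves a 6x6 system and composes the inverted
increment, `xi <- log(exp(xi) exp(-dxi))`.

The analytic Jacobian row combines the image gradient, the projection
derivative and the derivative of the transformed point with respect to
the twist at identity, `[-[x]_x | I3]`. Sign conventions for the skew block
differ across the literature; ours is the one that matches finite
differences of `xi -> I(W(p; xi))`, and the test suite asserts this
agreement directly rather than trusting any quoted convention.

## Depth

Depth comes from integer disparity maps, `z = f b / D`, with `D = 0`
marking invalid pixels. Stereo matching itself is an external component:
maps are read from files (PNG or text grids) or produced by the built-in
renderer. A left--right consistency filter (threshold `delta = 1` px by
default) removes occlusion fill-in before triangulation. Disparities stay
integers end to end; no sub-pixel refinement is applied, and the
quantization this induces is visible as a small depth-dependent bias that
averages out over the selected pixel set.

## Pixel selection

Pixels with zero disparity are discarded first (they back-project to
infinity), the rest are ranked by gradient magnitude, and the top
`floor(N p / 100)` are kept where `N` is the **total** pixel count -- on a
240 x 320 frame the budgets are exactly 19,200 / 38,400 / 57,600 pixels at
25 / 50 / 75%, which keeps the Jacobian dimension constant across frames.
Ties break in raster order so the selection is deterministic. The default
is 25%.

## Robustness

Saturation, occlusion and disparity faults produce non-Gaussian
residuals. Each iteration standardizes residuals by the MAD scale
`s = 1.4826 median(|r|)` and weights them with the Tukey biweight,
`w = (1 - (r/(s c))^2)^2` for `|r/s| <= c`, zero beyond, with
`c = 4.6851` (95% asymptotic efficiency under Gaussian noise). Note that
the biweight *weight* function is identical to `psi(r)/r` for Tukey's
estimator, so the printed weight form and the textbook IRLS form
coincide; there is nothing to choose between. When every residual is zero
the scale degenerates and all weights are set to 1.

## Numerics

Initialization is the zero twist (at 10 fps inter-frame motion is small);
an optional warm start can be supplied. Interpolation at warped
coordinates is bilinear; pixels warping out of bounds or behind the
camera get weight 0, and more than 50% invalid pixels raises a
low-overlap warning. Gradients are central differences with replicated
borders. Convergence: `|dxi| < 1e-6` or relative cost change `< 1e-8`,
at most 100 iterations. No image pyramid is used -- the method targets
single-scale 240 x 320 frames with small motion.

# Global alignment

## Graph

Poses are planar, `v = (x, y, theta)`. The initial graph chains the
odometry motions from `v1 = 0`. Odometry edge `i -> i+1` contributes the
relative-pose residual

```
r_ij = [ R(th_ij)^T (R(th_i)^T (t_j - t_i) - t_ij) ;
         wrap(th_j - th_i - th_ij) ]
```

which we derived from the defining product
`T(xi_ij)^-1 T(v_i)^-1 T(v_j)`; it is exactly zero when the poses compose
the edge motion (a property the test suite asserts). Each GPS fix `g_k`
(anchored by subtracting the first fix `g0`; at least two fixes are
required to resolve orientation) constrains its pose through
`r_ik = R(phi) t_i - g_k`, coupling every fixed pose to the global
orientation node `phi`. All residuals are weighted by information
matrices (inverse covariances).

## Information defaults

The field values behind these matrices are not observable from data
alone, so they are explicit configuration with the following defaults:
GPS `(1/sigma_g^2) I` with `sigma_g = 5` m (consumer receiver under
canopy; optionally scaled per fix by PDOP, off by default because the use
of recorded PDOP is ambiguous in practice); odometry
`diag(1/sigma_t^2, 1/sigma_t^2, 1/sigma_th^2)` with `sigma_t = 0.1` m,
`sigma_th = 0.005` rad per edge, i.e. the heading deliberately much
stiffer than translation so the chain bends to the GPS track without
rotating locally -- accurate headings are what make the stem observations
reconstruct consistently. When the synthetic scenarios emit *exact*
odometry edges, the scenario helpers tighten this to `sigma_t = 1e-4` m
and `sigma_th = 1e-6` rad ("trust the odometry at sub-millimeter level"),
which makes the chain near-rigid; stiffer values add nothing but
conditioning hazard, as the information diagonal already spans ~12
orders of magnitude against the GPS entries.

## Optimization

The normal equations `H ds = -b` are assembled sparsely: analytic 3x3
blocks (A, B) per odometry edge, a 2x1 block (C) coupling each GPS
residual to `phi` and a 2x3 block (D) to its pose. All blocks are
validated against finite differences of the residual functions. `H` is
`(1+3n) x (1+3n)` and almost block-tridiagonal with one arrow
row/column for `phi`; it is factored with CHOLMOD's sparse Cholesky
(fill-reducing permutation) via the Matrix package, with a dense
fallback below 200 unknowns.

Damping follows the classic LM schedule -- halve on an accepted
(objective-decreasing) step, double on a rejected one -- but the damping
term is `lambda diag(H)` (Marquardt scaling) rather than `lambda I`, with
`lambda0 = 1e-5`. With identity damping and a stiff-heading information
matrix, any lambda large enough to damp the heading block freezes the
whole state: the first damped step is microscopic and a step-norm
termination (`|ds| < 0.001` by default) fires before any progress is
made. Marquardt scaling is invariant to the per-block scales and leaves
the schedule meaningful; identity damping (initialized at `trace(H)`)
remains available as `lm_config(damping = "identity")`. Steps that
increase the objective are always rejected and the previous state is
restored.

Robust GPS weighting mirrors the VO stage: residual *norms* are
standardized by their MAD and Tukey-weighted, and the weight scales the
fix's information matrix; weights are recomputed at every linearization.
Acceptance decisions within one linearization compare objectives under
the weights frozen at that linearization, so the accepted-step objective
is monotone by construction. After convergence each pose is rotated by
`phi*`, translated back by `g0`, and headings incremented by `phi*`;
`phi` is dropped thereafter.

# Local refinement

Detections arrive per frame as camera-frame planar offsets (lateral x,
forward y, meters). With the aligned poses they map to the world by
`z_hat = R(theta_i) z + t_i`. DBSCAN with Euclidean distance, radius 1 m
and a minimum of 10 points (both configurable) associates observations to
individual stems; label 0 is noise. Clustering runs **once**, on the
aligned state; the association is frozen during optimization, matching
the staged design (and avoiding association flapping). Cluster means
initialize the stem centers.

The augmented state is `(v_1..v_n, m_1..m_L)` -- the orientation
parameter is gone, so the GPS Jacobian block degenerates to `(I2, 0)` and
the GPS residual to `t_i - g_k` in UTM. Each observation contributes
`r_il = R(theta_i)^T (m_l - t_i) - z_iq` with pose block
`E = [-R^T | dR^T/dtheta (m - t)]` and center block `F = R^T`; both are
validated against finite differences (the transposes are easy to get
wrong, so finite differences are the arbiter). Observation
information is `(1/sigma(d)^2) I` with `sigma(d) = 0.1 + 0.05 d` per
meter of detection range -- distant detections, which back-project
through fewer disparity steps, count less. The same LM machinery
optimizes the joint system; per-cluster empirical covariances are
recorded before and after refinement (their traces shrink when the
refinement actually tightens the geometry, which is the behavior the
acceptance suite asserts on drifting-odometry worlds).

# The synthetic world

The generator emulates the data-collection conditions the pipeline is
designed for, and every study scenario is a canned function so tests,
scripts and examples run the same experiment:

* ~1115 m smooth constant-speed path (1 m/s, 10 poses/s, curvature
  bounded by 0.03 1/m, a ~33 m minimum turning radius typical of walking
  through a stand), random initial heading, UTM-like origin;
* 140 stems placed uniformly over a corridor +-12 m around the path with
  a 4 m hard-core spacing (sparse pine-stand density) and >= 1 m
  clearance from the path;
* exact odometry edges, optionally perturbed per edge by Gaussian noise
  to emulate VO drift (`perturb_odometry`);
* GPS: dense (one fix per pose) with per-axis sigma = 5 m Gaussian
  noise; optionally 5% of fixes displaced by uniform radial outliers in
  [0, 200] m; or intermittent -- first fix, last fix, one random fix per
  100 m interval, i.e. 12 fixes over the default path;
* stem detections inside a 90 degree field of view up to 12 m with
  range-dependent noise `sigma(d) = 0.1 + 0.05 d`, information matrices
  set from the same sigma;
* rendered stereo-time pairs: a textured plane (smooth random albedo,
  bilinearly interpolated, ~14 px projected wavelength) imaged before and
  after a known twist, with the true integer disparity map. Both views
  sample the same continuous albedo, so photometric consistency is exact
  up to interpolation. Fronto-parallel planes at depths `f b / D` for
  integer `D` give quantization-free depth, which is what the VO
  recovery tests use; slanted planes exercise the geometry but inherit
  integer-disparity quantization error.

All generators are pure functions of their spec and seed (the caller's
RNG stream is saved and restored).

What the generator does **not** emulate: photometric nuisances
(illumination change, auto-exposure, motion blur), disparity outliers
from repetitive texture, canopy-dependent GPS error correlation (fix
errors are i.i.d.), detector false positives, and stems occluding one
another. Passing tests therefore demonstrate the estimators and the
optimization machinery, not robustness to every field effect.

# Problem sizes and scenario calibration

The localization experiments run at full scale: 11,151 poses over 1115 m,
one GPS fix per pose, ~6,000 stem observations, five seeds per scenario
(about 40 s per scenario set on one core; sparse Cholesky keeps each LM
iteration around a tenth of a second). The oracle-equivalence tests use
graphs of 3--10 poses where dense brute-force optimization with
numerically differentiated Jacobians is exact enough to compare against
at 1e-8. The intermittent-GPS scenario adds per-edge odometry noise
(0.005 m, 5e-4 rad) so the raw chain drifts by several meters over the
path -- the regime the fusion exists for; its information matrices match
the generating noise, the statistically consistent choice.

# Known limitations

* Heading is only constrained by odometry and stem observations, never
  globally; over very long tracks it will drift (a magnetometer fusion
  would fix this and slots naturally into the GPS-style constraints).
* A single UTM zone is assumed; crossing a zone boundary is an error.
* DBSCAN with a 1 m radius merges stems whose observation clouds
  overlap; below ~2 m true spacing association becomes unreliable.
* The VO stage has no keyframing or windowed bundle adjustment; drift
  control is entirely delegated to the GNSS fusion.
* Integer disparities cap depth resolution at `f b / D (D+1)` per step;
  beyond ~15 m depth (for the default 350 px / 0.12 m geometry) stem
  range estimates are dominated by quantization.
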