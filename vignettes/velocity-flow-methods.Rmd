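---
title: "Modeling developmental trajectories with time-varying velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling developmental trajectories with time-varying velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velflow)
```

## The problem

Developmental brain atlases sample a continuous growth process at a handful
of discrete ages — for the mouse, embryonic stages such as E11.5 through
E18.5 and postnatal stages through P56, each with its own template and a
shared anatomical label vocabulary.  Pairwise registration connects adjacent
stages, but mapping between non-adjacent ages then means chaining warps
through every intermediate stage, and nothing at all exists at unsampled
ages.  `velflow` instead fits a single time-varying velocity field
$v(x, t)$ over the whole developmental interval.  Integrating the flow

$$\frac{d\varphi}{dt} = v(\varphi(t),\, t), \qquad \varphi(t_0) = x$$

from any time $t_0$ to any time $t_1$ produces a diffeomorphic displacement
field between those two continuous timepoints — including "virtual" ages
where no template was ever acquired.

## The developmental time axis

Stage ages (days on a single conception-anchored axis) are mapped to
normalized times in $[0, 1]$ by a log min–max transform:
$t_i = (\ln a_i - \ln a_0) / (\ln a_T - \ln a_0)$, after optionally
truncating ages at a `cap_age`.  The log transform allocates finer temporal
resolution to early development, where morphological change per day is
largest; the cap encodes that late change is negligible (for a P56 endpoint
with birth at E19, capping at $19 + 28 = 47$ days treats the final four
postnatal weeks as morphologically static).  The conception-anchored merge
of embryonic and postnatal ages with birth at E19 is a configuration choice
(`birth_offset_days`, default 19) recorded in every model sidecar, because
raster ages and postnatal day counts are anchored differently across
datasets.

```{r}
normalize_stage_times(c(11.5, 13.5, 15.5, 18.5, 23, 33, 75), cap_age = 47)
```

## Input point sets

The optimizer consumes corresponding point trajectories, not images.  From a
series of common-label images, `extract_label_points()` samples two strata
per label: *contour* voxels (those with a six-connected neighbour of a
different label) and *region* (interior) voxels, at fractions defaulting to
10% and 1%.  Counts are `round(fraction * available)` (half away from zero)
with a floor of one point per nonempty stratum, so small structures are
always represented; sampling is stratified per label rather than pooled for
the same reason.  Contour points carry twice the optimization weight of
region points, emphasizing boundary correspondence.  The pairwise transports
that put the sampled points into correspondence across stages are *inputs*
(e.g. displacement fields from any pairwise registration tool, or the
synthetic generator's exact flows); re-implementing a pairwise registration
algorithm is out of scope.

## The fitting loop

`fit_time_varying_velocity()` stores the field on $M$ uniformly spaced time
slices (`n_integration_points`) and refines it iteratively from zero:

1. For each slice time $s_k$, find the adjacent stage pair
   $t_i \le s_k \le t_j$ (slices coinciding with an interior stage time use
   the earlier interval).
2. Transport the stage-$i$ points forward $t_i \to s_k$ and the stage-$j$
   points backward $t_j \to s_k$ through the *current* field with
   point-wise RK4.
3. The per-point residual $r_n = q_n^{b} - q_n^{f}$ is anchored at the
   branch midpoint $m_n = (q_n^{f} + q_n^{b})/2$; each branch should move
   half the residual, which keeps the scheme symmetric (and hence
   inverse-consistent) by construction.
4. A smooth update is fit to $(m_n, \tfrac{1}{2} r_n (M-1))$ by weighted
   B-spline scattered-data approximation and added to slice $k$ with step
   size $\delta$ (default 0.2).  The $(M-1)$ factor converts a displacement
   into a velocity per unit normalized time: a unit bump at one slice has a
   temporal hat profile whose integral is $1/(M-1)$, so without it the step
   size would depend on the slice count.
5. The convergence metric is the weighted mean Euclidean mismatch
   $\overline{|q^{b} - q^{f}|}$ over all points and slices; iteration stops
   at `convergence_tol` (default 0, i.e. a fixed iteration budget, which
   mirrors fixed-budget practice for this optimizer) or `max_iterations`.

Residuals for all slices within one iteration are measured against the
field frozen at the iteration start (a Jacobi-style pass), rather than
letting early-slice updates influence later slices in the same sweep.  This
makes the first trace entry exactly the identity-transform mismatch, makes
iterations order-independent, and costs nothing measurable in convergence
rate.  The optimizer itself is deterministic; randomness enters only
through point sampling, which is seed-controlled.

Two conventions the optimizer depends on were genuinely open design
choices: anchoring residuals at branch midpoints (any point on the segment
would serve; the midpoint is the unique symmetric choice) and the
$(M-1)$ velocity scaling just described.  Both are validated by parameter
recovery against closed-form flows rather than by matching any particular
reference implementation bit-for-bit.

## The B-spline regularizer

`fit_bspline_scattered()` turns noisy per-point residuals into a smooth
update field in two stages.  A weighted affine trend (WLS intercept +
linear terms) is removed first, so constant and linear vector fields —
which a velocity update frequently resembles — are reproduced exactly.
The trend residuals are then approximated by multilevel tensor-product
B-splines on dyadically refined control lattices: at each level, control
values accumulate the local weighted scheme
$\phi_c = \sum_p w\,B_c^2\,\hat\phi_c \big/ \sum_p w\,B_c^2$ with
$\hat\phi_c = B_c z / \sum_a B_a^2$ the single-point exact solution, and
each level fits the residual of the previous one.  The affine stage is
deliberate: the pure accumulation scheme is a local quasi-interpolant and
cannot reproduce even constants exactly, while the velocity updates the
optimizer needs are dominated by low-order trends; removing the trend
first gives exactness on the trend subspace at no cost to locality.
Defaults are cubic splines, a $4^3$-interval base lattice, and 4 levels;
these are declared defaults (the appropriate resolution depends on the
anatomy's spatial frequency content, and nothing in the method fixes them),
and both the component-wise smoothing and open uniform knot placement over
the domain box (so repeated fits share one basis) are standard choices for
this family of approximants.

Weight semantics: doubling all weights leaves the fit unchanged; doubling
one point's weight equals duplicating that point; a point with relatively
negligible weight contributes negligibly wherever other data support the
lattice.

## Integration, inversion, containers

Velocities are stored per unit *normalized* time; conversion to days goes
through the timeline.  `integrate_velocity_field()` runs classical RK4 with
`ceiling(n_steps * |t1 - t0|)` steps (default `n_steps` crosses each
inter-slice interval at least twice during fitting).  Space-time
interpolation is trilinear in space and linear in time between the two
bracketing slices.  Out-of-domain samples clamp to the boundary value and
integrated positions are clamped into the grid box, so trajectories degrade
gracefully instead of acquiring zeros or escaping.
`invert_displacement_field()` uses the standard fixed-point iteration
$u^{-1} \leftarrow -u \circ (\mathrm{id} + u^{-1})$ (default 20 iterations,
tolerance $0.01 \times$ the smallest voxel spacing) and raises an error
naming the residual when the mean update grows five consecutive iterations.

All containers live in physical space (mm) with 0-based voxel indices and
the voxel-center convention, matching NIfTI sampling semantics; direction
matrices other than identity are supported throughout.  Velocity and
displacement fields serialize as 5-D NIfTI volumes with a JSON sidecar
(grid provenance, slice times, timeline, fit configuration echo) that is
sufficient to re-run a fit identically.

## Virtual templates

`synthesize_template()` warps the two bracketing stage templates to the
target time via the fitted field and averages them voxel-wise.  The default
weighting is inverse temporal distance ($1/(|\Delta t| + 10^{-6})$,
normalized), so a target coinciding with a stage time reproduces that
stage's template; equal weighting is also available, since nothing in the
averaging procedure itself dictates the weights.  No sharpening or
iterative shape-update steps from full groupwise template construction are
applied — the output is a plain weighted mean of the two warped images.

## The synthetic generator and what it does (not) show

`flow_scene()` couples a nested-ellipsoid label geometry — a brain-mask-like
outer label containing four disjoint substructures, five labels in all on a
$48^3$ grid at 0.5 mm by default — with an analytic flow whose map between
any two times is available in closed form: a translation, a linear (matrix
exponential) flow, radial growth with scale $(1 + \beta t_1)/(1 + \beta
t_0)$, or a drifting affine flow built from an augmented matrix exponential
(chosen over naive composition of primitive flows because the augmented
form is still an exact one-parameter group).  All maps satisfy the group
and inverse properties exactly, so they are exact oracles for every
integration, inversion and fitting test.  Label rasters are produced by
backward-mapping voxel centers and reading the analytic ellipsoid label, so
they contain no interpolation error; Gaussian jitter (`noise_sd`, default
0 mm — correspondences are treated as exact unless a study asks otherwise)
is applied to point trajectories only, never to rasters.

What passing these tests shows: the optimizer recovers smooth invertible
flows from point correspondences to a small fraction of the domain size,
and its warps match an exact pairwise baseline in label overlap.  What they
do not show: performance under the topology changes, contrast variation,
and correspondence errors of real multi-stage atlases — the generator's
flows are spatially low-order, its labels are ellipsoids, and its
correspondences are exact up to optional isotropic jitter.

## Problem sizes and numerical choices

The test and acceptance workloads use $48^3$ label scenes, $16^3$ velocity
grids spanning the same physical box, $M = 6$ integration points,
$\delta = 0.2$ and 60 fitting iterations — sizes chosen so the whole
validation suite reruns in minutes while leaving the convergence behavior
(geometric decay of the mismatch trace, median endpoint error well under 2%
of the domain diagonal) clearly visible.  A velocity grid coarser than the
image grid is deliberate: the fitted field is smooth by construction, and
`integrate_velocity_field()` accepts any output grid, so label-resolution
warps never require label-resolution velocity storage.  Degenerate inputs
are defined rather than accidental: `t0 == t1` integrates to an exactly
zero displacement; a static scene is a zero-residual fixed point of the
optimizer; a slice time equal to an interior stage time uses the earlier
stage interval; empty point lists pass through transport untouched.

## Known limitations

- Stationary-velocity (log-Euclidean) shortcuts, adaptive RK step control
  and spatial multi-resolution pyramids over the velocity grid are not
  implemented.
- The optimizer is landmark-driven only; there is no intensity (image
  metric) term.
- Weight renormalization (dividing by the mean weight, default on) makes
  $\delta$ insensitive to sampling density but means absolute weights have
  no meaning beyond their ratios.
- The number of integration points is a free parameter; published uses of
  this family of models vary between about 10 and 11, and nothing in the
  method fixes it, so it is configuration, not a constant.
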