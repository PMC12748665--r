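# Time-varying velocity field: container, space-time interpolation, RK4
# integration to displacement fields, and displacement inversion.
#
# Velocities are stored per unit *normalized* time on M uniformly spaced
# time slices spanning [0,1]; integrating the flow dphi/dt = v(phi, t)
# between two normalized times yields a diffeomorphic displacement field.

#' Construct a time-varying velocity field
#'
#' @param grid spatial [image_grid].
#' @param vectors numeric array of dim `c(grid$size, M, 3)`: the x/y/z
#'   velocity components (mm per unit normalized time) on M time slices.
#' @param timeline optional [dev_timeline] recording the developmental ages
#'   the normalized axis was derived from (provenance only).
#' @return an object of class `velocity_field` with uniformly spaced
#'   `slice_times` on \[0, 1\].
#' @export
velocity_field <- function(grid, vectors, timeline = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 5L || !identical(as.integer(d[1:3]), grid$size) ||
      d[5] != 3L) {
    stop("velocity array must have dim c(grid size, n_slices, 3)")
  }
  M <- d[4]
  if (M < 2L) stop("a velocity field needs at least 2 time slices")
  if (!all(is.finite(vectors))) stop("velocity components must be finite")
  structure(list(grid = grid, n_slices = as.integer(M),
                 slice_times = seq(0, 1, length.out = M),
                 vectors = vectors, timeline = timeline),
            class = "velocity_field")
}

#' An all-zero velocity field
#' @param grid spatial [image_grid].
#' @param n_slices number of uniformly spaced time slices (>= 2).
#' @param timeline optional [dev_timeline] provenance.
#' @return a [velocity_field] of zeros.
#' @export
zero_velocity_field <- function(grid, n_slices, timeline = NULL) {
  velocity_field(grid, array(0, dim = c(grid$size, n_slices, 3L)), timeline)
}

#' Integration settings for velocity-field flows
#' @param n_steps classical RK4 steps per unit normalized time (>= 1); an
#'   integration over span `|t1 - t0|` uses `ceiling(n_steps * |t1 - t0|)`
#'   steps (minimum 1).
#' @return an object of class `integration_settings`.
#' @export
integration_settings <- function(n_steps = 10L) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  structure(list(n_steps = n_steps), class = "integration_settings")
}

# Interpolate velocity slice k (1-based) at continuous 0-based indices.
.slice_interp <- function(vf, k, cidx) {
  s <- vf$grid$size
  vox <- prod(s)
  M <- vf$n_slices
  base <- (k - 1L) * vox
  comp_stride <- vox * M      # layout c(size, M, 3): components outermost
  sel <- c(base + seq_len(vox),
           base + comp_stride + seq_len(vox),
           base + 2L * comp_stride + seq_len(vox))
  .interp_trilinear(vf$vectors[sel], s, cidx)
}

#' Evaluate a velocity field at physical points and a normalized time
#'
#' Linear interpolation in time between the two bracketing slices of the
#' trilinearly interpolated spatial vectors; `t` outside \[0, 1\] is an
#' error.  Spatial queries outside the grid clamp to the boundary.
#'
#' @param vf a [velocity_field].
#' @param p physical point(s): length-3 vector or n x 3 matrix.
#' @param t normalized time in \[0, 1\].
#' @return n x 3 matrix of velocities (mm / unit normalized time).
#' @export
velocity_at <- function(vf, p, t) {
  stopifnot(inherits(vf, "velocity_field"), length(t) == 1L, is.finite(t))
  if (t < -1e-12 || t > 1 + 1e-12) stop("t must lie in [0, 1]")
  p <- .as_points(p)
  if (!all(is.finite(p))) stop("query points must be finite")
  cidx <- physical_to_index(vf$grid, p)
  M <- vf$n_slices
  u <- min(max(t, 0), 1) * (M - 1)
  k0 <- min(floor(u), M - 2)
  a <- u - k0
  v0 <- .slice_interp(vf, k0 + 1L, cidx)
  if (a <= 1e-12) return(v0)
  v1 <- .slice_interp(vf, k0 + 2L, cidx)
  (1 - a) * v0 + a * v1
}

# Clamp physical points to the grid's voxel-center hull.
.clamp_to_grid <- function(grid, p) {
  cidx <- physical_to_index(grid, p)
  cl <- pmin(pmax(cidx, 0), matrix(grid$size - 1L, nrow(cidx), 3L,
                                   byrow = TRUE))
  if (max(abs(cl - cidx)) == 0) p else index_to_physical(grid, cl)
}

#' Transport physical points along a velocity-field flow
#'
#' Integrates `dphi/dt = v(phi(t), t)` from `t0` to `t1` (backward if
#' `t1 < t0`) with classical 4th-order Runge-Kutta, using
#' `ceiling(n_steps * |t1 - t0|)` steps (minimum 1).  Positions are clamped
#' to the grid box after each step, so trajectories cannot exit the domain.
#'
#' @param vf a [velocity_field].
#' @param points n x 3 matrix of physical start positions (may be empty).
#' @param t0,t1 normalized times in \[0, 1\].
#' @param settings an [integration_settings].
#' @return n x 3 matrix of end positions `phi(t1)`.
#' @export
integrate_velocity_field_at_points <- function(vf, points, t0, t1,
                                               settings = integration_settings()) {
  stopifnot(inherits(vf, "velocity_field"),
            inherits(settings, "integration_settings"))
  for (t in c(t0, t1)) {
    if (!is.finite(t) || t < -1e-12 || t > 1 + 1e-12) {
      stop("integration times must lie in [0, 1]")
    }
  }
  points <- .as_points(points)
  if (nrow(points) == 0L) return(points)
  if (t0 == t1) return(points)
  nsteps <- max(1L, ceiling(settings$n_steps * abs(t1 - t0)))
  h <- (t1 - t0) / nsteps
  x <- points
  t <- t0
  for (s in seq_len(nsteps)) {
    k1 <- velocity_at(vf, x, t)
    k2 <- velocity_at(vf, x + h / 2 * k1, .clamp01(t + h / 2))
    k3 <- velocity_at(vf, x + h / 2 * k2, .clamp01(t + h / 2))
    k4 <- velocity_at(vf, x + h * k3, .clamp01(t + h))
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x <- .clamp_to_grid(vf$grid, x)
    t <- t0 + s * h
  }
  x
}

.clamp01 <- function(t) min(max(t, 0), 1)

#' Integrate a velocity field into a displacement field
#'
#' For each voxel center x of `grid`, transports x from `t0` to `t1` through
#' the flow (see [integrate_velocity_field_at_points]) and stores
#' `u(x) = phi(t1) - x`.  The transform taking a stage-`t0` image into
#' stage-`t1` space is obtained by integrating from `t1` back to `t0` and
#' warping with the result.
#'
#' @param vf a [velocity_field].
#' @param t0,t1 normalized times in \[0, 1\] (`t0 > t1` integrates backward).
#' @param settings an [integration_settings].
#' @param grid output [image_grid]; defaults to the velocity grid.  Velocity
#'   values are interpolated from the velocity grid, so a coarser velocity
#'   field can be integrated on a finer image grid.
#' @return a [displacement_field] on `grid`.
#' @export
integrate_velocity_field <- function(vf, t0, t1,
                                     settings = integration_settings(),
                                     grid = vf$grid) {
  x <- .grid_voxel_centers(grid)
  phi <- integrate_velocity_field_at_points(vf, x, t0, t1, settings)
  displacement_field(grid, array(phi - x, dim = c(grid$size, 3L)))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Iterates `u_inv <- -disp o (id + u_inv)` until the mean voxel update falls
#' below `tol` or `max_iters` is reached, so that
#' `(id + disp) o (id + u_inv)` is approximately the identity.
#'
#' @param disp a [displacement_field].
#' @param max_iters maximum fixed-point iterations.
#' @param tol convergence tolerance on the mean update magnitude (mm);
#'   default 0.01 x the smallest voxel spacing.
#' @return a [displacement_field] on the same grid.
#' @export
invert_displacement_field <- function(disp, max_iters = 20L,
                                      tol = 0.01 * min(disp$grid$spacing)) {
  stopifnot(inherits(disp, "displacement_field"))
  grid <- disp$grid
  x <- .grid_voxel_centers(grid)
  uinv <- matrix(0, nrow(x), 3L)
  prev_upd <- Inf
  n_grow <- 0L
  for (it in seq_len(max_iters)) {
    new <- -interpolate_vector(disp, x + uinv)
    upd <- mean(sqrt(rowSums((new - uinv)^2)))
    uinv <- new
    if (upd > prev_upd) {
      n_grow <- n_grow + 1L
      if (n_grow >= 5L) {
        stop(sprintf(
          "displacement inversion diverging: mean update grew to %.4g mm", upd))
      }
    } else n_grow <- 0L
    prev_upd <- upd
    if (upd < tol) break
  }
  displacement_field(grid, array(uinv, dim = c(grid$size, 3L)))
}

#' Compose two displacement fields
#'
#' Returns the field of `(id + a) o (id + b)`, i.e.
#' `u(x) = b(x) + a(x + b(x))`, on the grid of `b`.
#'
#' @param a,b [displacement_field]s on compatible grids (applied as `a`
#'   after `b`).
#' @return a [displacement_field].
#' @export
compose_displacement_fields <- function(a, b) {
  stopifnot(inherits(a, "displacement_field"),
            inherits(b, "displacement_field"))
  x <- .grid_voxel_centers(b$grid)
  ub <- matrix(b$vectors, ncol = 3L)
  u <- ub + interpolate_vector(a, x + ub)
  displacement_field(b$grid, array(u, dim = c(b$grid$size, 3L)))
}
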