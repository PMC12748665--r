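# Synthetic longitudinal scenes with analytic, exactly invertible flows.
#
# A FlowScene couples a nested-ellipsoid label geometry (a brain-mask-like
# outer structure containing smaller substructures) with a smooth
# time-varying flow whose map between any two times is available in closed
# form.  The closed-form maps satisfy the group property exactly, so they
# serve as exact oracles for integration, inversion and fitting.
#
# Flow kinds (t0, t1 are normalized times in [0,1]; c is a center):
#   translation    x + v (t1 - t0)
#   affine         c + expm(A (t1 - t0)) (x - c)
#   radial_growth  c + (x - c) (1 + beta t1) / (1 + beta t0)
#   composite      c + affine part of expm([[A, v], [0, 0]] (t1 - t0))
#                  applied to (x - c): a drifting affine flow, still an
#                  exact one-parameter group.

#' Describe a synthetic longitudinal flow scene
#'
#' @param flow_kind one of `"translation"`, `"affine"`, `"radial_growth"`,
#'   `"composite"`.
#' @param parameters named list of flow parameters: `v` (length-3 velocity,
#'   mm per unit normalized time) for translation/composite; `A` (3x3
#'   matrix, operator norm < 0.5) and `center` for affine/composite;
#'   `beta` (|beta| < 0.5) and `center` for radial growth.  `center`
#'   defaults to the grid center.
#' @param n_stages number of sampled stages (>= 2).
#' @param stage_times normalized stage times (default uniform on \[0, 1\]).
#' @param grid spatial [image_grid]; default 48^3 voxels at 0.5 mm.
#' @param label_spec list of ellipsoids, each
#'   `list(center =, semi_axes =, label =)`, ordered outer to inner (later
#'   entries take precedence); default a 5-label nested geometry.
#' @param noise_sd isotropic Gaussian jitter (mm) added to non-reference
#'   stage points by [generate_trajectories]; never applied to label
#'   rasters.
#' @param seed integer seed for sampling and jitter.
#' @return an object of class `flow_scene`.
#' @export
flow_scene <- function(flow_kind = c("translation", "affine",
                                     "radial_growth", "composite"),
                       parameters = list(), n_stages = 3L,
                       stage_times = NULL, grid = NULL, label_spec = NULL,
                       noise_sd = 0, seed = 42L) {
  flow_kind <- match.arg(flow_kind)
  if (is.null(grid)) grid <- image_grid(c(48, 48, 48), spacing = rep(0.5, 3))
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stop("a scene needs at least 2 stages")
  if (is.null(stage_times)) stage_times <- seq(0, 1, length.out = n_stages)
  stage_times <- as.numeric(stage_times)
  if (length(stage_times) != n_stages || stage_times[1] != 0 ||
      stage_times[n_stages] != 1 || any(diff(stage_times) <= 0)) {
    stop("stage_times must increase strictly from 0 to 1")
  }
  center_default <- grid$origin + grid$direction %*%
    (grid$spacing * (grid$size - 1L) / 2)
  p <- parameters
  if (is.null(p$center)) p$center <- as.numeric(center_default)
  if (flow_kind %in% c("translation", "composite") && is.null(p$v)) {
    p$v <- c(3, 1.5, -1)
  }
  if (flow_kind %in% c("affine", "composite") && is.null(p$A)) {
    p$A <- matrix(c(0.10, 0.15, 0,
                    -0.15, 0.10, 0,
                    0, 0, 0.05), 3, 3)
  }
  if (flow_kind == "radial_growth" && is.null(p$beta)) p$beta <- 0.2
  if (!is.null(p$A)) {
    if (norm(p$A, "2") >= 0.5) stop("flow matrix A must have norm < 0.5")
  }
  if (!is.null(p$beta) && abs(p$beta) >= 0.5) {
    stop("growth rate beta must satisfy |beta| < 0.5")
  }
  if (is.null(label_spec)) label_spec <- .default_label_spec(grid)
  .check_nesting(label_spec)
  structure(list(flow_kind = flow_kind, parameters = p,
                 n_stages = n_stages, stage_times = stage_times,
                 grid = grid, label_spec = label_spec,
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "flow_scene")
}

# 5 labels: an outer "brain" ellipsoid with four disjoint substructures.
.default_label_spec <- function(grid) {
  ctr <- as.numeric(grid$origin + grid$direction %*%
                      (grid$spacing * (grid$size - 1L) / 2))
  ext <- grid$spacing * (grid$size - 1L)
  u <- min(ext) / 2           # half-extent of the shortest axis
  list(
    list(center = ctr, semi_axes = u * c(0.62, 0.52, 0.57), label = 1L),
    list(center = ctr + u * c(0.25, 0.12, 0), semi_axes = u * c(0.16, 0.13, 0.15),
         label = 2L),
    list(center = ctr + u * c(-0.25, 0.12, 0), semi_axes = u * c(0.16, 0.13, 0.15),
         label = 3L),
    list(center = ctr + u * c(0, -0.2, 0.18), semi_axes = u * c(0.13, 0.12, 0.12),
         label = 4L),
    list(center = ctr + u * c(0, -0.2, -0.18), semi_axes = u * c(0.13, 0.12, 0.12),
         label = 5L))
}

# Every pair of ellipsoids must be nested (one inside the other) or
# disjoint; partial overlap would make the innermost-label rule ambiguous.
.check_nesting <- function(label_spec) {
  k <- length(label_spec)
  if (k < 1L) stop("label_spec must contain at least one ellipsoid")
  sphere <- .unit_sphere_samples()
  surface_in <- function(of, vs) {
    surf <- sweep(sphere %*% diag(of$semi_axes), 2L, of$center, "+")
    q <- rowSums(sweep(surf, 2L, vs$center, "-")^2 /
                   matrix(vs$semi_axes^2, nrow(surf), 3L, byrow = TRUE))
    q <= 1
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      ei <- label_spec[[i]]; ej <- label_spec[[j]]
      inside_ji <- surface_in(ej, ei)   # later surface vs earlier ellipsoid
      if (any(inside_ji) && !all(inside_ji)) {
        stop(sprintf("ellipsoids %d and %d overlap without nesting", i, j))
      }
      inside_ij <- surface_in(ei, ej)
      if (all(inside_ij)) {
        stop(sprintf(
          "ellipsoid %d (listed later) contains earlier ellipsoid %d", j, i))
      }
    }
  }
  invisible(TRUE)
}

.unit_sphere_samples <- function(n = 146L) {
  # deterministic quasi-uniform sphere covering (golden spiral)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# analytic label at stage-0 geometry: innermost (= last listed) containing
# ellipsoid wins; 0 outside all.
.analytic_labels <- function(label_spec, pts) {
  lab <- integer(nrow(pts))
  for (e in label_spec) {
    q <- rowSums(sweep(pts, 2L, e$center, "-")^2 /
                   matrix(e$semi_axes^2, nrow(pts), 3L, byrow = TRUE))
    lab[q <= 1] <- e$label
  }
  lab
}

#' Closed-form flow map of a scene between two normalized times
#'
#' Returns the exact point mapper of the scene's flow from `t0` to `t1`
#' (identity when `t0 == t1`; the inverse map when `t1 < t0`).  The maps of
#' all flow kinds form one-parameter groups, so composing `t0 -> s -> t1`
#' equals mapping `t0 -> t1` exactly.
#'
#' @param scene a [flow_scene].
#' @param t0,t1 normalized times in \[0, 1\].
#' @return a function mapping an n x 3 point matrix to an n x 3 matrix.
#' @export
ground_truth_map <- function(scene, t0, t1) {
  stopifnot(inherits(scene, "flow_scene"))
  for (t in c(t0, t1)) {
    if (!is.finite(t) || t < -1e-12 || t > 1 + 1e-12) {
      stop("times must lie in [0, 1]")
    }
  }
  p <- scene$parameters
  dt <- t1 - t0
  switch(scene$flow_kind,
    translation = function(x) {
      .as_points(x) + matrix(p$v * dt, nrow(.as_points(x)), 3L, byrow = TRUE)
    },
    affine = {
      E <- as.matrix(Matrix::expm(p$A * dt))
      function(x) {
        x <- .as_points(x)
        sweep(sweep(x, 2L, p$center, "-") %*% t(E), 2L, p$center, "+")
      }
    },
    radial_growth = {
      s <- (1 + p$beta * t1) / (1 + p$beta * t0)
      function(x) {
        x <- .as_points(x)
        sweep(sweep(x, 2L, p$center, "-") * s, 2L, p$center, "+")
      }
    },
    composite = {
      Maug <- rbind(cbind(p$A, p$v), c(0, 0, 0, 0))
      E <- as.matrix(Matrix::expm(Maug * dt))
      function(x) {
        x <- .as_points(x)
        xc <- sweep(x, 2L, p$center, "-")
        sweep(xc %*% t(E[1:3, 1:3]), 2L, p$center + E[1:3, 4], "+")
      }
    })
}

# Instantaneous analytic velocity of the scene's flow at (x, t), mm per
# unit normalized time.
.scene_velocity <- function(scene, x, t) {
  x <- .as_points(x)
  p <- scene$parameters
  switch(scene$flow_kind,
    translation = matrix(p$v, nrow(x), 3L, byrow = TRUE),
    affine = sweep(x, 2L, p$center, "-") %*% t(p$A),
    radial_growth = sweep(x, 2L, p$center, "-") * (p$beta / (1 + p$beta * t)),
    composite = sweep(x, 2L, p$center, "-") %*% t(p$A) +
      matrix(p$v, nrow(x), 3L, byrow = TRUE))
}

#' Sample a scene's analytic velocity onto a velocity-field container
#'
#' Useful as an exact ground-truth [velocity_field]: integrating it should
#' reproduce [ground_truth_map] up to interpolation and RK4 error.
#'
#' @param scene a [flow_scene].
#' @param grid spatial grid for the field (default the scene grid).
#' @param n_slices number of time slices.
#' @return a [velocity_field].
#' @export
scene_velocity_field <- function(scene, grid = scene$grid, n_slices = 11L) {
  x <- .grid_voxel_centers(grid)
  st <- seq(0, 1, length.out = n_slices)
  vec <- array(0, dim = c(grid$size, n_slices, 3L))
  for (k in seq_len(n_slices)) {
    vec[, , , k, ] <- array(.scene_velocity(scene, x, st[k]),
                            dim = c(grid$size, 3L))
  }
  velocity_field(grid, vec)
}

#' Rasterize a scene's label geometry at every stage
#'
#' Stage s is produced by mapping each voxel center backward through the
#' closed-form flow to time 0 and reading the analytic ellipsoid label
#' there, so rasters contain no interpolation error and the vocabulary is
#' constant across stages.
#'
#' @param scene a [flow_scene].
#' @return list of [label_image]s, one per stage.
#' @export
generate_label_series <- function(scene) {
  stopifnot(inherits(scene, "flow_scene"))
  x <- .grid_voxel_centers(scene$grid)
  lapply(scene$stage_times, function(ts) {
    y <- if (ts == 0) x else ground_truth_map(scene, ts, 0)(x)
    label_image(scene$grid,
                array(.analytic_labels(scene$label_spec, y),
                      dim = scene$grid$size))
  })
}

#' Rasterize a scene's labels at one (possibly unsampled) time
#'
#' @param scene a [flow_scene].
#' @param t normalized time in \[0, 1\].
#' @return a [label_image].
#' @export
rasterize_scene_labels <- function(scene, t) {
  x <- .grid_voxel_centers(scene$grid)
  y <- if (t == 0) x else ground_truth_map(scene, t, 0)(x)
  label_image(scene$grid,
              array(.analytic_labels(scene$label_spec, y),
                    dim = scene$grid$size))
}

#' Generate ground-truth point trajectories from a scene
#'
#' Samples contour/region points from the rasterized stage-0 labels
#' (via [extract_label_points]), chains them through the closed-form flow to
#' every stage (via [assemble_trajectories]), then adds seeded isotropic
#' Gaussian jitter of sd `scene$noise_sd` (mm) to every non-reference stage.
#'
#' @param scene a [flow_scene].
#' @param contour_fraction,region_fraction sampling fractions (defaults
#'   0.10 and 0.01).
#' @return a [point_trajectory_set].
#' @export
generate_trajectories <- function(scene, contour_fraction = 0.10,
                                  region_fraction = 0.01) {
  stopifnot(inherits(scene, "flow_scene"))
  labels0 <- rasterize_scene_labels(scene, 0)
  samp <- extract_label_points(labels0, contour_fraction, region_fraction,
                               seed = scene$seed)
  transports <- lapply(seq_len(scene$n_stages - 1L), function(s) {
    ground_truth_map(scene, scene$stage_times[s], scene$stage_times[s + 1L])
  })
  traj <- assemble_trajectories(samp$points, samp$kinds, samp$label_ids,
                                transports)
  if (scene$noise_sd > 0) {
    rng <- .with_seed(scene$seed + 1000L)
    on.exit(rng(), add = TRUE)
    for (s in 2:scene$n_stages) {
      traj$coords[, s, ] <- traj$coords[, s, ] +
        matrix(stats::rnorm(3L * traj$n_points, sd = scene$noise_sd),
               traj$n_points, 3L)
    }
  }
  traj
}
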