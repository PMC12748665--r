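# The iterative optimizer: turns corresponding point trajectories into a
# time-varying velocity field.
#
# Each iteration freezes the current field, then for every integration slice
# transports the bracketing stages' points to the slice time through the
# field (forward from the earlier stage, backward from the later one),
# measures the per-point residual between the two branches, fits a smooth
# B-spline update to the half-residuals at the branch midpoints, and adds a
# step-size-scaled fraction of it to the slice.  The residual is scaled by
# the inverse slice spacing (M - 1): a unit velocity bump at one slice
# contributes 1/(M - 1) to the integrated displacement (its temporal hat
# function has that integral), so the scaled update expresses the desired
# correction as a velocity per unit normalized time and the step size stays
# dimensionless.

#' Optimizer configuration for velocity-field fitting
#'
#' @param n_integration_points number M of velocity time slices (>= 2).
#' @param max_iterations iteration budget (>= 1).
#' @param step_size update step delta in \[0, 1\]; 0 leaves the field
#'   unchanged every iteration (useful as a diagnostic no-op).
#' @param convergence_tol stop when the weighted mean branch mismatch (mm)
#'   falls below this; the default 0 runs the full iteration budget.
#' @param base_mesh_size,n_levels,spline_order B-spline update mesh
#'   parameters (see [bspline_mesh]).
#' @param n_steps RK4 steps per unit normalized time used for point
#'   transports during fitting; default `2 * (M - 1)` so every inter-slice
#'   interval is crossed by at least two steps.
#' @param renormalize_weights divide point weights by their mean so the
#'   effective step size is independent of sampling density (default TRUE).
#' @param seed recorded for provenance (the optimizer itself is
#'   deterministic).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(n_integration_points = 11L, max_iterations = 200L,
                       step_size = 0.2, convergence_tol = 0,
                       base_mesh_size = c(4, 4, 4), n_levels = 4L,
                       spline_order = 3L, n_steps = NULL,
                       renormalize_weights = TRUE, seed = 1L) {
  M <- as.integer(n_integration_points)
  if (M < 2L) stop("n_integration_points must be >= 2")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (step_size < 0 || step_size > 1) stop("step_size must lie in [0, 1]")
  if (is.null(n_steps)) n_steps <- 2L * (M - 1L)
  structure(list(n_integration_points = M,
                 max_iterations = as.integer(max_iterations),
                 step_size = step_size, convergence_tol = convergence_tol,
                 base_mesh_size = base_mesh_size,
                 n_levels = as.integer(n_levels),
                 spline_order = as.integer(spline_order),
                 n_steps = as.integer(n_steps),
                 renormalize_weights = isTRUE(renormalize_weights),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit a time-varying velocity field to corresponding point sets
#'
#' Minimizes the weighted average Euclidean mismatch between point sets
#' transported to common slice times from their bracketing stages, by
#' iteratively adding regularized (B-spline smoothed) update fields to each
#' of the M uniformly spaced velocity slices.  The field starts at zero, so
#' the first trace entry equals the mean inter-stage mismatch under the
#' identity transform, and a zero step size leaves the field unchanged.
#'
#' @param traj a [point_trajectory_set]; stage count must match the
#'   timeline, and all coordinates must lie inside the physical box of
#'   `grid`.
#' @param timeline a [dev_timeline] giving the normalized stage times.
#' @param grid spatial [image_grid] of the fitted field (may be coarser than
#'   the images the field will later warp).
#' @param cfg a [fit_config].
#' @return an object of class `velocity_fit`: `field` (the fitted
#'   [velocity_field]), `convergence_trace` (weighted mean mismatch in mm,
#'   one entry per iteration), `per_slice_trace` (iterations x M matrix of
#'   median mismatch per slice), `converged_at` (iteration index or `NA`).
#' @export
fit_time_varying_velocity <- function(traj, timeline, grid,
                                      cfg = fit_config()) {
  stopifnot(inherits(traj, "point_trajectory_set"),
            inherits(timeline, "dev_timeline"),
            inherits(grid, "image_grid"),
            inherits(cfg, "fit_config"))
  Tn <- length(timeline$normalized_times)
  if (traj$n_stages != Tn) {
    stop("trajectory has ", traj$n_stages, " stages but timeline has ", Tn)
  }
  if (Tn < 2L) stop("need at least two stages")
  # all stage coordinates must lie inside the grid's physical box
  all_pts <- matrix(traj$coords, ncol = 3L)
  ci <- physical_to_index(grid, all_pts)
  hi <- matrix(grid$size - 1L, nrow(ci), 3L, byrow = TRUE)
  if (any(ci < -1e-6) || any(ci - hi > 1e-6)) {
    stop("trajectory coordinates fall outside the velocity grid's physical box")
  }
  M <- cfg$n_integration_points
  slice_times <- seq(0, 1, length.out = M)
  nt <- timeline$normalized_times
  intervals <- vapply(slice_times, function(s) .stage_interval(timeline, s),
                      integer(1))
  w <- traj$weights
  if (cfg$renormalize_weights) w <- w / mean(w)
  mesh <- bspline_mesh(grid, base_mesh_size = cfg$base_mesh_size,
                       n_levels = cfg$n_levels, order = cfg$spline_order)
  settings <- integration_settings(cfg$n_steps)
  vf <- zero_velocity_field(grid, M, timeline)
  trace <- numeric(0)
  per_slice <- matrix(NA_real_, 0, M)
  converged_at <- NA_integer_
  for (it in seq_len(cfg$max_iterations)) {
    # frozen-field (Jacobi) pass: residuals for every slice are measured
    # against the field as of the start of the iteration
    upd <- vector("list", M)
    err_wsum <- 0; wsum <- 0
    med <- numeric(M)
    for (k in seq_len(M)) {
      s_k <- slice_times[k]
      i <- intervals[k]; j <- i + 1L
      qf <- integrate_velocity_field_at_points(vf, traj$coords[, i, ],
                                               nt[i], s_k, settings)
      qb <- integrate_velocity_field_at_points(vf, traj$coords[, j, ],
                                               nt[j], s_k, settings)
      r <- qb - qf
      if (!all(is.finite(r))) {
        stop(sprintf("non-finite residuals at iteration %d, slice %d", it, k))
      }
      mid <- (qf + qb) / 2
      en <- sqrt(rowSums(r^2))
      err_wsum <- err_wsum + sum(w * en)
      wsum <- wsum + sum(w)
      med[k] <- stats::median(en)
      upd[[k]] <- fit_bspline_scattered(mid, r / 2 * (M - 1), w, mesh, grid)
    }
    metric <- err_wsum / wsum
    trace <- c(trace, metric)
    per_slice <- rbind(per_slice, med)
    for (k in seq_len(M)) {
      sel <- .slice_flat_indices(grid$size, M, k)
      vf$vectors[sel] <- vf$vectors[sel] +
        cfg$step_size * as.vector(upd[[k]]$vectors)
    }
    if (metric < cfg$convergence_tol) {
      converged_at <- it
      break
    }
  }
  dimnames(per_slice) <- NULL
  structure(list(field = vf, convergence_trace = trace,
                 per_slice_trace = per_slice, converged_at = converged_at,
                 config = cfg),
            class = "velocity_fit")
}

# flat indices of slice k in a c(size, M, 3) array
.slice_flat_indices <- function(size, M, k) {
  vox <- prod(size)
  base <- (k - 1L) * vox
  comp_stride <- vox * M
  c(base + seq_len(vox),
    base + comp_stride + seq_len(vox),
    base + 2L * comp_stride + seq_len(vox))
}

#' @export
print.velocity_fit <- function(x, ...) {
  n <- length(x$convergence_trace)
  cat("velocity_fit:", x$field$n_slices, "slices on",
      paste(x$field$grid$size, collapse = "x"), "grid;",
      n, "iterations\n")
  if (n > 0) {
    cat(sprintf("  mean mismatch: %.4g mm -> %.4g mm%s\n",
                x$convergence_trace[1], x$convergence_trace[n],
                if (!is.na(x$converged_at))
                  paste0(" (converged at ", x$converged_at, ")") else ""))
  }
  invisible(x)
}

#' Compare velocity-field warping with supplied pairwise transports
#'
#' For every adjacent stage pair, warps the earlier stage's labels into the
#' later stage's space twice -- once through the fitted velocity field and
#' once through the supplied pairwise transport -- and reports per-label
#' Dice overlap against the later stage's labels.  Reporting only; no
#' thresholding is applied.
#'
#' @param fitted a `velocity_fit` or [velocity_field].
#' @param timeline the [dev_timeline] used for the fit.
#' @param label_series list of [label_image]s on one shared grid, one per
#'   stage.
#' @param pairwise_transports list of `T - 1` resampling maps, one per
#'   adjacent pair: each maps stage-`s+1` physical coordinates to stage-`s`
#'   coordinates (a function or a [displacement_field]).
#' @param settings an [integration_settings].
#' @return a data.frame with columns `stage_pair`, `label`,
#'   `dice_velocity`, `dice_pairwise`.
#' @export
evaluate_against_pairwise <- function(fitted, timeline, label_series,
                                      pairwise_transports,
                                      settings = integration_settings()) {
  vf <- if (inherits(fitted, "velocity_fit")) fitted$field else fitted
  stopifnot(inherits(vf, "velocity_field"),
            inherits(timeline, "dev_timeline"))
  Tn <- length(label_series)
  if (length(pairwise_transports) != Tn - 1L) {
    stop("need one pairwise transport per adjacent stage pair (",
         Tn - 1L, "), got ", length(pairwise_transports))
  }
  grid <- label_series[[1]]$grid
  for (li in label_series) {
    if (!.grids_equal(li$grid, grid)) stop("label series must share one grid")
  }
  nt <- timeline$normalized_times
  x <- .grid_voxel_centers(grid)
  rows <- list()
  for (s in seq_len(Tn - 1L)) {
    target <- label_series[[s + 1L]]
    disp_vel <- integrate_velocity_field(vf, nt[s + 1L], nt[s], settings,
                                         grid = grid)
    warped_vel <- warp_image(label_series[[s]], disp_vel)
    mapped <- .apply_transport(pairwise_transports[[s]], x)
    disp_pw <- displacement_field(grid, array(mapped - x,
                                              dim = c(grid$size, 3L)))
    warped_pw <- warp_image(label_series[[s]], disp_pw)
    for (lab in target$vocabulary) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage_pair = sprintf("%d->%d", s, s + 1L),
        label = lab,
        dice_velocity = dice_coefficient(warped_vel, target, lab),
        dice_pairwise = dice_coefficient(warped_pw, target, lab))
    }
  }
  do.call(rbind, rows)
}
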