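# Optimizer tests run at desk scale: 24^3 scene rasters, 12^3 velocity
# grids, a handful of stages.  The closed-form generator flows provide the
# recovery oracle.

toy_fit <- function(flow_kind = "translation", iters = 25L, M = 6L,
                    n_stages = 3L, ...) {
  scene <- h_toy_scene(flow_kind, n_stages = n_stages, ...)
  traj <- generate_trajectories(scene)
  tl <- h_uniform_timeline(n_stages)
  vgrid <- h_velocity_grid(scene$grid)
  fit <- fit_time_varying_velocity(
    traj, tl, vgrid,
    fit_config(n_integration_points = M, max_iterations = iters,
               step_size = 0.2))
  list(scene = scene, traj = traj, tl = tl, fit = fit)
}

test_that("static anatomy is a zero-residual fixed point", {
  scene <- h_toy_scene("translation")
  traj <- generate_trajectories(scene)
  for (s in 2:3) traj$coords[, s, ] <- traj$coords[, 1, ]
  fit <- fit_time_varying_velocity(
    traj, h_uniform_timeline(3), h_velocity_grid(scene$grid),
    fit_config(n_integration_points = 4, max_iterations = 2))
  expect_equal(fit$convergence_trace, c(0, 0))
  expect_lt(max(abs(fit$field$vectors)), 1e-9)
})

test_that("the first trace entry equals the identity-transform mismatch", {
  r <- toy_fit(iters = 1L, M = 4L)
  # with a zero field every slice measures its bracketing stage pair
  # directly; accumulate the same weighted mean from the raw coordinates
  nt <- r$tl$normalized_times
  w <- r$traj$weights / mean(r$traj$weights)
  slice_times <- seq(0, 1, length.out = 4)
  num <- 0; den <- 0
  for (s_k in slice_times) {
    i <- if (s_k < nt[2] || (s_k == nt[2] && s_k < 1)) 1L else 2L
    mism <- sqrt(rowSums((r$traj$coords[, i + 1L, ] -
                            r$traj$coords[, i, ])^2))
    num <- num + sum(w * mism); den <- den + sum(w)
  }
  expect_equal(r$fit$convergence_trace[1], num / den, tolerance = 1e-12)
})

test_that("a zero step size never changes the field and the trace is constant", {
  scene <- h_toy_scene("radial_growth")
  traj <- generate_trajectories(scene)
  fit <- fit_time_varying_velocity(
    traj, h_uniform_timeline(3), h_velocity_grid(scene$grid),
    fit_config(n_integration_points = 4, max_iterations = 3, step_size = 0))
  expect_equal(max(abs(fit$field$vectors)), 0)
  expect_equal(length(unique(fit$convergence_trace)), 1L)
})

test_that("the fitted field recovers a translation flow from 3 stages", {
  r <- toy_fit("translation", iters = 25L, parameters = list(v = c(2.5, 1, -1)))
  expect_equal(length(r$fit$convergence_trace), 25L)
  # trace decays monotonically after the first few iterations and by >= 50%
  tr <- r$fit$convergence_trace
  expect_true(all(diff(tr[5:25]) <= 1e-12))
  expect_lt(tr[25], 0.5 * tr[1])
  # endpoint transport matches the last-stage points
  phi <- integrate_velocity_field_at_points(
    r$fit$field, r$traj$coords[, 1, ], 0, 1, integration_settings(12))
  err <- stats::median(sqrt(rowSums((phi - r$traj$coords[, 3, ])^2)))
  expect_lt(err, 0.02 * h_domain_diagonal(r$scene$grid))
})

test_that("per-slice traces are recorded for every integration point", {
  r <- toy_fit(iters = 4L, M = 5L)
  expect_equal(dim(r$fit$per_slice_trace), c(4L, 5L))
  expect_true(all(is.finite(r$fit$per_slice_trace)))
})

test_that("convergence tolerance stops the fit early and flags converged_at", {
  scene <- h_toy_scene("translation", parameters = list(v = c(1, 0.5, 0)))
  traj <- generate_trajectories(scene)
  fit <- fit_time_varying_velocity(
    traj, h_uniform_timeline(3), h_velocity_grid(scene$grid),
    fit_config(n_integration_points = 4, max_iterations = 100,
               convergence_tol = 0.05))
  expect_false(is.na(fit$converged_at))
  expect_lt(length(fit$convergence_trace), 100L)
  expect_lt(utils::tail(fit$convergence_trace, 1), 0.05)
})

test_that("mismatched stage counts and out-of-box points are rejected", {
  scene <- h_toy_scene("translation")
  traj <- generate_trajectories(scene)
  expect_error(fit_time_varying_velocity(
    traj, h_uniform_timeline(4), h_velocity_grid(scene$grid), fit_config()),
    "stages")
  tiny <- image_grid(c(4, 4, 4), spacing = c(1, 1, 1))
  expect_error(fit_time_varying_velocity(
    traj, h_uniform_timeline(3), tiny, fit_config()),
    "physical box")
})

test_that("velocity warping tracks the exact pairwise baseline in Dice", {
  r <- toy_fit("radial_growth", iters = 30L)
  series <- generate_label_series(r$scene)
  nt <- r$tl$normalized_times
  transports <- lapply(1:2, function(s) {
    ground_truth_map(r$scene, nt[s + 1], nt[s])
  })
  tab <- evaluate_against_pairwise(r$fit, r$tl, series, transports,
                                   integration_settings(12))
  expect_true(all(tab$dice_velocity >= 0 & tab$dice_velocity <= 1))
  expect_true(all(tab$dice_pairwise >= 0 & tab$dice_pairwise <= 1))
  gap <- mean(tab$dice_pairwise) - mean(tab$dice_velocity)
  expect_lt(gap, 0.05)
  # identity series with identity transports scores 1 everywhere
  same <- list(series[[1]], series[[1]])
  zf <- zero_velocity_field(r$fit$field$grid, 3, r$tl)
  tl2 <- h_uniform_timeline(2)
  tab2 <- evaluate_against_pairwise(zf, tl2, same, list(identity))
  expect_true(all(tab2$dice_velocity == 1))
  expect_true(all(tab2$dice_pairwise == 1))
})
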