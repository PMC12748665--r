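# Builds velocity containers directly (no generator involvement) so the
# closed-form oracles stay independent of the synthetic-data module.

linear_velocity_field <- function(grid, A, center, n_slices = 5L) {
  x <- index_to_physical(grid,
                         as.matrix(expand.grid(seq_len(grid$size[1]) - 1,
                                               seq_len(grid$size[2]) - 1,
                                               seq_len(grid$size[3]) - 1)))
  v <- sweep(x, 2, center, "-") %*% t(A)
  vec <- array(0, dim = c(grid$size, n_slices, 3L))
  for (k in seq_len(n_slices)) {
    vec[, , , k, ] <- array(v, dim = c(grid$size, 3L))
  }
  velocity_field(grid, vec)
}

test_that("space-time velocity interpolation blends bracketing slices linearly", {
  g <- h_grid(8)
  vec <- array(0, dim = c(g$size, 2, 3))
  vec[, , , 2, 1] <- 2                      # slice 1: 0, slice 2: (2,0,0)
  vf <- velocity_field(g, vec)
  p <- matrix(c(3.2, 4.1, 2.7), 1, 3)
  expect_equal(velocity_at(vf, p, 0), matrix(0, 1, 3))
  expect_equal(velocity_at(vf, p, 1), matrix(c(2, 0, 0), 1, 3))
  expect_equal(velocity_at(vf, p, 0.5), matrix(c(1, 0, 0), 1, 3))
  # constant-in-time field: result independent of t
  cf <- h_constant_velocity(g, c(1, -2, 0.5), 4)
  expect_equal(velocity_at(cf, p, 0.13), velocity_at(cf, p, 0.87))
})

test_that("a constant flow integrates to the exact translation", {
  g <- h_grid(20)
  vf <- h_constant_velocity(g, c(1, 0, 0))
  d <- integrate_velocity_field(vf, 0, 0.5, integration_settings(10))
  interior <- h_interior(d$vectors, 2)
  expect_lt(max(abs(interior[, , , 1] - 0.5)), 1e-9)
  expect_lt(max(abs(interior[, , , 2:3])), 1e-9)
  # t0 == t1 gives an identically zero displacement
  d0 <- integrate_velocity_field(vf, 0.3, 0.3)
  expect_equal(max(abs(d0$vectors)), 0)
  expect_error(integrate_velocity_field(vf, -0.1, 1), "\\[0, 1\\]")
})

test_that("RK4 on a linear flow matches the matrix-exponential oracle", {
  g <- h_grid(20)
  A <- diag(c(0.2, 0, 0))
  ctr <- c(9.5, 9.5, 9.5)
  vf <- linear_velocity_field(g, A, ctr)
  set.seed(5)
  pts <- matrix(runif(300, 4, 15), 100, 3)
  oracle <- sweep(sweep(pts, 2, ctr, "-") %*% t(as.matrix(Matrix::expm(A))),
                  2, ctr, "+")
  got <- integrate_velocity_field_at_points(vf, pts, 0, 1,
                                            integration_settings(10))
  rel <- max(sqrt(rowSums((got - oracle)^2))) /
    max(sqrt(rowSums(oracle^2)))
  expect_lt(rel, 1e-6)
  # empty input passes through
  expect_equal(nrow(integrate_velocity_field_at_points(
    vf, matrix(0, 0, 3), 0, 1)), 0L)
})

test_that("halving the RK4 step size shows fourth-order error decay", {
  g <- h_grid(20)
  A <- matrix(c(0.1, 0.15, 0, -0.15, 0.1, 0, 0, 0, 0.05), 3, 3)
  ctr <- c(9.5, 9.5, 9.5)
  vf <- linear_velocity_field(g, A, ctr)
  set.seed(6)
  pts <- matrix(runif(300, 5, 14), 100, 3)
  oracle <- sweep(sweep(pts, 2, ctr, "-") %*% t(as.matrix(Matrix::expm(A))),
                  2, ctr, "+")
  err <- vapply(c(5L, 10L), function(ns) {
    got <- integrate_velocity_field_at_points(vf, pts, 0, 1,
                                              integration_settings(ns))
    max(sqrt(rowSums((got - oracle)^2)))
  }, numeric(1))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("point-wise and raster integration agree at voxel centers", {
  g <- h_grid(12)
  A <- matrix(c(0.1, 0.15, 0, -0.15, 0.1, 0, 0, 0, 0.05), 3, 3)
  vf <- linear_velocity_field(g, A, c(5.5, 5.5, 5.5))
  d <- integrate_velocity_field(vf, 0, 0.7, integration_settings(10))
  x <- index_to_physical(g, as.matrix(expand.grid(0:11, 0:11, 0:11)))
  phi <- integrate_velocity_field_at_points(vf, x, 0, 0.7,
                                            integration_settings(10))
  expect_lt(max(abs(phi - x - matrix(d$vectors, ncol = 3))), 1e-9)
})

test_that("flows satisfy the group property and forward-backward consistency", {
  g <- h_grid(20)
  A <- matrix(c(0.1, 0.15, 0, -0.15, 0.1, 0, 0, 0, 0.05), 3, 3)
  vf <- linear_velocity_field(g, A, c(9.5, 9.5, 9.5))
  s <- integration_settings(10)
  set.seed(8)
  p0 <- matrix(runif(300, 5, 14), 100, 3)
  two_leg <- integrate_velocity_field_at_points(
    vf, integrate_velocity_field_at_points(vf, p0, 0, 0.5, s), 0.5, 1, s)
  one_leg <- integrate_velocity_field_at_points(vf, p0, 0, 1, s)
  expect_lt(max(sqrt(rowSums((two_leg - one_leg)^2))), 1e-5)
  # forward then backward returns to the start well under 0.05 x spacing
  back <- integrate_velocity_field_at_points(vf, one_leg, 1, 0, s)
  expect_lt(mean(sqrt(rowSums((back - p0)^2))), 0.05 * min(g$spacing))
})

test_that("displacement inversion composes to near-identity and is involutive", {
  g <- h_grid(20)
  A <- matrix(c(0.1, 0.15, 0, -0.15, 0.1, 0, 0, 0, 0.05), 3, 3)
  vf <- linear_velocity_field(g, A, c(9.5, 9.5, 9.5))
  disp <- integrate_velocity_field(vf, 0, 1, integration_settings(10))
  expect_lt(max(abs(disp$vectors)) / min(g$spacing), 3)  # smooth, ~2 voxels
  inv <- invert_displacement_field(disp)
  comp <- compose_displacement_fields(disp, inv)
  res <- array(sqrt(rowSums(matrix(comp$vectors, ncol = 3)^2)), g$size)
  expect_lt(max(h_interior(res, 3)) / min(g$spacing), 0.1)
  # inverse of the inverse recovers the original (interior)
  inv2 <- invert_displacement_field(inv)
  diff <- array(sqrt(rowSums(matrix(inv2$vectors - disp$vectors,
                                    ncol = 3)^2)), g$size)
  expect_lt(max(h_interior(diff, 3)) / min(g$spacing), 0.1)
  # zero field inverts to zero
  z <- invert_displacement_field(zero_displacement_field(g))
  expect_equal(max(abs(z$vectors)), 0)
})

test_that("inversion reports divergence on a non-invertible field", {
  g <- h_grid(10)
  x <- index_to_physical(g, as.matrix(expand.grid(0:9, 0:9, 0:9)))
  u <- 1.2 * sweep(x, 2, c(4.5, 4.5, 4.5), "-")  # fixed-point map expands
  disp <- displacement_field(g, array(u, c(g$size, 3)))
  expect_error(invert_displacement_field(disp, max_iters = 50), "diverg")
})
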