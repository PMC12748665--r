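test_that("ground-truth maps form exact one-parameter groups", {
  for (kind in c("translation", "affine", "radial_growth", "composite")) {
    scene <- h_toy_scene(kind)
    set.seed(9)
    pts <- matrix(runif(60, 6, 18), 20, 3)
    # t0 == t1 is the identity
    expect_equal(ground_truth_map(scene, 0.4, 0.4)(pts), pts)
    # forward then backward is the identity
    fwd <- ground_truth_map(scene, 0, 1)(pts)
    back <- ground_truth_map(scene, 1, 0)(fwd)
    expect_lt(max(abs(back - pts)), 1e-12)
    # two legs equal one leg
    mid <- ground_truth_map(scene, 0, 0.3)(pts)
    two <- ground_truth_map(scene, 0.3, 1)(mid)
    expect_lt(max(abs(two - fwd)), 1e-12)
  }
})

test_that("radial growth scales radii by (1 + beta t)", {
  scene <- h_toy_scene("radial_growth", parameters = list(beta = 0.2))
  ctr <- scene$parameters$center
  p <- matrix(ctr + c(3, 0, 0), 1, 3)
  q <- ground_truth_map(scene, 0, 1)(p)
  expect_equal(sqrt(sum((q - ctr)^2)), 3 * 1.2, tolerance = 1e-12)
})

test_that("scene parameters outside the invertibility range are rejected", {
  expect_error(h_toy_scene("radial_growth", parameters = list(beta = 0.7)),
               "beta")
  expect_error(h_toy_scene("affine", parameters = list(A = diag(3) * 0.6)),
               "norm")
})

test_that("label rasters keep a constant vocabulary and move with the flow", {
  scene <- h_toy_scene("translation", parameters = list(v = c(2, 1, -1)))
  series <- generate_label_series(scene)
  vocabs <- lapply(series, function(s) s$vocabulary)
  for (v in vocabs) expect_identical(v, vocabs[[1]])
  centroid <- function(img, lab) {
    idx <- which(img$labels == lab, arr.ind = TRUE) - 1
    colMeans(index_to_physical(img$grid, idx))
  }
  for (lab in c(1L, 2L)) {
    move <- centroid(series[[3]], lab) - centroid(series[[1]], lab)
    expect_lt(max(abs(move - c(2, 1, -1))), 0.5 * max(scene$grid$spacing))
  }
  # a zero-velocity translation freezes the scene
  frozen <- generate_label_series(
    h_toy_scene("translation", parameters = list(v = c(0, 0, 0))))
  expect_identical(frozen[[1]]$labels, frozen[[3]]$labels)
})

test_that("rasterization error floor: warped stage-0 labels match stage rasters", {
  # default-resolution scene (48^3 at 0.5 mm); nearest-neighbour warping of
  # the stage-0 raster through the exact flow loses only surface voxels
  scene <- flow_scene("radial_growth", n_stages = 3)
  series <- generate_label_series(scene)
  x <- index_to_physical(scene$grid,
                         as.matrix(expand.grid(0:47, 0:47, 0:47)))
  whole <- function(img) {
    label_image(img$grid, array(as.integer(img$labels > 0), img$grid$size))
  }
  for (s in 2:3) {
    mapper <- ground_truth_map(scene, scene$stage_times[s], 0)
    disp <- displacement_field(scene$grid,
                               array(mapper(x) - x, c(scene$grid$size, 3)))
    warped <- warp_image(series[[1]], disp)
    expect_gte(dice_coefficient(whole(warped), whole(series[[s]]), 1L), 0.95)
  }
  # the backward-mapped rasters themselves are exact: re-rasterizing at a
  # stage time reproduces the series image identically
  expect_identical(rasterize_scene_labels(scene, scene$stage_times[2])$labels,
                   series[[2]]$labels)
})

test_that("inconsistently overlapping ellipsoids are rejected", {
  g <- h_grid(24)
  bad <- list(
    list(center = c(10, 10, 10), semi_axes = c(5, 5, 5), label = 1L),
    list(center = c(14, 10, 10), semi_axes = c(4, 4, 4), label = 2L))
  expect_error(flow_scene("translation", grid = g, label_spec = bad),
               "nesting")
})

test_that("trajectory noise has the expected chi-distributed magnitude", {
  scene <- flow_scene("translation", parameters = list(v = c(1, 0.5, 0)),
                      noise_sd = 0.1, seed = 11)
  noisy <- generate_trajectories(scene, contour_fraction = 0.35,
                                 region_fraction = 0.05)
  clean_scene <- scene; clean_scene$noise_sd <- 0
  clean <- generate_trajectories(clean_scene, contour_fraction = 0.35,
                                 region_fraction = 0.05)
  expect_gte(noisy$n_points, 1000L)
  dev <- noisy$coords[, 2:3, ] - clean$coords[, 2:3, ]
  rms <- sqrt(mean(rowSums(array(dev, c(dim(dev)[1] * 2, 3))^2)))
  expect_equal(rms, 0.1 * sqrt(3), tolerance = 0.1)
  # the reference stage is never jittered
  expect_equal(noisy$coords[, 1, ], clean$coords[, 1, ])
})

test_that("sampled analytic velocity integrates to the closed-form map", {
  scene <- h_toy_scene("composite")
  vf <- scene_velocity_field(scene, scene$grid, 7)
  set.seed(12)
  pts <- matrix(runif(90, 7, 17), 30, 3)
  got <- integrate_velocity_field_at_points(vf, pts, 0, 1,
                                            integration_settings(12))
  want <- ground_truth_map(scene, 0, 1)(pts)
  expect_lt(max(sqrt(rowSums((got - want)^2))), 1e-4)
})
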