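# Shared fixture builders.  Everything is generated in code; no files.

# small unit-spacing grid
h_grid <- function(n = 20L, spacing = 1, origin = 0) {
  image_grid(rep(n, 3L), rep(spacing, 3L), rep(origin, 3L))
}

# uniform normalized stage times via exponentially spaced ages
h_uniform_timeline <- function(n_stages) {
  normalize_stage_times(exp(seq(0, 1, length.out = n_stages)))
}

# velocity field with identical vectors everywhere and on every slice
h_constant_velocity <- function(grid, v, n_slices = 3L) {
  vec <- array(0, dim = c(grid$size, n_slices, 3L))
  for (k in 1:3) vec[, , , , k] <- v[k]
  velocity_field(grid, vec)
}

# displacement field with a constant vector
h_constant_displacement <- function(grid, v) {
  vec <- array(0, dim = c(grid$size, 3L))
  for (k in 1:3) vec[, , , k] <- v[k]
  displacement_field(grid, vec)
}

# solid-cube label image: 10^3 cube inside an n^3 background grid
h_cube_label <- function(n = 14L, lo = 3L, hi = 12L) {
  g <- h_grid(n)
  lab <- array(0L, g$size)
  lab[lo:hi, lo:hi, lo:hi] <- 1L
  label_image(g, lab)
}

# desk-scale scene (24^3 at 1 mm) for quick optimizer tests
h_toy_scene <- function(flow_kind = "translation", n_stages = 3L, ...) {
  flow_scene(flow_kind, n_stages = n_stages,
             grid = image_grid(c(24, 24, 24), spacing = rep(1, 3)), ...)
}

# coarse velocity grid spanning the same physical box as a scene grid
h_velocity_grid <- function(scene_grid, n = 12L) {
  extent <- scene_grid$spacing * (scene_grid$size - 1L)
  image_grid(rep(n, 3L), extent / (n - 1L), scene_grid$origin,
             scene_grid$direction)
}

h_domain_diagonal <- function(grid) {
  sqrt(sum((grid$spacing * (grid$size - 1L))^2))
}

# interior slab of a 3-D/4-D array (drop m voxels per face)
h_interior <- function(arr, m = 3L) {
  d <- dim(arr)
  idx <- lapply(d[1:3], function(n) (m + 1L):(n - m))
  if (length(d) == 3L) arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  else arr[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
}
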