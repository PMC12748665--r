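# Virtual templates: synthesize an image at an unsampled time by warping
# the two bracketing stage templates to the target time through the fitted
# velocity field and averaging them voxel-wise.

#' Synthesize a virtual template at an unsampled time
#'
#' Each input template is warped from its stage time to `target_time` by
#' integrating the velocity field backward from the target (the resampling
#' map), and the warped images are combined as a weighted voxel-wise mean.
#' With `"inverse_temporal_distance"` weighting the weights are
#' `1 / (|stage_time - target_time| + 1e-6)`, normalized to sum to one, so
#' a target coinciding with a stage time reproduces that stage's template
#' up to interpolation error.
#'
#' @param inputs list of two `list(image =, time =)` pairs: a
#'   [scalar_image] and its normalized stage time.  The two stage times
#'   must bracket `target_time`.
#' @param target_time normalized time in \[0, 1\].
#' @param vf a fitted [velocity_field] covering both stage times.
#' @param settings an [integration_settings].
#' @param weighting `"inverse_temporal_distance"` (default) or `"equal"`.
#' @return a [scalar_image] on the input grid.
#' @export
synthesize_template <- function(inputs, target_time, vf,
                                settings = integration_settings(),
                                weighting = c("inverse_temporal_distance",
                                              "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(vf, "velocity_field"), length(inputs) == 2L)
  for (inp in inputs) {
    if (!inherits(inp$image, "scalar_image") || is.null(inp$time)) {
      stop("each input must be list(image = scalar_image, time = stage time)")
    }
  }
  times <- vapply(inputs, function(i) as.numeric(i$time), numeric(1))
  if (!is.finite(target_time) || target_time < 0 || target_time > 1) {
    stop("target_time must lie in [0, 1]")
  }
  if (min(times) - 1e-12 > target_time || max(times) + 1e-12 < target_time) {
    stop("input stage times must bracket the target time")
  }
  grid <- inputs[[1]]$image$grid
  if (!.grids_equal(inputs[[2]]$image$grid, grid)) {
    stop("input templates must share one grid")
  }
  wts <- switch(weighting,
    equal = c(0.5, 0.5),
    inverse_temporal_distance = {
      raw <- 1 / (abs(times - target_time) + 1e-6)
      raw / sum(raw)
    })
  acc <- array(0, dim = grid$size)
  for (i in 1:2) {
    disp <- integrate_velocity_field(vf, target_time, times[i], settings,
                                     grid = grid)
    warped <- warp_image(inputs[[i]]$image, disp)
    acc <- acc + wts[i] * warped$values
  }
  scalar_image(grid, acc)
}
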