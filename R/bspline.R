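# Multilevel weighted B-spline scattered-data approximation.
#
# The regularizer of the fitting loop: noisy per-point displacement residuals
# are turned into a smooth vector field by a tensor-product B-spline fit,
# refined over dyadic control-lattice levels (each level fits the residual of
# the previous one, so the composite field is the sum of the per-level
# fields).  Per level the control values follow the local weighted
# accumulation scheme: numerator sum(w * B^2 * phi_hat) and denominator
# sum(w * B^2), with phi_hat = B * value / sum(B^2) the single-point exact
# solution.

#' Describe a multilevel B-spline mesh
#'
#' @param domain an [image_grid] whose voxel centers bound the physical box
#'   the spline is parameterized over, or a list with elements `lower`,
#'   `extent` (length-3, mm) and `direction` (3x3).
#' @param base_mesh_size integer vector of length 3: control intervals per
#'   axis at the coarsest level (each >= 1).
#' @param n_levels integer >= 1: dyadic refinement levels; level L has
#'   `base_mesh_size * 2^(L-1)` intervals per axis.
#' @param order spline degree (1, 2 or 3; default cubic).
#' @return an object of class `bspline_mesh`.
#' @export
bspline_mesh <- function(domain, base_mesh_size = c(4, 4, 4), n_levels = 4L,
                         order = 3L) {
  if (inherits(domain, "image_grid")) {
    domain <- list(lower = domain$origin,
                   extent = domain$spacing * (domain$size - 1L),
                   direction = domain$direction)
  }
  stopifnot(is.list(domain),
            length(domain$lower) == 3L, length(domain$extent) == 3L)
  if (is.null(domain$direction)) domain$direction <- diag(3)
  base_mesh_size <- as.integer(base_mesh_size)
  if (length(base_mesh_size) == 1L) base_mesh_size <- rep(base_mesh_size, 3L)
  if (any(base_mesh_size < 1L)) stop("base_mesh_size components must be >= 1")
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  order <- as.integer(order)
  if (!order %in% 1:3) stop("spline order must be 1, 2 or 3")
  if (any(domain$extent <= 0)) stop("mesh domain must have positive extent")
  structure(list(domain = domain, base_mesh_size = base_mesh_size,
                 n_levels = n_levels, order = order),
            class = "bspline_mesh")
}

# Uniform B-spline basis values for local parameter t in [0,1]:
# returns length(t) x (order+1) matrix.
.ubspline_basis <- function(t, order) {
  if (order == 1L) {
    cbind(1 - t, t)
  } else if (order == 2L) {
    cbind((1 - t)^2 / 2, (-2 * t^2 + 2 * t + 1) / 2, t^2 / 2)
  } else {
    t2 <- t * t; t3 <- t2 * t
    cbind((1 - t)^3 / 6,
          (3 * t3 - 6 * t2 + 4) / 6,
          (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
          t3 / 6)
  }
}

# Map physical points into per-axis local coordinates q in [0, extent].
# Points outside the box are clamped (with a one-shot warning).
.mesh_local_coords <- function(mesh, points) {
  q <- sweep(points, 2L, mesh$domain$lower, "-") %*% mesh$domain$direction
  lo <- 0; hi <- matrix(mesh$domain$extent, nrow(q), 3L, byrow = TRUE)
  out_of_box <- any(q < -1e-9) || any(q - hi > 1e-9)
  if (out_of_box) {
    warning("some points lie outside the mesh domain; clamping to the box")
  }
  pmin(pmax(q, lo), hi)
}

# Per-axis spline coordinates at a given lattice resolution: interval index
# (0-based) and basis matrix.  m = intervals on that axis.
.axis_span <- function(q, extent, m, order) {
  u <- q / extent * m
  i <- pmin(floor(u), m - 1)
  list(i = i, B = .ubspline_basis(u - i, order))
}

# Fit one level: returns control-value array of dim c(nc, K) where
# nc = prod(m + order) and K = ncol(values).
.ba_fit_level <- function(qx, qy, qz, extent, values, weights, m, order) {
  sx <- .axis_span(qx, extent[1], m[1], order)
  sy <- .axis_span(qy, extent[2], m[2], order)
  sz <- .axis_span(qz, extent[3], m[3], order)
  d1 <- order + 1L
  ncx <- m[1] + order; ncy <- m[2] + order; ncz <- m[3] + order
  n <- length(qx); K <- ncol(values)
  ncomb <- d1^3
  # tensor-product basis weights and flat control indices, n x ncomb
  W <- matrix(0, n, ncomb)
  IDX <- matrix(0L, n, ncomb)
  c_ <- 0L
  for (dz in seq_len(d1) - 1L) {
    for (dy in seq_len(d1) - 1L) {
      for (dx in seq_len(d1) - 1L) {
        c_ <- c_ + 1L
        W[, c_] <- sx$B[, dx + 1L] * sy$B[, dy + 1L] * sz$B[, dz + 1L]
        IDX[, c_] <- (sx$i + dx) + ncx * ((sy$i + dy) + ncy * (sz$i + dz)) + 1L
      }
    }
  }
  sumB2 <- rowSums(W * W)
  nc <- ncx * ncy * ncz
  wB2 <- weights * W * W              # n x ncomb, recycled by column
  den <- numeric(nc)
  num <- matrix(0, nc, K)
  idx_v <- as.vector(IDX)
  den_acc <- rowsum(as.vector(wB2), idx_v)
  den[as.integer(rownames(den_acc))] <- den_acc
  for (k in seq_len(K)) {
    phi_hat <- (W * (values[, k] / sumB2))   # n x ncomb
    acc <- rowsum(as.vector(wB2 * phi_hat), idx_v)
    num[as.integer(rownames(acc)), k] <- acc
  }
  ctrl <- num
  nz <- den > 0
  ctrl[nz, ] <- ctrl[nz, , drop = FALSE] / den[nz]
  ctrl[!nz, ] <- 0
  list(ctrl = ctrl, W = W, IDX = IDX)
}

# Evaluate a level's control lattice at the fitting points, reusing the
# cached basis weights/indices.
.ba_eval_points_cached <- function(level, K) {
  n <- nrow(level$W)
  out <- matrix(0, n, K)
  for (c_ in seq_len(ncol(level$W))) {
    out <- out + level$W[, c_] * level$ctrl[level$IDX[, c_], , drop = FALSE]
  }
  out
}

# Evaluate control lattice at arbitrary physical points.
.ba_eval_points <- function(ctrl, mesh, m, points) {
  q <- .mesh_local_coords(mesh, points)
  lev <- list(ctrl = ctrl)
  sx <- .axis_span(q[, 1], mesh$domain$extent[1], m[1], mesh$order)
  sy <- .axis_span(q[, 2], mesh$domain$extent[2], m[2], mesh$order)
  sz <- .axis_span(q[, 3], mesh$domain$extent[3], m[3], mesh$order)
  d1 <- mesh$order + 1L
  ncx <- m[1] + mesh$order; ncy <- m[2] + mesh$order
  K <- ncol(ctrl)
  out <- matrix(0, nrow(q), K)
  for (dz in seq_len(d1) - 1L) {
    for (dy in seq_len(d1) - 1L) {
      for (dx in seq_len(d1) - 1L) {
        w <- sx$B[, dx + 1L] * sy$B[, dy + 1L] * sz$B[, dz + 1L]
        idx <- (sx$i + dx) + ncx * ((sy$i + dy) + ncy * (sz$i + dz)) + 1L
        out <- out + w * ctrl[idx, , drop = FALSE]
      }
    }
  }
  out
}

# Separable evaluation of one level on a full grid sharing the mesh
# direction.  Returns an array of dim c(grid$size, K).
.ba_eval_grid <- function(ctrl, mesh, m, grid) {
  if (max(abs(grid$direction - mesh$domain$direction)) > 1e-9) {
    vals <- .ba_eval_points(ctrl, mesh, m, .grid_voxel_centers(grid))
    return(array(vals, dim = c(grid$size, ncol(ctrl))))
  }
  order <- mesh$order
  nc <- m + order
  # per-axis dense basis matrices (grid samples x control points)
  basis_axis <- function(ax) {
    centers0 <- sum((grid$origin - mesh$domain$lower) *
                      mesh$domain$direction[, ax])
    q <- centers0 + (seq_len(grid$size[ax]) - 1) * grid$spacing[ax]
    q <- pmin(pmax(q, 0), mesh$domain$extent[ax])
    sp <- .axis_span(q, mesh$domain$extent[ax], m[ax], order)
    Bm <- matrix(0, grid$size[ax], nc[ax])
    for (d in 0:order) {
      Bm[cbind(seq_len(grid$size[ax]), sp$i + d + 1L)] <- sp$B[, d + 1L]
    }
    Bm
  }
  Bx <- basis_axis(1); By <- basis_axis(2); Bz <- basis_axis(3)
  K <- ncol(ctrl)
  out <- array(0, dim = c(grid$size, K))
  for (k in seq_len(K)) {
    A <- array(ctrl[, k], dim = nc)
    t1 <- Bx %*% matrix(A, nc[1], nc[2] * nc[3])            # gx x (c2*c3)
    t1 <- aperm(array(t1, dim = c(grid$size[1], nc[2], nc[3])), c(2, 1, 3))
    t2 <- By %*% matrix(t1, nc[2], grid$size[1] * nc[3])    # gy x (gx*c3)
    t2 <- aperm(array(t2, dim = c(grid$size[2], grid$size[1], nc[3])),
                c(2, 1, 3))
    t3 <- matrix(t2, grid$size[1] * grid$size[2], nc[3]) %*% t(Bz)
    out[, , , k] <- array(t3, dim = grid$size)
  }
  out
}

# Weighted affine trend (intercept + linear terms), fit by weighted least
# squares; rank-deficient configurations fall back to whatever the pivoted
# QR can support (a single point yields its own value).  Returns the 4 x K
# coefficient matrix.
.affine_trend <- function(points, values, weights) {
  X <- cbind(1, points)
  fit <- stats::lm.wfit(X, values, weights)
  cf <- as.matrix(fit$coefficients)
  cf[is.na(cf)] <- 0
  cf
}

#' Weighted multilevel B-spline approximation of scattered vectors
#'
#' Fits a smooth vector field to irregularly placed vector samples in two
#' stages: a weighted affine trend (so constant and linear fields are
#' reproduced exactly), then weighted tensor-product B-spline approximation
#' of the trend residuals, refined over dyadic control-lattice levels --
#' each level fits the residual left by the previous one, and the returned
#' field is the trend plus the sum of the per-level spline fields sampled on
#' `out_grid`.  Each vector component is smoothed independently with the
#' shared basis.  Doubling all weights leaves the fit unchanged; a point with
#' (relatively) tiny weight contributes (relatively) negligibly wherever
#' other data support the lattice.
#'
#' @param points n x 3 matrix of physical sample locations (mm).
#' @param values n x 3 matrix of sample vectors (or an n-vector for a scalar
#'   field fit).
#' @param weights n positive weights.
#' @param mesh a [bspline_mesh]; points outside its domain are clamped with a
#'   warning.
#' @param out_grid [image_grid] the fitted field is sampled on.
#' @return a [displacement_field] on `out_grid`; attribute
#'   `level_rms` records the weighted RMS residual at the data points after
#'   each level.
#' @export
fit_bspline_scattered <- function(points, values, weights, mesh, out_grid) {
  stopifnot(inherits(mesh, "bspline_mesh"), inherits(out_grid, "image_grid"))
  points <- .as_points(points)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  n <- nrow(points)
  if (n == 0L) stop("no data points supplied")
  if (nrow(values) != n || length(weights) != n) {
    stop("points, values and weights must have equal length")
  }
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("weights must be positive and finite")
  }
  if (!all(is.finite(points)) || !all(is.finite(values))) {
    stop("points and values must be finite")
  }
  K <- ncol(values)
  q <- .mesh_local_coords(mesh, points)
  extent <- mesh$domain$extent
  trend <- .affine_trend(points, values, weights)
  resid <- values - cbind(1, points) %*% trend
  gx <- .grid_voxel_centers(out_grid)
  total <- array(cbind(1, gx) %*% trend, dim = c(out_grid$size, K))
  level_rms <- numeric(mesh$n_levels)
  wsum <- sum(weights)
  for (L in seq_len(mesh$n_levels)) {
    m <- mesh$base_mesh_size * 2L^(L - 1L)
    lev <- .ba_fit_level(q[, 1], q[, 2], q[, 3], extent, resid, weights,
                         m, mesh$order)
    fitted <- .ba_eval_points_cached(lev, K)
    resid <- resid - fitted
    total <- total + .ba_eval_grid(lev$ctrl, mesh, m, out_grid)
    level_rms[L] <- sqrt(sum(weights * rowSums(resid^2)) / wsum)
  }
  field <- if (K == 3L) displacement_field(out_grid, total)
           else structure(list(grid = out_grid, vectors = total),
                          class = "displacement_field")
  attr(field, "level_rms") <- level_rms
  field
}
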