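# Physical-space raster containers shared by every other component.
#
# Conventions: 0-based voxel indexing, voxel-center sampling, all points and
# vectors in physical units (mm).  A grid maps index i to
# origin + direction %*% (spacing * i).

#' Construct an image grid
#'
#' An `image_grid` describes the physical-space geometry of a 3-D raster:
#' voxel counts, voxel spacing (mm), the physical coordinate of the center of
#' voxel (0,0,0), and an orthonormal direction matrix mapping index axes to
#' physical axes.
#'
#' @param size integer vector of length 3, voxels per axis (each >= 2).
#' @param spacing positive numeric vector of length 3, mm per voxel.
#' @param origin numeric vector of length 3, physical coordinate (mm) of the
#'   center of voxel index (0,0,0).
#' @param direction 3x3 orthonormal matrix (|det| = 1).
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(size, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  size <- as.integer(size)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  stopifnot(length(size) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(size < 2L)) stop("grid size must be >= 2 along every axis")
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (!all(dim(direction) == c(3L, 3L)) ||
      abs(abs(det(direction)) - 1) > 1e-10 ||
      max(abs(crossprod(direction) - diag(3))) > 1e-10) {
    stop("direction must be a 3x3 orthonormal matrix")
  }
  structure(list(size = size, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$size, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  origin", paste(signif(x$origin, 4), collapse = ", "), "mm\n")
  invisible(x)
}

# index -> physical affine matrix (3x3), A = direction %*% diag(spacing)
.grid_affine <- function(grid) grid$direction %*% diag(grid$spacing)

#' Convert 0-based voxel indices to physical coordinates
#'
#' @param grid an [image_grid].
#' @param idx numeric matrix (n x 3) of 0-based (possibly fractional) indices,
#'   or a length-3 vector.
#' @return n x 3 matrix of physical coordinates (mm).
#' @export
index_to_physical <- function(grid, idx) {
  idx <- .as_points(idx)
  sweep(idx %*% t(.grid_affine(grid)), 2L, grid$origin, "+")
}

#' Convert physical coordinates to continuous 0-based voxel indices
#'
#' @param grid an [image_grid].
#' @param pts numeric matrix (n x 3) of physical coordinates, or a length-3
#'   vector.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
physical_to_index <- function(grid, pts) {
  pts <- .as_points(pts)
  sweep(pts, 2L, grid$origin, "-") %*% t(solve(.grid_affine(grid)))
}

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L)
  else p <- matrix(as.numeric(p), ncol = 3L, dimnames = NULL)
  if (ncol(p) != 3L) stop("points must have 3 columns")
  p
}

# all voxel centers of a grid as an n x 3 physical-coordinate matrix,
# in R array (column-major, x fastest) order
.grid_voxel_centers <- function(grid) {
  s <- grid$size
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
  index_to_physical(grid, idx)
}

.grids_equal <- function(a, b, tol = 1e-6) {
  all(a$size == b$size) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' Construct a scalar image
#'
#' @param grid an [image_grid].
#' @param values numeric array with `dim(values) == grid$size`.
#' @return an object of class `scalar_image`.
#' @export
scalar_image <- function(grid, values) {
  stopifnot(inherits(grid, "image_grid"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$size)) {
    stop("value array shape does not match grid size")
  }
  structure(list(grid = grid, values = values), class = "scalar_image")
}

#' Construct a label image
#'
#' Label 0 is reserved for background; the vocabulary is the set of distinct
#' nonzero labels present.
#'
#' @param grid an [image_grid].
#' @param labels non-negative integer array with `dim(labels) == grid$size`.
#' @return an object of class `label_image` with a `vocabulary` element.
#' @export
label_image <- function(grid, labels) {
  stopifnot(inherits(grid, "image_grid"))
  labels <- as.array(labels)
  if (!identical(as.integer(dim(labels)), grid$size)) {
    stop("label array shape does not match grid size")
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative (0 = background)")
  vocab <- sort(unique(as.vector(labels)))
  vocab <- vocab[vocab != 0L]
  structure(list(grid = grid, labels = labels, vocabulary = vocab),
            class = "label_image")
}

#' Construct a displacement field
#'
#' A per-voxel physical-space offset u(x); the transform it encodes is
#' x -> x + u(x).
#'
#' @param grid an [image_grid].
#' @param vectors numeric array with `dim(vectors) == c(grid$size, 3)`,
#'   offsets in mm.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(grid, vectors) {
  stopifnot(inherits(grid, "image_grid"))
  vectors <- as.array(vectors)
  if (!identical(as.integer(dim(vectors)), c(grid$size, 3L))) {
    stop("vector array shape must be grid size x 3")
  }
  if (!all(is.finite(vectors))) stop("displacement vectors must be finite")
  structure(list(grid = grid, vectors = vectors), class = "displacement_field")
}

#' A displacement field of zeros on a grid
#' @param grid an [image_grid].
#' @return a [displacement_field] with all-zero vectors.
#' @export
zero_displacement_field <- function(grid) {
  displacement_field(grid, array(0, dim = c(grid$size, 3L)))
}

# Trilinear interpolation of a multi-component voxel array.
# values: array dim c(size, K); cidx: n x 3 continuous 0-based indices.
# Out-of-domain indices are clamped to the boundary.  Returns n x K matrix.
.interp_trilinear <- function(values, size, cidx) {
  n <- nrow(cidx)
  K <- length(values) / prod(size)
  nx <- size[1]; ny <- size[2]; nz <- size[3]
  cx <- pmin(pmax(cidx[, 1], 0), nx - 1)
  cy <- pmin(pmax(cidx[, 2], 0), ny - 1)
  cz <- pmin(pmax(cidx[, 3], 0), nz - 1)
  i0 <- pmin(floor(cx), nx - 2); fx <- cx - i0
  j0 <- pmin(floor(cy), ny - 2); fy <- cy - j0
  k0 <- pmin(floor(cz), nz - 2); fz <- cz - k0
  base <- i0 + nx * (j0 + ny * k0) + 1  # 1-based flat index of corner (0,0,0)
  vox <- nx * ny * nz
  out <- matrix(0, n, K)
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - fz else fz
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - fy else fy
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - fx else fx
        w <- wx * wy * wz
        flat <- base + dx + nx * dy + nx * ny * dz
        for (k in seq_len(K)) {
          out[, k] <- out[, k] + w * values[flat + (k - 1) * vox]
        }
      }
    }
  }
  out
}

#' Interpolate a displacement field at physical points
#'
#' Trilinear interpolation of the vector components.  Points outside the grid
#' hull are clamped to the boundary, so sampling degrades gracefully rather
#' than returning zeros.
#'
#' @param field a [displacement_field].
#' @param p physical point(s): length-3 vector or n x 3 matrix (mm).
#' @return n x 3 matrix of interpolated vectors (mm).
#' @export
interpolate_vector <- function(field, p) {
  stopifnot(inherits(field, "displacement_field"))
  p <- .as_points(p)
  if (!all(is.finite(p))) stop("query points must be finite")
  cidx <- physical_to_index(field$grid, p)
  .interp_trilinear(field$vectors, field$grid$size, cidx)
}

#' Interpolate a scalar image at physical points
#'
#' @param img a [scalar_image].
#' @param p physical point(s): length-3 vector or n x 3 matrix (mm).
#' @return numeric vector of interpolated values.
#' @export
interpolate_scalar <- function(img, p) {
  stopifnot(inherits(img, "scalar_image"))
  p <- .as_points(p)
  if (!all(is.finite(p))) stop("query points must be finite")
  cidx <- physical_to_index(img$grid, p)
  drop(.interp_trilinear(img$values, img$grid$size, cidx))
}

#' Warp an image by a displacement field
#'
#' The output value at each voxel center x is the input sampled at
#' x + disp(x): linear interpolation for scalar images, nearest-neighbour for
#' label images (so no labels outside the input vocabulary are created).
#'
#' @param img a [scalar_image] or [label_image].
#' @param disp a [displacement_field] on the same grid as `img`.
#' @return an image of the same class as `img`.
#' @export
warp_image <- function(img, disp) {
  stopifnot(inherits(disp, "displacement_field"))
  if (!.grids_equal(img$grid, disp$grid)) {
    stop("image and displacement grids do not match within tolerance")
  }
  grid <- img$grid
  x <- .grid_voxel_centers(grid)
  src <- x + matrix(disp$vectors, ncol = 3L)
  cidx <- physical_to_index(grid, src)
  if (inherits(img, "scalar_image")) {
    vals <- .interp_trilinear(img$values, grid$size, cidx)
    scalar_image(grid, array(vals, dim = grid$size))
  } else if (inherits(img, "label_image")) {
    s <- grid$size
    i <- pmin(pmax(round(cidx[, 1]), 0), s[1] - 1)
    j <- pmin(pmax(round(cidx[, 2]), 0), s[2] - 1)
    k <- pmin(pmax(round(cidx[, 3]), 0), s[3] - 1)
    flat <- i + s[1] * (j + s[2] * k) + 1
    label_image(grid, array(img$labels[flat], dim = s))
  } else {
    stop("img must be a scalar_image or label_image")
  }
}

#' Dice overlap coefficient for one label
#'
#' Computes 2|A n B| / (|A| + |B|) for the voxel sets carrying `label` in two
#' label images on the same grid.  Returns 1 when both sets are empty.
#'
#' @param a,b [label_image]s on identical grids.
#' @param label the label id to compare.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b, label) {
  stopifnot(inherits(a, "label_image"), inherits(b, "label_image"))
  if (!.grids_equal(a$grid, b$grid)) stop("label images must share a grid")
  ma <- a$labels == label
  mb <- b$labels == label
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) return(1.0)
  2 * sum(ma & mb) / (na + nb)
}
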