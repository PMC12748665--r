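# NIfTI-1 and JSON-sidecar input/output for every container.
#
# Scalar and label images round-trip through the NIfTI sform alone.
# Displacement and velocity fields are stored as 5-D NIfTI volumes
# (x, y, z, time-slices, vector components) whose JSON sidecar records grid
# provenance, slice times, timeline and fit provenance; the sidecar is
# authoritative for recomputation and the vector payload round-trips
# bit-exactly (float64).

.FORMAT_VERSION <- "1.0"

.sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

.grid_to_xform <- function(grid) {
  xf <- diag(4)
  xf[1:3, 1:3] <- .grid_affine(grid)
  xf[1:3, 4] <- grid$origin
  xf
}

.xform_to_grid <- function(xf, size) {
  A <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2L, spacing, "/")
  image_grid(size, spacing, xf[1:3, 4], direction)
}

.write_nifti_array <- function(arr, grid, path, datatype = "double") {
  nim <- RNifti::asNifti(arr, datatype = datatype)
  xf <- .grid_to_xform(grid)
  RNifti::sform(nim) <- structure(xf, code = 2L)
  RNifti::qform(nim) <- structure(xf, code = 0L)
  RNifti::writeNifti(nim, path, datatype = datatype)
  invisible(path)
}

# plain numeric array from a niftiImage, with all header attributes dropped
.nifti_payload <- function(nim) {
  array(as.vector(nim, mode = "double"), dim = dim(nim))
}

.grid_to_json <- function(grid) {
  list(size = grid$size, spacing = grid$spacing, origin = grid$origin,
       direction = as.vector(grid$direction))
}

.grid_from_json <- function(g) {
  image_grid(unlist(g$size), unlist(g$spacing), unlist(g$origin),
             matrix(unlist(g$direction), 3, 3))
}

#' Write a scalar image as NIfTI-1
#' @param img a [scalar_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_scalar_image <- function(img, path) {
  stopifnot(inherits(img, "scalar_image"))
  .write_nifti_array(img$values, img$grid, path, "double")
}

#' Read a scalar image from NIfTI-1
#' @param path input path.
#' @return a [scalar_image]; the grid is taken from the NIfTI transform.
#' @export
read_scalar_image <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- .nifti_payload(nim)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3-D scalar NIfTI volume, got ",
         length(dim(arr)), " dimensions: ", path)
  }
  scalar_image(.xform_to_grid(RNifti::xform(nim), dim(arr)), arr)
}

#' Write a label image as integer NIfTI-1
#' @param img a [label_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  stopifnot(inherits(img, "label_image"))
  .write_nifti_array(img$labels, img$grid, path, "int32")
}

#' Read a label image from NIfTI-1
#' @param path input path.
#' @return a [label_image].
#' @export
read_label_image <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- .nifti_payload(nim)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3-D label NIfTI volume: ", path)
  }
  label_image(.xform_to_grid(RNifti::xform(nim), dim(arr)), round(arr))
}

#' Write a displacement field as 5-D NIfTI plus JSON sidecar
#' @param field a [displacement_field].
#' @param path output path; the sidecar is written alongside with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  arr <- array(field$vectors, dim = c(field$grid$size, 1L, 3L))
  .write_nifti_array(arr, field$grid, path, "double")
  sidecar <- list(format_version = .FORMAT_VERSION,
                  type = "displacement_field",
                  grid = .grid_to_json(field$grid))
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_sidecar <- function(path, expected_type) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing JSON sidecar for ", expected_type, ": ", sp)
  }
  sidecar <- jsonlite::read_json(sp, simplifyVector = FALSE)
  if (!identical(sidecar$type, expected_type)) {
    stop("sidecar type mismatch: expected '", expected_type, "', found '",
         sidecar$type, "' in ", sp)
  }
  sidecar
}

#' Read a displacement field written by [write_displacement_field]
#' @param path NIfTI path (the `.json` sidecar must sit alongside).
#' @return a [displacement_field].
#' @export
read_displacement_field <- function(path) {
  sidecar <- .read_sidecar(path, "displacement_field")
  nim <- RNifti::readNifti(path)
  arr <- .nifti_payload(nim)
  d <- dim(arr)
  if (length(d) != 5L || d[4] != 1L || d[5] != 3L) {
    stop("expected a 5-D displacement NIfTI (x, y, z, 1, 3): ", path)
  }
  grid <- .grid_from_json(sidecar$grid)
  displacement_field(grid, array(arr, dim = c(grid$size, 3L)))
}

#' Write a velocity field as 5-D NIfTI plus JSON sidecar
#'
#' The sidecar records slice times, the developmental timeline and any fit
#' provenance supplied in `extra`; the vector payload round-trips
#' bit-exactly.
#'
#' @param vf a [velocity_field].
#' @param path output path.
#' @param extra named list merged into the sidecar (e.g. fit config echo and
#'   convergence summary).
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(vf, path, extra = list()) {
  stopifnot(inherits(vf, "velocity_field"))
  .write_nifti_array(vf$vectors, vf$grid, path, "double")
  sidecar <- list(format_version = .FORMAT_VERSION,
                  type = "velocity_field",
                  grid = .grid_to_json(vf$grid),
                  n_slices = vf$n_slices,
                  slice_times = vf$slice_times)
  if (!is.null(vf$timeline)) {
    sidecar$timeline <- list(
      stage_ages = vf$timeline$stage_ages,
      cap_age = vf$timeline$cap_age,
      normalized_times = vf$timeline$normalized_times)
  }
  if (length(extra) > 0L) sidecar <- c(sidecar, extra)
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a velocity field written by [write_velocity_field]
#' @param path NIfTI path (the `.json` sidecar must sit alongside).
#' @return a [velocity_field]; the sidecar's timeline, if present, is
#'   restored, and all other sidecar keys are attached as attribute
#'   `sidecar`.
#' @export
read_velocity_field <- function(path) {
  sidecar <- .read_sidecar(path, "velocity_field")
  nim <- RNifti::readNifti(path)
  arr <- .nifti_payload(nim)
  d <- dim(arr)
  if (length(d) != 5L || d[5] != 3L) {
    stop("expected a 5-D velocity NIfTI (x, y, z, slices, 3): ", path)
  }
  grid <- .grid_from_json(sidecar$grid)
  timeline <- NULL
  if (!is.null(sidecar$timeline)) {
    cap <- unlist(sidecar$timeline$cap_age)   # NULL serializes as {}
    timeline <- normalize_stage_times(
      unlist(sidecar$timeline$stage_ages),
      if (length(cap) == 0L) NULL else as.numeric(cap))
  }
  vf <- velocity_field(grid, arr, timeline)
  attr(vf, "sidecar") <- sidecar
  vf
}
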