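# Weighted contour/region point sets sampled from common-label images --
# the data the velocity optimizer consumes.
#
# Boundary ("contour") voxels of a label are those with at least one
# six-connected neighbour carrying a different label (voxels on the volume
# face count as boundary); the remainder are interior ("region") voxels.
# Sampling is stratified per label so small structures stay represented,
# and contour points carry double optimization weight.

.CONTOUR_WEIGHT <- 2.0
.REGION_WEIGHT <- 1.0

#' Corresponding point trajectories across developmental stages
#'
#' Row n of `coords` tracks one anatomical point across all stages; contour
#' points carry exactly twice the weight of region points (before any
#' renormalization inside the optimizer).
#'
#' @param coords numeric array of dim `c(N, T, 3)`: point n at stage s.
#' @param kinds character vector of length N, each `"contour"` or
#'   `"region"`.
#' @param label_ids integer vector of length N: source label of each point.
#' @param weights optional numeric vector of length N; defaults to 2 for
#'   contour and 1 for region points.
#' @return an object of class `point_trajectory_set` with fields `coords`,
#'   `weights`, `kinds`, `label_ids`, `n_points`, `n_stages`.
#' @export
point_trajectory_set <- function(coords, kinds, label_ids, weights = NULL) {
  coords <- as.array(coords)
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L) {
    stop("coords must be an N x T x 3 array")
  }
  N <- d[1]; Tn <- d[2]
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  kinds <- as.character(kinds)
  if (length(kinds) != N || !all(kinds %in% c("contour", "region"))) {
    stop("kinds must be 'contour' or 'region', one per point")
  }
  if (length(label_ids) != N) stop("label_ids must have one entry per point")
  if (is.null(weights)) {
    weights <- ifelse(kinds == "contour", .CONTOUR_WEIGHT, .REGION_WEIGHT)
  }
  if (length(weights) != N || any(weights <= 0)) {
    stop("weights must be positive, one per point")
  }
  structure(list(coords = coords, weights = as.numeric(weights),
                 kinds = kinds, label_ids = as.integer(label_ids),
                 n_points = N, n_stages = Tn),
            class = "point_trajectory_set")
}

#' @export
print.point_trajectory_set <- function(x, ...) {
  cat("point_trajectory_set:", x$n_points, "points x", x$n_stages, "stages (",
      sum(x$kinds == "contour"), "contour /", sum(x$kinds == "region"),
      "region )\n")
  invisible(x)
}

# Boundary mask under 6-connectivity: TRUE where any face neighbour differs
# (out-of-volume neighbours count as different).
.boundary_mask <- function(labels) {
  d <- dim(labels)
  pad <- array(-1L, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- labels
  ctr <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  bnd <- array(FALSE, dim = d)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (sh in shifts) {
    nb <- pad[2:(d[1] + 1L) + sh[1], 2:(d[2] + 1L) + sh[2],
              2:(d[3] + 1L) + sh[3]]
    bnd <- bnd | (nb != ctr)
  }
  bnd
}

# round-half-away-from-zero with a floor of 1 for nonempty strata
.sample_count <- function(available, fraction) {
  if (available == 0L) return(0L)
  max(1L, as.integer(floor(available * fraction + 0.5)))
}

#' Sample contour and region points from a label image
#'
#' For each label in the vocabulary, boundary voxels (six-connected
#' label-change test) and interior voxels are sampled uniformly without
#' replacement at the given fractions -- `round(fraction * count)`,
#' half away from zero, with a floor of one point per nonempty stratum.
#' Physical voxel centers are returned.
#'
#' @param img a [label_image] with at least one nonzero label.
#' @param contour_fraction,region_fraction sampling fractions in (0, 1\].
#' @param seed integer seed controlling the (only) source of randomness.
#' @return a list with `points` (n x 3 physical coordinates), `kinds`
#'   (`"contour"`/`"region"`), `label_ids`.
#' @export
extract_label_points <- function(img, contour_fraction = 0.10,
                                 region_fraction = 0.01, seed = 1L) {
  stopifnot(inherits(img, "label_image"))
  for (f in c(contour_fraction, region_fraction)) {
    if (!is.finite(f) || f <= 0 || f > 1) {
      stop("sampling fractions must lie in (0, 1]")
    }
  }
  if (length(img$vocabulary) == 0L) stop("label image has no nonzero labels")
  bnd <- .boundary_mask(img$labels)
  rng <- .with_seed(seed)
  on.exit(rng(), add = TRUE)
  pts <- list(); kinds <- list(); lids <- list()
  for (lab in img$vocabulary) {
    in_lab <- img$labels == lab
    if (!any(in_lab)) {
      warning("label ", lab, " is empty; skipped")
      next
    }
    flat_b <- which(in_lab & bnd)
    flat_r <- which(in_lab & !bnd)
    take <- function(flat, k) {
      if (k == 0L || length(flat) == 0L) return(integer(0))
      if (k >= length(flat)) flat else sort(sample(flat, k))
    }
    sel_b <- take(flat_b, .sample_count(length(flat_b), contour_fraction))
    sel_r <- take(flat_r, .sample_count(length(flat_r), region_fraction))
    for (set in list(list(sel_b, "contour"), list(sel_r, "region"))) {
      if (length(set[[1]]) == 0L) next
      idx <- .flat_to_index(set[[1]], img$grid$size)
      pts[[length(pts) + 1L]] <- index_to_physical(img$grid, idx)
      kinds[[length(kinds) + 1L]] <- rep(set[[2]], length(set[[1]]))
      lids[[length(lids) + 1L]] <- rep(lab, length(set[[1]]))
    }
  }
  list(points = do.call(rbind, pts),
       kinds = unlist(kinds),
       label_ids = as.integer(unlist(lids)))
}

# 1-based flat array index -> 0-based (i,j,k) index matrix
.flat_to_index <- function(flat, size) {
  f0 <- flat - 1L
  i <- f0 %% size[1]
  j <- (f0 %/% size[1]) %% size[2]
  k <- f0 %/% (size[1] * size[2])
  cbind(i, j, k)
}

# run code under a seeded RNG, restoring the caller's RNG state; returns the
# restore function for on.exit
.with_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv())
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Chain reference-stage points through per-stage transports
#'
#' Builds a [point_trajectory_set] by pushing the reference-stage points
#' through the supplied transports, ordered from the reference (first) stage
#' outward: column `s+1` is column `s` mapped through `transports[[s]]`.
#' Contour rows get weight 2, region rows weight 1.
#'
#' @param points_at_reference n x 3 matrix of physical points at the first
#'   stage.
#' @param kinds,label_ids as returned by [extract_label_points].
#' @param transports list of `T - 1` point mappers, each either a function
#'   `matrix -> matrix` or a [displacement_field] (applied as
#'   `x + u(x)`).
#' @return a [point_trajectory_set] with `T = length(transports) + 1` stages.
#' @export
assemble_trajectories <- function(points_at_reference, kinds, label_ids,
                                  transports) {
  pts <- .as_points(points_at_reference)
  N <- nrow(pts)
  Tn <- length(transports) + 1L
  coords <- array(NA_real_, dim = c(N, Tn, 3L))
  coords[, 1L, ] <- pts
  cur <- pts
  for (s in seq_along(transports)) {
    cur <- .apply_transport(transports[[s]], cur)
    if (!all(is.finite(cur))) {
      bad <- which(!apply(is.finite(cur), 1L, all))[1]
      stop(sprintf("transport to stage %d produced non-finite coordinates (point %d)",
                   s + 1L, bad))
    }
    coords[, s + 1L, ] <- cur
  }
  point_trajectory_set(coords, kinds, label_ids)
}

.apply_transport <- function(tr, pts) {
  if (is.function(tr)) {
    .as_points(tr(pts))
  } else if (inherits(tr, "displacement_field")) {
    pts + interpolate_vector(tr, pts)
  } else {
    stop("transport must be a function or a displacement_field")
  }
}

#' Write a point-trajectory set to a delimited text file
#'
#' Tab-separated, one row per (point, stage), with header columns
#' `point_id, kind, label_id, weight, stage_index, x, y, z`.
#'
#' @param traj a [point_trajectory_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_point_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "point_trajectory_set"))
  N <- traj$n_points; Tn <- traj$n_stages
  df <- data.frame(
    point_id = rep(seq_len(N), each = Tn),
    kind = rep(traj$kinds, each = Tn),
    label_id = rep(traj$label_ids, each = Tn),
    weight = rep(traj$weights, each = Tn),
    stage_index = rep(seq_len(Tn) - 1L, times = N),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a point-trajectory set from a delimited text file
#'
#' Validates the correspondence invariant: every point id must appear
#' exactly once at every stage index.  A missing `weight` column defaults to
#' 2 (contour) / 1 (region) with a warning.
#'
#' @param path file written by [write_point_trajectories] (tab- or
#'   comma-separated).
#' @return a [point_trajectory_set].
#' @export
read_point_trajectories <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("point_id", "kind", "label_id", "stage_index", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("point file is missing columns: ", paste(miss, collapse = ", "))
  }
  ids <- sort(unique(df$point_id))
  stages <- sort(unique(df$stage_index))
  N <- length(ids); Tn <- length(stages)
  if (nrow(df) != N * Tn) {
    stop("point file violates correspondence: expected ", N * Tn,
         " rows (", N, " points x ", Tn, " stages), found ", nrow(df))
  }
  tab <- table(df$point_id, df$stage_index)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop("point file violates correspondence: point ",
         rownames(tab)[bad[1]], " has ", tab[bad[1], bad[2]],
         " rows at stage ", colnames(tab)[bad[2]])
  }
  df <- df[order(match(df$point_id, ids), match(df$stage_index, stages)), ]
  coords <- array(NA_real_, dim = c(N, Tn, 3L))
  coords[, , 1] <- matrix(df$x, N, Tn, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, N, Tn, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, N, Tn, byrow = TRUE)
  first <- df[df$stage_index == stages[1], ]
  weights <- NULL
  if ("weight" %in% names(df)) {
    weights <- first$weight
  } else {
    warning("point file has no weight column; applying defaults ",
            "(contour 2.0, region 1.0)")
  }
  point_trajectory_set(coords, first$kind, first$label_id, weights)
}
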