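# Developmental time axis: stage ages (days, conception-anchored) are mapped
# onto a normalized log-scaled axis in [0,1], so early development -- where
# morphological change is fastest -- gets finer temporal resolution.

#' Normalize developmental stage ages onto a log-scaled [0,1] axis
#'
#' Ages are optionally truncated at `cap_age` (late ages beyond which
#' morphological change is negligible collapse toward the cap), then
#' log-transformed and min-max normalized:
#' `t_i = (ln min(a_i, cap) - ln min(a_0, cap)) / (ln min(a_T, cap) - ln min(a_0, cap))`.
#' The result is invariant to rescaling all (capped) ages by a positive
#' constant.
#'
#' @param ages strictly increasing positive numeric vector (days on a single
#'   conception-anchored axis), length >= 2.
#' @param cap_age positive scalar or `NULL`: ages above it are truncated to
#'   it before the log transform.  Must exceed the first age, and may tie at
#'   most the last age (two capped ages may not coincide).
#' @return an object of class `dev_timeline` with elements `stage_ages`,
#'   `cap_age`, `normalized_times`.
#' @export
normalize_stage_times <- function(ages, cap_age = NULL) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L) stop("need at least two stage ages")
  if (any(ages <= 0)) stop("ages must be positive")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  capped <- ages
  if (!is.null(cap_age)) {
    cap_age <- as.numeric(cap_age)
    if (cap_age <= ages[1]) stop("cap_age must exceed the first stage age")
    capped <- pmin(ages, cap_age)
    if (any(diff(capped) <= 0)) {
      stop("cap_age truncates two or more stages to the same age")
    }
  }
  lt <- log(capped)
  nt <- (lt - lt[1]) / (lt[length(lt)] - lt[1])
  structure(list(stage_ages = ages, cap_age = cap_age,
                 normalized_times = nt),
            class = "dev_timeline")
}

#' @export
print.dev_timeline <- function(x, ...) {
  cat("dev_timeline:", length(x$stage_ages), "stages, ages",
      paste(x$stage_ages, collapse = ", "), "days",
      if (!is.null(x$cap_age)) paste0("(cap ", x$cap_age, ")") else "", "\n")
  cat("  normalized:", paste(signif(x$normalized_times, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stage indices bracketing a normalized time
#'
#' Returns the tightest pair of stage indices (1-based) `(i, j)` with
#' `normalized_times[i] <= t <= normalized_times[j]` and `j = i + 1`; when
#' `t` coincides with a stage time (within 1e-12), `i = j = ` that stage.
#'
#' @param timeline a [dev_timeline] (from [normalize_stage_times]).
#' @param t normalized time in \[0, 1\].
#' @return integer vector `c(i, j)`.
#' @export
nearest_bracketing_stages <- function(timeline, t) {
  stopifnot(inherits(timeline, "dev_timeline"), length(t) == 1L)
  nt <- timeline$normalized_times
  if (!is.finite(t) || t < 0 || t > 1) stop("t must lie in [0, 1]")
  hit <- which(abs(nt - t) <= 1e-12)
  if (length(hit) > 0L) return(c(hit[1], hit[1]))
  i <- findInterval(t, nt)
  c(i, i + 1L)
}

# Interval of adjacent stages containing normalized time t, for slice
# updates: returns i such that nt[i] <= t <= nt[i+1], with ties at an
# interior stage time broken toward the earlier interval, and the endpoint
# times using the first/last interval.
.stage_interval <- function(timeline, t) {
  nt <- timeline$normalized_times
  Tn <- length(nt)
  if (t <= nt[1]) return(1L)
  if (t >= nt[Tn]) return(Tn - 1L)
  i <- findInterval(t, nt, left.open = TRUE)  # ties go to earlier interval
  min(max(i, 1L), Tn - 1L)
}

#' Convert ages to normalized times on a timeline's log axis
#'
#' Applies the timeline's cap and log min-max normalization to arbitrary
#' ages (not only stage ages), so continuous ages map onto the same
#' normalized axis the velocity field is parameterized over.
#'
#' @param timeline a [dev_timeline].
#' @param age positive age(s) in days; must fall inside the stage age range
#'   after capping.
#' @return normalized time(s) in \[0, 1\].
#' @export
age_to_normalized_time <- function(timeline, age) {
  stopifnot(inherits(timeline, "dev_timeline"))
  age <- as.numeric(age)
  if (any(age <= 0)) stop("ages must be positive")
  capped <- if (is.null(timeline$cap_age)) age else pmin(age, timeline$cap_age)
  a <- timeline$stage_ages
  c0 <- a[1]
  cT <- if (is.null(timeline$cap_age)) a[length(a)]
        else min(a[length(a)], timeline$cap_age)
  t <- (log(capped) - log(c0)) / (log(cT) - log(c0))
  if (any(t < -1e-9 | t > 1 + 1e-9)) {
    stop("age outside the timeline's stage range")
  }
  pmin(pmax(t, 0), 1)
}

#' Convert normalized times back to ages on a timeline's log axis
#'
#' Inverse of [age_to_normalized_time] for uncapped ages; normalized time 1
#' maps to the capped last age.
#'
#' @param timeline a [dev_timeline].
#' @param t normalized time(s) in \[0, 1\].
#' @return age(s) in days.
#' @export
normalized_time_to_age <- function(timeline, t) {
  stopifnot(inherits(timeline, "dev_timeline"))
  t <- as.numeric(t)
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  a <- timeline$stage_ages
  c0 <- a[1]
  cT <- if (is.null(timeline$cap_age)) a[length(a)]
        else min(a[length(a)], timeline$cap_age)
  exp(log(c0) + t * (log(cT) - log(c0)))
}

# Parse stage names like "E13.5" / "P4" to conception-anchored ages in days.
.parse_stage_age <- function(name, birth_offset_days = 19) {
  name <- trimws(name)
  if (grepl("^[Ee][0-9.]+$", name)) {
    as.numeric(sub("^[Ee]", "", name))
  } else if (grepl("^[Pp][0-9.]+$", name)) {
    birth_offset_days + as.numeric(sub("^[Pp]", "", name))
  } else {
    val <- suppressWarnings(as.numeric(name))
    if (is.na(val)) stop("cannot parse stage age: ", name)
    val
  }
}
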