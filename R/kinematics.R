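# Kinematic variables computed from registered landmark trajectories.
#
# Coordinate convention (fixed here because digitizing software does not
# impose one): ventral view x = mediolateral (fish's right positive),
# y = anteroposterior (anterior positive); lateral view x = anteroposterior
# (anterior positive), y = dorsoventral (dorsal positive). Counterclockwise
# rotation is positive under this convention.

KIN_VARIABLE_TABLE <- data.frame(
  variable = c(
    "cranial_elevation_angle",
    "premaxillary_protrusion_angle",
    "premaxillary_protrusion_length",
    "hyoid_retraction_angle",
    "hyoid_retraction_length",
    "mandibular_retraction_length",
    "opercular_expansion_length",
    "oral_sucker_area"
  ),
  units = c("deg", "deg", "BL", "deg", "BL", "BL", "BL", "BL2"),
  view = c("lateral", "lateral", "lateral", "ventral", "ventral",
           "ventral", "ventral", "ventral"),
  stringsAsFactors = FALSE
)

#' Names (and units) of the eight kinematic variables
#'
#' @param table if `TRUE`, return a data.frame with `variable`, `units`
#'   (`deg`, `BL` or `BL2`) and source `view`; otherwise the character vector
#'   of names.
#' @return Character vector or data.frame.
#' @export
kin_variables <- function(table = FALSE) {
  if (table) KIN_VARIABLE_TABLE else KIN_VARIABLE_TABLE$variable
}

#' Signed rotation angle between two 2-D vectors
#'
#' Angle through which `v_reference` must rotate to align with `v_current`,
#' in degrees in (-180, 180]; positive is counterclockwise. Computed with the
#' two-argument arctangent of the cross and dot products, which is numerically
#' stable near 0.
#'
#' @param v_current,v_reference length-2 vectors or n x 2 matrices (rowwise).
#' @return Numeric vector of signed angles in degrees.
#' @export
signed_rotation_angle <- function(v_current, v_reference) {
  cur <- rbind(v_current)
  ref <- rbind(v_reference)
  if (ncol(cur) != 2 || ncol(ref) != 2) {
    gk_stop("gk_usage_error", "vectors must be 2-D")
  }
  if (nrow(ref) == 1 && nrow(cur) > 1) ref <- ref[rep(1, nrow(cur)), , drop = FALSE]
  nc <- sqrt(rowSums(cur^2)); nr <- sqrt(rowSums(ref^2))
  if (any(nc == 0) || any(nr == 0)) {
    bad <- which(nc == 0 | nr == 0)[1]
    gk_stop("gk_geometry_error",
            sprintf("zero-length vector at frame %d", bad - 1L))
  }
  cross <- ref[, 1] * cur[, 2] - ref[, 2] * cur[, 1]
  dot <- ref[, 1] * cur[, 1] + ref[, 2] * cur[, 2]
  unname(atan2(cross, dot) * 180 / pi)
}

# Unsigned angle (degrees, [0, 180]) between row vectors of two n x 2 matrices.
unsigned_angle <- function(a, b) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) {
    gk_stop("gk_geometry_error", "zero-length vector in angle computation")
  }
  cosang <- pmin(1, pmax(-1, rowSums(a * b) / (na * nb)))
  acos(cosang) * 180 / pi
}

#' Geometric model of oral-sucker area from ventral landmarks
#'
#' The ventral mouth outline is modeled from four landmarks: A = point 1
#' (anterior edge of the upper lip), B = point 3 (mandibular symphysis),
#' C = point 4 (right caudolateral tip of the mouth), D = point 6 (midpoint of
#' the right mandible), with E the computed midpoint of B and C anchoring the
#' chord, and theta the angle at A between vectors AB and AC. The enclosed
#' area is the sum of three shapes (left side accounted for by bilateral
#' symmetry):
#'
#' * `X = theta * |AB|^2 / 2` — circular sector at A spanning the anterior lip,
#' * `Y = |AB x AC| / 2`     — triangle A-B-C,
#' * `Z = |(D-B) x (C-B)| / 2` — triangle B-D-C, the mandibular bulge beyond
#'   the chord B-C.
#'
#' Areas are returned in the square of the input coordinate unit (cm^2 for
#' calibrated trials); [compute_variable()] divides by body length squared.
#'
#' @param A,B,C,D length-2 vectors or n x 2 matrices of landmark coordinates
#'   (points 1, 3, 4, 6).
#' @return Numeric vector of modeled areas.
#' @export
oral_sucker_area <- function(A, B, C, D) {
  A <- rbind(A); B <- rbind(B); C <- rbind(C); D <- rbind(D)
  AB <- B - A
  AC <- C - A
  nAB <- sqrt(rowSums(AB^2)); nAC <- sqrt(rowSums(AC^2))
  if (any(nAB == 0) || any(nAC == 0)) {
    gk_stop("gk_geometry_error", "coincident mouth landmarks (zero-length AB or AC)")
  }
  cross <- AB[, 1] * AC[, 2] - AB[, 2] * AC[, 1]
  dot <- rowSums(AB * AC)
  # collinear A, B, C: sector and triangle degenerate to zero area
  if (any(abs(cross) <= 1e-12 * nAB * nAC)) {
    gk_stop("gk_geometry_error",
            "mouth landmarks A, B, C are collinear (degenerate sucker geometry)")
  }
  theta <- atan2(abs(cross), dot)
  if (any(theta >= pi - 1e-12)) {
    gk_stop("gk_orientation_error",
            "theta >= pi: mouth landmarks appear mislabeled")
  }
  X <- theta * nAB^2 / 2
  Y <- abs(cross) / 2
  BD <- D - B
  BC <- C - B
  Z <- abs(BD[, 1] * BC[, 2] - BD[, 2] * BC[, 1]) / 2
  as.numeric(X + Y + Z)
}

#' Compute one kinematic variable for a trial
#'
#' Computes the per-frame trace of one of the eight kinematic variables over
#' the trial's cycle. The trial is registered to the pectoral-fin reference
#' first if it is not already (see [register_frames()]); after registration
#' the stationary midpoint M of the pectoral-fin bases is the ventral origin.
#' Lengths are normalized by body length (BL), areas by BL^2, angles are in
#' degrees. Positive values always mean the named motion (protrusion,
#' retraction, elevation, expansion).
#'
#' Variable definitions (point numbers refer to the 23-landmark scheme):
#' * `cranial_elevation_angle`: signed rotation of the vector from point 18
#'   (anterior neurocranium) to point 20 (epaxial insertion) relative to its
#'   orientation at the first cycle frame (lateral view).
#' * `premaxillary_protrusion_angle`: signed rotation of the vector from
#'   point 15 (upper-lip tip) to point 18, relative to the first frame.
#' * `premaxillary_protrusion_length`: 2-D displacement magnitude of point 15
#'   from its position at the first frame, in the registered lateral frame.
#' * `hyoid_retraction_angle`: unsigned angle at point 8 (hyoid arch) between
#'   the vector to M and the vector to point 11 (opercular landmark).
#' * `hyoid_retraction_length`: shortening of the distance from point 8 to M
#'   relative to the first frame (positive = retraction toward M).
#' * `mandibular_retraction_length`: shortening of the distance from point 3
#'   (mandibular symphysis) to M relative to the first frame.
#' * `opercular_expansion_length`: absolute distance between points 10 and 11
#'   (opercular tips) — a width, not a change score.
#' * `oral_sucker_area`: the [oral_sucker_area()] model on points 1, 3, 4, 6.
#'
#' @param trial a `landmark_trial`.
#' @param variable one of [kin_variables()].
#' @return A `kinematic_series`: list with `variable`, `units`, `values`
#'   (one per cycle frame), `time`, and trial provenance fields.
#' @export
compute_variable <- function(trial, variable) {
  info <- KIN_VARIABLE_TABLE[KIN_VARIABLE_TABLE$variable == variable, ]
  if (nrow(info) != 1) {
    gk_stop("gk_usage_error", sprintf(
      "unknown variable '%s'; see kin_variables()", variable))
  }
  if (!isTRUE(attr(trial, "registered"))) trial <- register_frames(trial)
  BL <- trial$body_length
  tt <- cycle_times(trial)
  vals <- switch(
    variable,
    cranial_elevation_angle = {
      v <- lm_xy(trial, 20) - lm_xy(trial, 18)
      signed_rotation_angle(v, v[1, ])
    },
    premaxillary_protrusion_angle = {
      v <- lm_xy(trial, 15) - lm_xy(trial, 18)
      signed_rotation_angle(v, v[1, ])
    },
    premaxillary_protrusion_length = {
      p15 <- lm_xy(trial, 15)
      d <- sweep(p15, 2, p15[1, ])
      sqrt(rowSums(d^2)) / BL
    },
    hyoid_retraction_angle = {
      p8 <- lm_xy(trial, 8)
      unsigned_angle(-p8, lm_xy(trial, 11) - p8)  # M at origin after registration
    },
    hyoid_retraction_length = {
      d <- sqrt(rowSums(lm_xy(trial, 8)^2))
      (d[1] - d) / BL
    },
    mandibular_retraction_length = {
      d <- sqrt(rowSums(lm_xy(trial, 3)^2))
      (d[1] - d) / BL
    },
    opercular_expansion_length = {
      d <- lm_xy(trial, 10) - lm_xy(trial, 11)
      sqrt(rowSums(d^2)) / BL
    },
    oral_sucker_area = {
      oral_sucker_area(lm_xy(trial, 1), lm_xy(trial, 3),
                       lm_xy(trial, 4), lm_xy(trial, 6)) / BL^2
    }
  )
  structure(
    list(
      variable = variable, units = info$units, values = as.numeric(vals),
      time = tt, trial_id = trial$trial_id, behavior = trial$behavior,
      species = trial$species, individual_id = trial$individual_id,
      body_length = BL
    ),
    class = "kinematic_series"
  )
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %s [%s] | trial %s | %d frames | range [%.4g, %.4g]\n",
              x$variable, x$units, x$trial_id, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.kinematic_series <- function(x, ...) {
  data.frame(
    trial_id = x$trial_id, behavior = x$behavior, species = x$species,
    individual_id = x$individual_id, variable = x$variable,
    frame_index = seq_along(x$values) - 1L, time_s = x$time,
    value = x$values, units = x$units
  )
}

#' Compute all (or selected) kinematic variables for one or more trials
#'
#' @param trials a `landmark_trial` or list of them.
#' @param variables subset of [kin_variables()] (default all eight).
#' @return Long data.frame: one row per (trial, variable, frame), columns
#'   `trial_id`, `behavior`, `species`, `individual_id`, `variable`,
#'   `frame_index`, `time_s`, `value`, `units`.
#' @export
compute_all_variables <- function(trials, variables = kin_variables()) {
  if (inherits(trials, "landmark_trial")) trials <- list(trials)
  out <- lapply(trials, function(tr) {
    tr <- if (isTRUE(attr(tr, "registered"))) tr else register_frames(tr)
    do.call(rbind, lapply(variables, function(v) {
      as.data.frame(compute_variable(tr, v))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
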