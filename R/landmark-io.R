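# Landmark I/O: trial container, CSV reading/writing, validation,
# gap interpolation, and registration to the pectoral-fin reference.

VENTRAL_IDS <- 1:14
LATERAL_IDS <- 15:23
BEHAVIORS <- c("feeding", "climbing")

# Reference landmarks whose midpoint defines the stationary body point:
# ventral 12/13 = right/left pectoral fin bases; lateral 22/23 = dorsal/ventral
# edges of the pectoral fin base.
REF_IDS <- list(ventral = c(12L, 13L), lateral = c(22L, 23L))

LANDMARK_COLUMNS <- c(
  "trial_id", "species", "individual_id", "behavior", "body_length_cm",
  "frame_rate_hz", "frame_index", "time_s", "view", "landmark_id",
  "x", "y", "missing"
)

#' Construct a landmark trial
#'
#' A `landmark_trial` holds one digitized behavioral cycle: synchronized
#' ventral (landmarks 1-14) and lateral (landmarks 15-23) 2-D coordinates per
#' frame, in centimeters, plus trial metadata. The behavioral cycle runs over
#' the closed frame interval `[cycle_start, cycle_end]` (0-based indices);
#' by convention a digitized file spans exactly one cycle, so the defaults
#' cover all frames.
#'
#' @param trial_id,species,individual_id character scalars identifying the trial.
#' @param behavior `"feeding"` or `"climbing"`.
#' @param body_length total body length in cm (> 0).
#' @param frame_rate frames per second (> 0).
#' @param points data.frame with columns `frame_index`, `time`, `view`,
#'   `landmark_id`, `x`, `y`, `missing` (0/1). Coordinates in cm; a missing
#'   landmark has `missing = 1` and `NA` coordinates, never silent zeros.
#' @param cycle_start,cycle_end frame indices bounding the cycle (closed
#'   interval). Default: first and last frame.
#' @param body_length_range plausibility window for `body_length` in cm.
#' @param validate run invariant checks (default `TRUE`).
#' @return An object of class `landmark_trial`.
#' @export
landmark_trial <- function(trial_id, species, individual_id, behavior,
                           body_length, frame_rate, points,
                           cycle_start = NULL, cycle_end = NULL,
                           body_length_range = c(1, 30), validate = TRUE) {
  points <- as.data.frame(points)
  need <- c("frame_index", "time", "view", "landmark_id", "x", "y", "missing")
  miss <- setdiff(need, names(points))
  if (length(miss) > 0) {
    gk_stop("gk_format_error",
            sprintf("points is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  points <- points[order(points$view, points$frame_index, points$landmark_id),
                   need, drop = FALSE]
  rownames(points) <- NULL
  fr <- sort(unique(points$frame_index))
  trial <- structure(
    list(
      trial_id = as.character(trial_id),
      species = as.character(species),
      individual_id = as.character(individual_id),
      behavior = as.character(behavior),
      body_length = as.numeric(body_length),
      frame_rate = as.numeric(frame_rate),
      cycle_start = as.integer(cycle_start %||% fr[1]),
      cycle_end = as.integer(cycle_end %||% fr[length(fr)]),
      points = points
    ),
    class = "landmark_trial"
  )
  if (validate) validate_trial(trial, body_length_range = body_length_range)
  trial
}

#' @export
print.landmark_trial <- function(x, ...) {
  cat(sprintf(
    "<landmark_trial> %s | %s %s (%s) | BL %.2f cm | %d frames @ %g Hz | cycle [%d, %d]%s\n",
    x$trial_id, x$species, x$individual_id, x$behavior, x$body_length,
    length(unique(x$points$frame_index)), x$frame_rate,
    x$cycle_start, x$cycle_end,
    if (isTRUE(attr(x, "registered"))) " | registered" else ""
  ))
  invisible(x)
}

#' Validate a landmark trial against its invariants
#'
#' Checks the view/landmark-id contract (ventral frames carry ids 1-14 only,
#' lateral frames ids 15-23 only), strictly increasing frame times with
#' spacing `1/frame_rate`, finite coordinates for non-missing points, cycle
#' bounds, and metadata plausibility.
#'
#' @param trial a `landmark_trial`.
#' @param body_length_range allowed window for body length in cm.
#' @return `trial`, invisibly; signals a classed error on violation.
#' @export
validate_trial <- function(trial, body_length_range = c(1, 30)) {
  p <- trial$points
  if (!trial$behavior %in% BEHAVIORS) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': behavior must be one of %s, got '%s'",
      trial$trial_id, paste(BEHAVIORS, collapse = "/"), trial$behavior))
  }
  if (!is.finite(trial$body_length) || trial$body_length < body_length_range[1] ||
      trial$body_length > body_length_range[2]) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': body_length %.3g cm outside plausibility window [%g, %g]",
      trial$trial_id, trial$body_length, body_length_range[1], body_length_range[2]))
  }
  if (!is.finite(trial$frame_rate) || trial$frame_rate <= 0) {
    gk_stop("gk_data_error", sprintf("trial '%s': frame_rate must be > 0", trial$trial_id))
  }
  if (!all(p$view %in% c("ventral", "lateral"))) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': view must be 'ventral' or 'lateral'", trial$trial_id))
  }
  bad_v <- p$view == "ventral" & !(p$landmark_id %in% VENTRAL_IDS)
  bad_l <- p$view == "lateral" & !(p$landmark_id %in% LATERAL_IDS)
  if (any(bad_v) || any(bad_l)) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': landmark ids must be 1-14 in ventral and 15-23 in lateral frames",
      trial$trial_id))
  }
  dup <- duplicated(p[, c("view", "frame_index", "landmark_id")])
  if (any(dup)) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': duplicate (frame_index, landmark_id, view) rows", trial$trial_id))
  }
  obs <- p$missing == 0
  if (any(!is.finite(p$x[obs])) || any(!is.finite(p$y[obs]))) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': non-finite coordinates on points not flagged missing",
      trial$trial_id))
  }
  tm <- unique(p[, c("frame_index", "time")])
  tm <- tm[order(tm$frame_index), ]
  if (anyDuplicated(tm$frame_index)) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': inconsistent time values within a frame", trial$trial_id))
  }
  if (nrow(tm) > 1) {
    dt <- diff(tm$time)
    if (any(dt <= 0)) {
      gk_stop("gk_data_error", sprintf(
        "trial '%s': frame times are not strictly increasing", trial$trial_id))
    }
    if (any(abs(dt - 1 / trial$frame_rate) > 1e-6 * max(1, 1 / trial$frame_rate))) {
      gk_stop("gk_data_error", sprintf(
        "trial '%s': frame spacing differs from 1/frame_rate", trial$trial_id))
    }
  }
  if (!(trial$cycle_start < trial$cycle_end &&
        trial$cycle_end <= max(tm$frame_index))) {
    gk_stop("gk_data_error", sprintf(
      "trial '%s': cycle indices must satisfy start < end <= last frame",
      trial$trial_id))
  }
  invisible(trial)
}

#' Read digitized landmark trajectories from a long-format CSV
#'
#' One row per digitized point; required columns: `trial_id`, `species`,
#' `individual_id`, `behavior`, `body_length_cm`, `frame_rate_hz`,
#' `frame_index`, `time_s`, `view`, `landmark_id`, `x`, `y`, `missing`.
#' Raw coordinates are multiplied by the per-view calibration factor
#' (cm per file unit) on read.
#'
#' @param path CSV file path.
#' @param calibration named numeric vector `c(ventral = ..., lateral = ...)`,
#'   cm per file unit for each view.
#' @param body_length_range plausibility window for body length (cm).
#' @return A named list of [landmark_trial] objects, one per `trial_id`,
#'   frames sorted by time.
#' @export
read_landmark_table <- function(path, calibration = c(ventral = 1, lateral = 1),
                                body_length_range = c(1, 30)) {
  if (!file.exists(path)) {
    gk_stop("gk_format_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(LANDMARK_COLUMNS, names(df))
  if (length(miss) > 0) {
    gk_stop("gk_format_error",
            sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(c("ventral", "lateral") %in% names(calibration))) {
    gk_stop("gk_usage_error", "calibration must name both 'ventral' and 'lateral'")
  }
  dup <- duplicated(df[, c("trial_id", "frame_index", "landmark_id", "view")])
  if (any(dup)) {
    gk_stop("gk_data_error", sprintf(
      "duplicate (trial_id, frame_index, landmark_id, view) rows, e.g. trial '%s' frame %d landmark %d",
      df$trial_id[dup][1], df$frame_index[dup][1], df$landmark_id[dup][1]))
  }
  df$x <- df$x * unname(calibration[df$view])
  df$y <- df$y * unname(calibration[df$view])
  df$x[df$missing == 1] <- NA_real_
  df$y[df$missing == 1] <- NA_real_

  trials <- lapply(split(df, df$trial_id), function(d) {
    meta <- unique(d[, c("species", "individual_id", "behavior",
                         "body_length_cm", "frame_rate_hz")])
    if (nrow(meta) != 1) {
      gk_stop("gk_data_error", sprintf(
        "trial '%s': inconsistent per-trial metadata", d$trial_id[1]))
    }
    pts <- data.frame(
      frame_index = d$frame_index, time = d$time_s, view = d$view,
      landmark_id = d$landmark_id, x = d$x, y = d$y, missing = d$missing
    )
    landmark_trial(
      trial_id = d$trial_id[1], species = meta$species,
      individual_id = meta$individual_id, behavior = meta$behavior,
      body_length = meta$body_length_cm, frame_rate = meta$frame_rate_hz,
      points = pts, body_length_range = body_length_range
    )
  })
  trials[order(names(trials))]
}

#' Write landmark trials to the long-format CSV dialect
#'
#' Inverse of [read_landmark_table()] at unit calibration (coordinates are
#' written in cm).
#'
#' @param trials a `landmark_trial` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(trials, path) {
  if (inherits(trials, "landmark_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    p <- tr$points
    data.frame(
      trial_id = tr$trial_id, species = tr$species,
      individual_id = tr$individual_id, behavior = tr$behavior,
      body_length_cm = tr$body_length, frame_rate_hz = tr$frame_rate,
      frame_index = p$frame_index, time_s = p$time, view = p$view,
      landmark_id = p$landmark_id, x = p$x, y = p$y, missing = p$missing
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$trial_id), , drop = FALSE]  # canonical order: idempotent IO
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Fill interior gaps in landmark trajectories by linear interpolation
#'
#' A gap is a run of frames where a landmark is flagged missing. Gaps must be
#' interior (observed frames on both sides) and no longer than `max_gap`
#' frames; longer or boundary gaps are unrecoverable. Interpolated frames are
#' recorded in the QC log (attribute `qc_log`, tab-separated
#' `trial_id<TAB>event<TAB>detail` lines).
#'
#' @param trial a `landmark_trial`.
#' @param max_gap maximum fillable gap length in frames (default 3).
#' @return The trial with gaps filled and `missing` cleared on filled points.
#' @export
interpolate_missing <- function(trial, max_gap = 3) {
  p <- trial$points
  qc <- attr(trial, "qc_log") %||% character()
  for (vw in unique(p$view)) {
    for (id in unique(p$landmark_id[p$view == vw])) {
      sel <- which(p$view == vw & p$landmark_id == id)
      sel <- sel[order(p$frame_index[sel])]
      miss <- p$missing[sel] == 1 | !is.finite(p$x[sel]) | !is.finite(p$y[sel])
      if (!any(miss)) next
      r <- rle(miss)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        gap_len <- r$lengths[k]
        fr_lo <- p$frame_index[sel[starts[k]]]
        fr_hi <- p$frame_index[sel[ends[k]]]
        interior <- starts[k] > 1 && ends[k] < length(sel)
        if (!interior || gap_len > max_gap) {
          gk_stop("gk_gap_error", sprintf(
            "trial '%s': unrecoverable gap for landmark %d (%s view), frames %d-%d (length %d, max_gap %d%s)",
            trial$trial_id, id, vw, fr_lo, fr_hi, gap_len, max_gap,
            if (!interior) ", at cycle boundary" else ""))
        }
        qc <- c(qc, sprintf("%s\tinterpolated\tlandmark=%d view=%s frames=%d-%d gap=%d",
                            trial$trial_id, id, vw, fr_lo, fr_hi, gap_len))
      }
      tt <- p$time[sel]
      ok <- !miss
      p$x[sel[miss]] <- stats::approx(tt[ok], p$x[sel][ok], xout = tt[miss])$y
      p$y[sel[miss]] <- stats::approx(tt[ok], p$y[sel][ok], xout = tt[miss])$y
      p$missing[sel[miss]] <- 0
    }
  }
  trial$points <- p
  attr(trial, "qc_log") <- qc
  trial
}

#' Register frames to the stationary pectoral-fin reference
#'
#' Translates every ventral frame so the midpoint of landmarks 12 and 13
#' (pectoral fin bases) sits at the origin, and every lateral frame so the
#' midpoint of landmarks 22 and 23 sits at the origin. This removes whole-body
#' advance (e.g. up the climbing substrate) so that displacement variables
#' measure cranial motion relative to the body, not locomotion. The operation
#' is idempotent and invariant under any rigid translation of the raw data.
#'
#' @param trial a `landmark_trial`.
#' @return The registered trial (attribute `registered = TRUE`).
#' @export
register_frames <- function(trial) {
  p <- trial$points
  for (vw in c("ventral", "lateral")) {
    ids <- REF_IDS[[vw]]
    vsel <- p$view == vw
    if (!any(vsel)) next
    for (fr in unique(p$frame_index[vsel])) {
      fsel <- vsel & p$frame_index == fr
      ref <- p[fsel & p$landmark_id %in% ids, ]
      if (nrow(ref) != 2 || any(ref$missing == 1) ||
          any(!is.finite(ref$x)) || any(!is.finite(ref$y))) {
        gk_stop("gk_registration_error", sprintf(
          "trial '%s': reference landmark(s) %s missing in %s frame %d",
          trial$trial_id, paste(ids, collapse = "/"), vw, fr))
      }
      p$x[fsel] <- p$x[fsel] - mean(ref$x)
      p$y[fsel] <- p$y[fsel] - mean(ref$y)
    }
  }
  trial$points <- p
  attr(trial, "registered") <- TRUE
  trial
}

#' Retrieve the QC log of a trial
#'
#' @param trial a `landmark_trial`.
#' @return Character vector of tab-separated `trial_id  event  detail` lines.
#' @export
qc_log <- function(trial) attr(trial, "qc_log") %||% character()

# Coordinates of one landmark over the cycle frames: n x 2 matrix, rows in
# frame order. Errors if the landmark is absent or still missing.
lm_xy <- function(trial, id, frames = NULL) {
  vw <- if (id %in% VENTRAL_IDS) "ventral" else "lateral"
  p <- trial$points
  sel <- p$view == vw & p$landmark_id == id
  if (is.null(frames)) {
    sel <- sel & p$frame_index >= trial$cycle_start & p$frame_index <= trial$cycle_end
  } else {
    sel <- sel & p$frame_index %in% frames
  }
  d <- p[sel, ]
  d <- d[order(d$frame_index), ]
  if (nrow(d) == 0 || any(d$missing == 1) || any(!is.finite(d$x)) || any(!is.finite(d$y))) {
    gk_stop("gk_geometry_error", sprintf(
      "trial '%s': landmark %d (%s view) missing within the cycle",
      trial$trial_id, id, vw))
  }
  cbind(x = d$x, y = d$y)
}

# Cycle time vector (seconds), one entry per frame of the closed cycle.
cycle_times <- function(trial) {
  p <- trial$points
  tm <- unique(p[p$frame_index >= trial$cycle_start &
                   p$frame_index <= trial$cycle_end, c("frame_index", "time")])
  tm <- tm[order(tm$frame_index), ]
  tm$time
}
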