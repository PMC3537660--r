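# Synthetic cyclic-motion generator: virtual fish performing parameterized
# feeding or climbing cycles, with analytic ground truth for every kinematic
# variable. The landmark geometry is built so that each variable definition,
# run in reverse, yields the requested waveform exactly (before noise).

#' Motion parameters for a synthetic behavioral cycle
#'
#' Amplitudes default to the published mean maxima for *Sicyopterus
#' stimpsoni* feeding and climbing regimes via [feeding_params()] /
#' [climbing_params()]. Waveforms are half-sine rise-and-return pulses by
#' default; a skewed beta-shaped pulse is available to construct known shape
#' differences between groups.
#'
#' @param behavior `"feeding"` or `"climbing"`.
#' @param species species label for trial metadata.
#' @param cycle_duration cycle length in seconds (> 0).
#' @param frame_rate sampling rate in Hz.
#' @param body_length total body length in cm.
#' @param premax_length_amp peak premaxillary protrusion length (BL).
#' @param premax_angle_amp peak premaxillary protrusion angle (degrees).
#' @param cranial_elevation_amp peak cranial elevation angle (degrees).
#' @param hyoid_length_amp peak hyoid retraction length (BL).
#' @param mandible_length_amp peak mandibular retraction length (BL).
#' @param opercular_baseline resting inter-opercular width (BL).
#' @param opercular_excursion peak opercular widening beyond baseline (BL).
#' @param sucker_area_baseline resting oral-sucker area (BL^2).
#' @param phase_lag fraction of the cycle by which hyoid/mandibular
#'   retraction (and opercular widening) trail premaxillary protrusion,
#'   in `[0, 1)`.
#' @param noise_sd isotropic Gaussian digitizing noise, cm per coordinate.
#' @param whole_body_advance whole-body translation per cycle in cm
#'   (climbing locomotion; removed by registration).
#' @param waveform `"halfsine"` or `"beta"`.
#' @param beta_shape length-2 numeric `c(p, q)` (> 1 each) for the beta
#'   pulse `s^(p-1) (1-s)^(q-1)`, normalized to unit peak.
#' @param seed integer seed making the trial deterministic; `NULL` uses the
#'   current RNG state.
#' @return A `motion_params` list.
#' @export
motion_params <- function(behavior,
                          species = "Sicyopterus stimpsoni",
                          cycle_duration,
                          frame_rate,
                          body_length,
                          premax_length_amp,
                          premax_angle_amp,
                          cranial_elevation_amp,
                          hyoid_length_amp,
                          mandible_length_amp,
                          opercular_baseline,
                          opercular_excursion,
                          sucker_area_baseline,
                          phase_lag = 0.25,
                          noise_sd = 0.01,
                          whole_body_advance = 0,
                          waveform = c("halfsine", "beta"),
                          beta_shape = c(3, 3),
                          seed = NULL) {
  waveform <- match.arg(waveform)
  p <- list(
    behavior = behavior, species = species,
    cycle_duration = cycle_duration, frame_rate = frame_rate,
    body_length = body_length,
    premax_length_amp = premax_length_amp,
    premax_angle_amp = premax_angle_amp,
    cranial_elevation_amp = cranial_elevation_amp,
    hyoid_length_amp = hyoid_length_amp,
    mandible_length_amp = mandible_length_amp,
    opercular_baseline = opercular_baseline,
    opercular_excursion = opercular_excursion,
    sucker_area_baseline = sucker_area_baseline,
    phase_lag = phase_lag, noise_sd = noise_sd,
    whole_body_advance = whole_body_advance,
    waveform = waveform, beta_shape = beta_shape, seed = seed
  )
  amps <- c(p$premax_length_amp, p$premax_angle_amp, p$cranial_elevation_amp,
            p$hyoid_length_amp, p$mandible_length_amp, p$opercular_baseline,
            p$opercular_excursion, p$sucker_area_baseline)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    gk_stop("gk_usage_error", "all amplitudes must be finite and >= 0")
  }
  if (!(phase_lag >= 0 && phase_lag < 1)) {
    gk_stop("gk_usage_error", "phase_lag must lie in [0, 1)")
  }
  if (noise_sd < 0) gk_stop("gk_usage_error", "noise_sd must be >= 0")
  if (!(cycle_duration > 0) || !(frame_rate > 0) || !(body_length > 0)) {
    gk_stop("gk_usage_error", "duration, frame rate and body length must be > 0")
  }
  if (waveform == "beta" && (length(beta_shape) != 2 || any(beta_shape <= 1))) {
    gk_stop("gk_usage_error", "beta_shape must be two values > 1")
  }
  structure(p, class = "motion_params")
}

#' Default parameters for the feeding regime
#'
#' Feeding cycles of about 0.141 s filmed at 500 Hz; amplitudes default to
#' the published feeding mean maxima (premaxillary protrusion 0.031 BL and
#' 25.031 deg, cranial elevation 5.824 deg, hyoid retraction 0.014 BL,
#' mandibular retraction 0.019 BL, peak opercular width 0.171 BL).
#'
#' @param ... overrides passed to [motion_params()].
#' @return A `motion_params`.
#' @export
feeding_params <- function(...) {
  defaults <- list(
    behavior = "feeding", cycle_duration = 0.141, frame_rate = 500,
    body_length = 5.05,
    premax_length_amp = 0.031, premax_angle_amp = 25.031,
    cranial_elevation_amp = 5.824, hyoid_length_amp = 0.014,
    mandible_length_amp = 0.019,
    opercular_baseline = 0.164, opercular_excursion = 0.007,
    sucker_area_baseline = 0.005
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(motion_params, args)
}

#' Default parameters for the climbing regime
#'
#' Climbing cycles of about 0.313 s filmed at 200 Hz; amplitudes default to
#' the published climbing mean maxima (premaxillary protrusion 0.035 BL and
#' 22.897 deg, cranial elevation 7.173 deg, hyoid retraction 0.028 BL,
#' mandibular retraction 0.034 BL, peak opercular width 0.132 BL), with a
#' whole-body advance up the substrate each cycle.
#'
#' @param ... overrides passed to [motion_params()].
#' @return A `motion_params`.
#' @export
climbing_params <- function(...) {
  defaults <- list(
    behavior = "climbing", cycle_duration = 0.313, frame_rate = 200,
    body_length = 6.40,
    premax_length_amp = 0.035, premax_angle_amp = 22.897,
    cranial_elevation_amp = 7.173, hyoid_length_amp = 0.028,
    mandible_length_amp = 0.034,
    opercular_baseline = 0.125, opercular_excursion = 0.007,
    sucker_area_baseline = 0.0035,
    whole_body_advance = 0.3
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(motion_params, args)
}

# Unit-peak pulse over cycle phase s in [0, 1]; 0 at both ends.
motion_pulse <- function(s, waveform = "halfsine", beta_shape = c(3, 3)) {
  if (waveform == "halfsine") return(sin(pi * s))
  p <- beta_shape[1]; q <- beta_shape[2]
  mode <- (p - 1) / (p + q - 2)
  peak <- mode^(p - 1) * (1 - mode)^(q - 1)
  s^(p - 1) * (1 - s)^(q - 1) / peak
}

# Pulse delayed by `lag` of the cycle and compressed into the remainder,
# so it still starts and ends at zero.
lagged_pulse <- function(s, lag, waveform, beta_shape) {
  s2 <- pmax(0, pmin(1, (s - lag) / (1 - lag)))
  motion_pulse(s2, waveform, beta_shape)
}

# Resting head geometry in cm, relative to the pectoral reference midpoints.
# Mouth landmarks follow a fixed template scaled so the sucker-area model
# equals the requested baseline at rest; point 15 sits on a circle about
# point 18 with radius tying the premaxillary length and angle amplitudes
# together (L = 2 r sin(A/2)).
rest_geometry <- function(p) {
  BL <- p$body_length
  # mouth template (unit coords): A, B on the midline, C/D on the right
  tmpl <- list(A = c(0, 0.55), B = c(0, -0.45), C = c(0.80, 0.05),
               D = c(0.42, -0.28))
  tmpl_area <- oral_sucker_area(tmpl$A, tmpl$B, tmpl$C, tmpl$D)
  lam <- sqrt(p$sucker_area_baseline * BL^2 / tmpl_area)
  mc_y <- 0.26 * BL   # mouth center, anterior of the pectoral midpoint

  ang <- p$premax_angle_amp * pi / 180
  r <- if (ang > 1e-9) {
    p$premax_length_amp * BL / (2 * sin(ang / 2))
  } else {
    0.07 * BL
  }
  beta <- -40 * pi / 180   # resting direction of vector 18 -> 15

  list(
    BL = BL, lam = lam, mc_y = mc_y, r = r, beta = beta,
    ventral = list(
      A_y = mc_y + lam * tmpl$A[2],    # point 1
      p2_y = mc_y + lam * tmpl$A[2] - 0.10 * lam,
      B_y = mc_y + lam * tmpl$B[2],    # point 3
      C = c(lam * tmpl$C[1], mc_y + lam * tmpl$C[2]),   # point 4
      D = c(lam * tmpl$D[1], mc_y + lam * tmpl$D[2]),   # point 6
      hyoid_y = 0.14 * BL,             # point 8
      p9_y = 0.10 * BL,
      operc_y = 0.04 * BL,             # points 10/11
      pec_x = 0.05 * BL,               # points 12/13
      pelvic_y = -0.05 * BL            # point 14
    ),
    lateral = list(
      P18 = c(0.22, 0.055) * BL,
      P20 = c(0.06, 0.07) * BL,
      P19 = c(0.16, 0.06) * BL,
      P17 = c(0.17, -0.01) * BL,
      P21 = c(0.05, 0.01) * BL,
      P22 = c(0, 0.03) * BL,
      P23 = c(0, -0.03) * BL
    )
  )
}

# Closed-form hyoid retraction angle (deg) given hyoid y (cm), opercular
# half-width (cm) and opercular y (cm); the stationary point M is the origin.
hyoid_angle_closed_form <- function(hy_y, half_w, op_y) {
  v1x <- 0; v1y <- -hy_y                 # point 8 -> M
  v2x <- -half_w; v2y <- op_y - hy_y     # point 8 -> point 11 (left)
  cosang <- (v1x * v2x + v1y * v2y) /
    (sqrt(v1x^2 + v1y^2) * sqrt(v2x^2 + v2y^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Closed-form sucker-area model (same three shapes as the kinematics module,
# written independently here so the generator's truth does not call the code
# under test).
sucker_area_closed_form <- function(Ay, By, C, D_x, D_y) {
  ABx <- 0; ABy <- By - Ay
  ACx <- C[1]; ACy <- C[2] - Ay
  nAB <- abs(ABy); nAC <- sqrt(ACx^2 + ACy^2)
  cross <- ABx * ACy - ABy * ACx
  dot <- ABx * ACx + ABy * ACy
  theta <- atan2(abs(cross), dot)
  X <- theta * nAB^2 / 2
  Y <- abs(cross) / 2
  BDx <- D_x; BDy <- D_y - By
  BCx <- C[1]; BCy <- C[2] - By
  Z <- abs(BDx * BCy - BDy * BCx) / 2
  X + Y + Z
}

#' Generate one synthetic behavioral cycle
#'
#' Builds landmark trajectories for a virtual fish from a resting head
#' geometry: half-sine (or beta-pulse) protrusion of the premaxilla
#' (points 15 and 1), phase-lagged retraction of the mandible (points 3, 6,
#' 7) and hyoid (point 8) toward the pectoral midpoint, opercular widening
#' (points 10/11), stationary reference landmarks (12/13/14 ventral, 22/23
#' lateral), optional uniform whole-body advance, and isotropic Gaussian
#' digitizing noise added last. The analytic noise-free trace of every
#' kinematic variable is returned alongside the trial.
#'
#' @param params a `motion_params`.
#' @param trial_id,individual_id identifiers for the trial metadata.
#' @return List with `trial` (a [landmark_trial]) and `truth` (long
#'   data.frame `trial_id`, `variable`, `frame_index`, `value` in final
#'   units: degrees, BL, BL^2).
#' @export
generate_trial <- function(params, trial_id = "synth-1", individual_id = "ind-1") {
  p <- params
  n <- round(p$cycle_duration * p$frame_rate) + 1
  if (n < 8) {
    gk_stop("gk_insufficient_frames_error", sprintf(
      "cycle of %.4g s at %g Hz gives only %d frames (need >= 8)",
      p$cycle_duration, p$frame_rate, n))
  }
  if (!is.null(p$seed)) set.seed(p$seed)
  tt <- (0:(n - 1)) / p$frame_rate
  s <- (0:(n - 1)) / (n - 1)
  BL <- p$body_length
  g <- rest_geometry(p)

  wp <- motion_pulse(s, p$waveform, p$beta_shape)
  wl <- lagged_pulse(s, p$phase_lag, p$waveform, p$beta_shape)

  phi <- p$premax_angle_amp * wp * pi / 180        # premax rotation, rad
  phic <- p$cranial_elevation_amp * wp * pi / 180  # cranial rotation, rad
  dm <- p$mandible_length_amp * BL * wl            # mandible retraction, cm
  dh <- p$hyoid_length_amp * BL * wl               # hyoid retraction, cm
  W <- (p$opercular_baseline + p$opercular_excursion * wl) * BL  # width, cm

  # lateral point 15: rotation about point 18 (or radial protrusion when the
  # angle amplitude is zero)
  v0 <- g$r * c(cos(g$beta), sin(g$beta))
  if (p$premax_angle_amp > 1e-9) {
    p15x <- g$lateral$P18[1] + cos(phi) * v0[1] - sin(phi) * v0[2]
    p15y <- g$lateral$P18[2] + sin(phi) * v0[1] + cos(phi) * v0[2]
    premax_len_cm <- 2 * g$r * sin(phi / 2)
  } else {
    ext <- g$r + p$premax_length_amp * BL * wp
    p15x <- g$lateral$P18[1] + ext * cos(g$beta)
    p15y <- g$lateral$P18[2] + ext * sin(g$beta)
    premax_len_cm <- p$premax_length_amp * BL * wp
  }
  da <- p15x - p15x[1]   # anterior premax displacement, reused ventrally

  # ventral mouth landmark positions over time (cm)
  Ay <- g$ventral$A_y + da
  By <- g$ventral$B_y - dm
  Cx <- g$ventral$C[1]; Cy <- g$ventral$C[2]
  Dx <- g$ventral$D[1]; Dy <- g$ventral$D[2] - dm

  adv <- p$whole_body_advance * s   # cm, along direction of travel

  ventral <- list(
    `1` = cbind(0, Ay), `2` = cbind(0, g$ventral$p2_y + da),
    `3` = cbind(0, By), `4` = cbind(Cx, Cy), `5` = cbind(-Cx, Cy),
    `6` = cbind(Dx, Dy), `7` = cbind(-Dx, Dy),
    `8` = cbind(0, g$ventral$hyoid_y - dh), `9` = cbind(0, g$ventral$p9_y),
    `10` = cbind(W / 2, g$ventral$operc_y),
    `11` = cbind(-W / 2, g$ventral$operc_y),
    `12` = cbind(g$ventral$pec_x, 0), `13` = cbind(-g$ventral$pec_x, 0),
    `14` = cbind(0, g$ventral$pelvic_y)
  )
  P18 <- g$lateral$P18
  rot_about_18 <- function(P0, ang) {
    v <- P0 - P18
    cbind(P18[1] + cos(ang) * v[1] - sin(ang) * v[2],
          P18[2] + sin(ang) * v[1] + cos(ang) * v[2])
  }
  p16 <- rot_about_18(P18 + 0.55 * v0, phi)
  lateral <- list(
    `15` = cbind(p15x, p15y), `16` = p16,
    `17` = matrix(g$lateral$P17, n, 2, byrow = TRUE),
    `18` = matrix(P18, n, 2, byrow = TRUE),
    `19` = matrix(g$lateral$P19, n, 2, byrow = TRUE),
    `20` = rot_about_18(g$lateral$P20, phic),
    `21` = matrix(g$lateral$P21, n, 2, byrow = TRUE),
    `22` = matrix(g$lateral$P22, n, 2, byrow = TRUE),
    `23` = matrix(g$lateral$P23, n, 2, byrow = TRUE)
  )

  rows <- list()
  for (id in names(ventral)) {
    m <- ventral[[id]]
    rows[[length(rows) + 1]] <- data.frame(
      frame_index = 0:(n - 1), time = tt, view = "ventral",
      landmark_id = as.integer(id), x = rep_len(m[, 1], n),
      y = rep_len(m[, 2], n) + adv, missing = 0)
  }
  for (id in names(lateral)) {
    m <- lateral[[id]]
    rows[[length(rows) + 1]] <- data.frame(
      frame_index = 0:(n - 1), time = tt, view = "lateral",
      landmark_id = as.integer(id), x = rep_len(m[, 1], n) + adv,
      y = rep_len(m[, 2], n), missing = 0)
  }
  pts <- do.call(rbind, rows)
  if (p$noise_sd > 0) {
    pts$x <- pts$x + stats::rnorm(nrow(pts), 0, p$noise_sd)
    pts$y <- pts$y + stats::rnorm(nrow(pts), 0, p$noise_sd)
  }

  trial <- landmark_trial(
    trial_id = trial_id, species = p$species, individual_id = individual_id,
    behavior = p$behavior, body_length = BL, frame_rate = p$frame_rate,
    points = pts
  )

  truth_vals <- list(
    cranial_elevation_angle = p$cranial_elevation_amp * wp,
    premaxillary_protrusion_angle = p$premax_angle_amp * wp,
    premaxillary_protrusion_length = premax_len_cm / BL,
    hyoid_retraction_angle = hyoid_angle_closed_form(
      g$ventral$hyoid_y - dh, W / 2, g$ventral$operc_y),
    hyoid_retraction_length = p$hyoid_length_amp * wl,
    mandibular_retraction_length = p$mandible_length_amp * wl,
    opercular_expansion_length = W / BL,
    oral_sucker_area = sucker_area_closed_form(Ay, By, c(Cx, Cy), Dx, Dy) / BL^2
  )
  truth <- do.call(rbind, lapply(names(truth_vals), function(v) {
    data.frame(trial_id = trial_id, variable = v, frame_index = 0:(n - 1),
               value = truth_vals[[v]])
  }))
  rownames(truth) <- NULL
  list(trial = trial, truth = truth)
}

#' Generate a reproducible multi-trial synthetic study
#'
#' Emulates a study design of grouped behavioral cycles: per group, cycles
#' are distributed across individuals, individuals carry lognormal random
#' effects on motion amplitudes, and each cycle's duration is jittered
#' lognormally around the group mean.
#'
#' @param design named list of group specifications, each a list with
#'   `params` (a `motion_params`), `n_cycles`, `n_individuals`, and optional
#'   `cv_individual` (lognormal CV of per-individual amplitude multipliers,
#'   default 0.10) and `cv_duration` (per-cycle duration jitter CV, default
#'   0.05).
#' @param seed integer seed driving all randomness.
#' @param out_dir optional directory; when given, writes `landmarks.csv`
#'   (the [read_landmark_table()] dialect), `ground_truth.csv`, and a
#'   `params.yaml` sidecar recording the design and seed.
#' @return List with `trials` (named list of [landmark_trial]), `truth`
#'   (long data.frame), and `design_log` (per-trial parameter table).
#' @export
generate_study <- function(design, seed = 1, out_dir = NULL) {
  if (length(design) < 1) gk_stop("gk_usage_error", "design needs >= 1 group")
  if (is.null(names(design)) || any(names(design) == "")) {
    gk_stop("gk_usage_error", "design groups must be named")
  }
  set.seed(seed)
  amp_fields <- c("premax_length_amp", "premax_angle_amp",
                  "cranial_elevation_amp", "hyoid_length_amp",
                  "mandible_length_amp", "opercular_excursion")
  trials <- list(); truths <- list(); log_rows <- list()
  for (gname in names(design)) {
    spec <- design[[gname]]
    base <- spec$params
    n_cyc <- spec$n_cycles
    n_ind <- spec$n_individuals %||% 1L
    cv_i <- spec$cv_individual %||% 0.10
    cv_d <- spec$cv_duration %||% 0.05
    if (n_cyc < 1) gk_stop("gk_usage_error", "n_cycles must be >= 1")
    sdlog_i <- sqrt(log(1 + cv_i^2))
    sdlog_d <- sqrt(log(1 + cv_d^2))
    ind_mult <- if (cv_i > 0) {
      stats::rlnorm(n_ind, meanlog = -sdlog_i^2 / 2, sdlog = sdlog_i)
    } else rep(1, n_ind)
    ind_of_cycle <- rep(seq_len(n_ind), length.out = n_cyc)
    for (k in seq_len(n_cyc)) {
      ind <- ind_of_cycle[k]
      pk <- base
      for (f in amp_fields) pk[[f]] <- base[[f]] * ind_mult[ind]
      if (cv_d > 0) {
        pk$cycle_duration <- base$cycle_duration *
          stats::rlnorm(1, meanlog = -sdlog_d^2 / 2, sdlog = sdlog_d)
      }
      pk$seed <- NULL  # randomness flows from the study seed
      tid <- sprintf("%s_i%02d_c%03d", gname, ind, k)
      if (tid %in% names(trials)) {
        gk_stop("gk_usage_error", sprintf("duplicate trial id '%s'", tid))
      }
      gt <- generate_trial(pk, trial_id = tid,
                           individual_id = sprintf("%s_i%02d", gname, ind))
      trials[[tid]] <- gt$trial
      truths[[tid]] <- gt$truth
      log_rows[[tid]] <- data.frame(
        trial_id = tid, group = gname, individual = sprintf("%s_i%02d", gname, ind),
        behavior = pk$behavior, cycle_duration = pk$cycle_duration,
        frame_rate = pk$frame_rate, body_length = pk$body_length,
        amp_multiplier = ind_mult[ind]
      )
    }
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  design_log <- do.call(rbind, log_rows)
  rownames(design_log) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_landmark_table(trials, file.path(out_dir, "landmarks.csv"))
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    sidecar <- list(
      seed = seed,
      groups = lapply(design, function(spec) {
        pl <- unclass(spec$params)
        pl$seed <- NULL
        list(params = pl, n_cycles = spec$n_cycles,
             n_individuals = spec$n_individuals %||% 1L,
             cv_individual = spec$cv_individual %||% 0.10,
             cv_duration = spec$cv_duration %||% 0.05)
      })
    )
    yaml::write_yaml(sidecar, file.path(out_dir, "params.yaml"))
  }
  list(trials = trials, truth = truth, design_log = design_log)
}

#' Study design mirroring the published cycle counts
#'
#' Feeding: 96 cycles from 4 individuals; climbing: 36 cycles from 3
#' individuals, using the default behavior parameter sets.
#'
#' @param feeding,climbing `motion_params` for each behavior.
#' @return A design list for [generate_study()].
#' @export
default_study_design <- function(feeding = feeding_params(),
                                 climbing = climbing_params()) {
  list(
    feeding = list(params = feeding, n_cycles = 96L, n_individuals = 4L),
    climbing = list(params = climbing, n_cycles = 36L, n_individuals = 3L)
  )
}
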