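# Shared fixtures: all test data is generated in code.

# Fast, small parameter sets (short cycles, modest frame counts).
quick_feeding <- function(...) {
  args <- utils::modifyList(list(cycle_duration = 0.06, noise_sd = 0), list(...))
  do.call(feeding_params, args)
}
quick_climbing <- function(...) {
  args <- utils::modifyList(list(cycle_duration = 0.15, noise_sd = 0,
                                 whole_body_advance = 0), list(...))
  do.call(climbing_params, args)
}

# Hand-built static head geometry for unit-level variable checks.
# Returns per-landmark resting coordinates (cm) for a BL = 10 cm fish.
toy_geometry <- function() {
  list(
    ventral = rbind(
      `1` = c(0, 3.0), `2` = c(0, 2.8), `3` = c(0, 2.4), `4` = c(0.5, 2.5),
      `5` = c(-0.5, 2.5), `6` = c(0.3, 2.2), `7` = c(-0.3, 2.2),
      `8` = c(0, 1.4), `9` = c(0, 1.0), `10` = c(0.8, 0.4),
      `11` = c(-0.8, 0.4), `12` = c(0.5, 0), `13` = c(-0.5, 0),
      `14` = c(0, -0.5)
    ),
    lateral = rbind(
      `15` = c(2.6, 0.4), `16` = c(2.4, 0.45), `17` = c(1.7, -0.1),
      `18` = c(2.2, 0.55), `19` = c(1.6, 0.6), `20` = c(0.6, 0.7),
      `21` = c(0.5, 0.1), `22` = c(0, 0.3), `23` = c(0, -0.3)
    )
  )
}

# Build a trial from a function frame_coords(k) -> list(ventral=, lateral=)
# of full coordinate matrices (k = 0-based frame index).
toy_trial <- function(frame_coords, n_frames = 3, body_length = 10,
                      frame_rate = 100, behavior = "feeding") {
  rows <- list()
  for (k in 0:(n_frames - 1)) {
    g <- frame_coords(k)
    for (vw in c("ventral", "lateral")) {
      m <- g[[vw]]
      rows[[length(rows) + 1]] <- data.frame(
        frame_index = k, time = k / frame_rate, view = vw,
        landmark_id = as.integer(rownames(m)), x = m[, 1], y = m[, 2],
        missing = 0)
    }
  }
  landmark_trial(
    trial_id = "toy", species = "test", individual_id = "i1",
    behavior = behavior, body_length = body_length, frame_rate = frame_rate,
    points = do.call(rbind, rows))
}

static_toy_trial <- function(n_frames = 3, ...) {
  g <- toy_geometry()
  toy_trial(function(k) g, n_frames = n_frames, ...)
}

# Brute-force numeric oracle for the sucker-area model: polygonal integration
# of the same three shapes (sector approximated by a fine fan polygon,
# triangles by the shoelace formula).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(2:nrow(xy), 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

brute_force_sucker_area <- function(A, B, C, D, n_arc = 20000) {
  AB <- B - A; AC <- C - A
  a1 <- atan2(AB[2], AB[1]); a2 <- atan2(AC[2], AC[1])
  dth <- a2 - a1
  if (dth > pi) dth <- dth - 2 * pi
  if (dth < -pi) dth <- dth + 2 * pi
  r <- sqrt(sum(AB^2))
  arc <- a1 + dth * seq(0, 1, length.out = n_arc)
  sector <- polygon_area(rbind(A, cbind(A[1] + r * cos(arc), A[2] + r * sin(arc))))
  sector + polygon_area(rbind(A, B, C)) + polygon_area(rbind(B, D, C))
}

# From-scratch enumeration oracle for the two-sided exact Mann-Whitney p:
# distribution of U over all assignments of the pooled ranks to group A.
enumerate_mw_p <- function(a, b) {
  m <- length(a); N <- m + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  Us <- apply(utils::combn(N, m), 2, function(idx) {
    sum(sort(r)[idx]) - m * (m + 1) / 2
  })
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}
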