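# Percent-cycle normalization: quintic smoothing spline per trial per
# variable, resampling to 101 evenly spaced increments of cycle duration,
# and aggregation into mean +/- s.e.m. profiles.

# Order-6 (degree-5) B-spline knot vector over the data sites: full-multiplicity
# boundary knots, interior knots at the interior data sites trimmed by three at
# each end, so the basis dimension equals the number of data points and the
# unpenalized fit interpolates exactly.
quintic_knots <- function(t) {
  n <- length(t)
  c(rep(t[1], 6), if (n > 6) t[4:(n - 3)], rep(t[n], 6))
}

# Roughness penalty: Gram matrix of third derivatives of the basis,
# integrated over the fitted span. The third derivative of a quintic
# B-spline is piecewise quadratic, so 3-point Gauss-Legendre quadrature per
# knot span (exact for degree-4 integrands) gives the exact integral.
third_derivative_penalty <- function(knots) {
  k <- length(knots) - 6L
  uk <- unique(knots)
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  Omega <- matrix(0, k, k)
  for (i in seq_len(length(uk) - 1L)) {
    a <- uk[i]; b <- uk[i + 1L]
    h <- (b - a) / 2
    xs <- (a + b) / 2 + h * gp
    Bd <- splines::splineDesign(knots, xs, ord = 6L, derivs = rep(3L, 3L))
    Omega <- Omega + h * crossprod(Bd, gw * Bd)
  }
  Omega
}

#' Fit a quintic smoothing spline to a kinematic series
#'
#' Penalized degree-5 B-spline regression with a third-derivative roughness
#' penalty. With `smoothing = NULL` the penalty weight is chosen by
#' generalized cross-validation (GCV); with `smoothing = 0` the spline
#' interpolates the data exactly; a positive value fixes the (scale-free)
#' penalty weight. Because the penalty annihilates cubics, polynomials up to
#' degree 3 are reproduced exactly at any smoothing level.
#'
#' @param series a `kinematic_series` from [compute_variable()], or a numeric
#'   vector of values (then supply `time`).
#' @param smoothing `NULL` (GCV), `0` (interpolate), or a positive scalar.
#' @param time sample times, required when `series` is a bare numeric vector.
#' @return A `quintic_spline` object; evaluate with `predict(fit, t)`.
#'   Fields include the selected `lambda` and effective degrees of freedom
#'   `edf`.
#' @export
fit_quintic_spline <- function(series, smoothing = NULL, time = NULL) {
  if (inherits(series, "kinematic_series")) {
    y <- series$values
    t <- series$time
  } else {
    y <- as.numeric(series)
    t <- time
    if (is.null(t)) gk_stop("gk_usage_error", "supply `time` with a numeric series")
  }
  n <- length(y)
  if (n < 8) {
    gk_stop("gk_insufficient_data_error", sprintf(
      "need at least 8 frames for a quintic smoothing fit, got %d", n))
  }
  if (any(!is.finite(y)) || any(!is.finite(t))) {
    gk_stop("gk_data_error", "non-finite values in series or time")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    gk_stop("gk_data_error", "time must be strictly increasing")
  }
  knots <- quintic_knots(t)
  B <- splines::splineDesign(knots, t, ord = 6L)

  if (!is.null(smoothing) && smoothing == 0) {
    coef <- solve(B, y)
    lambda <- 0
    edf <- n
  } else {
    Omega <- third_derivative_penalty(knots)
    # scale-free parameterization: lambda multiplies Omega scaled to BtB
    scl <- sum(B^2) / max(sum(diag(Omega)), .Machine$double.eps)
    # penalty square root (Omega is PSD with a 4-dim cubic null space), so the
    # penalized fit solves a single well-conditioned augmented least squares
    eg <- eigen(Omega, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    L <- sqrt(eg$values[pos]) * t(eg$vectors[, pos, drop = FALSE])
    fit_at <- function(lambda) {
      Xa <- rbind(B, sqrt(lambda * scl) * L)
      qrX <- tryCatch(qr(Xa), error = function(e) NULL)
      if (is.null(qrX) || qrX$rank < ncol(Xa)) return(NULL)
      coef <- qr.coef(qrX, c(y, rep(0, nrow(L))))
      Rm <- qr.R(qrX)
      piv <- qrX$pivot
      Z <- backsolve(Rm, t(B[, piv, drop = FALSE]), transpose = TRUE)
      resid <- y - as.numeric(B %*% coef)
      list(coef = coef, edf = sum(Z^2), rss = sum(resid^2))
    }
    gcv <- function(log10l) {
      f <- fit_at(10^log10l)
      if (is.null(f) || (n - f$edf) < 1e-8) return(Inf)
      n * f$rss / (n - f$edf)^2
    }
    if (is.null(smoothing)) {
      opt <- stats::optimize(gcv, interval = c(-10, 8), tol = 1e-3)
      lambda <- 10^opt$minimum
    } else {
      if (!is.finite(smoothing) || smoothing < 0) {
        gk_stop("gk_usage_error", "smoothing must be NULL or a nonnegative scalar")
      }
      lambda <- smoothing
    }
    f <- fit_at(lambda)
    if (is.null(f)) gk_stop("gk_data_error", "singular spline system")
    coef <- f$coef
    edf <- f$edf
  }
  structure(
    list(knots = knots, coef = as.numeric(coef), range = range(t),
         lambda = lambda, edf = edf, n = n),
    class = "quintic_spline"
  )
}

#' Evaluate a fitted quintic spline
#'
#' @param object a `quintic_spline`.
#' @param newdata evaluation times; must lie within the fitted span.
#' @param ... unused.
#' @return Numeric vector of spline values.
#' @export
predict.quintic_spline <- function(object, newdata, ...) {
  t <- as.numeric(newdata)
  tol <- 1e-8 * max(1, diff(object$range))
  if (any(t < object$range[1] - tol) || any(t > object$range[2] + tol)) {
    gk_stop("gk_range_error", "evaluation outside the fitted span")
  }
  t <- pmin(pmax(t, object$range[1]), object$range[2])
  as.numeric(splines::splineDesign(object$knots, t, ord = 6L) %*% object$coef)
}

#' @export
print.quintic_spline <- function(x, ...) {
  cat(sprintf("<quintic_spline> n = %d | span [%.4g, %.4g] s | lambda = %.3g | edf = %.1f\n",
              x$n, x$range[1], x$range[2], x$lambda, x$edf))
  invisible(x)
}

#' Resample a fitted spline to 101 percent-cycle increments
#'
#' Evaluates the spline at `t_start + k * (t_end - t_start) / 100` for
#' `k = 0, ..., 100`, normalizing cycles of any duration to a common
#' 101-point percent-cycle axis (both endpoints included).
#'
#' @param spline a `quintic_spline` (or any object with a `predict` method
#'   over time).
#' @param t_start,t_end cycle boundaries in seconds, within the fitted span.
#' @return Numeric vector of length 101.
#' @export
resample_to_percent_cycle <- function(spline, t_start, t_end) {
  if (!(t_start < t_end)) {
    gk_stop("gk_usage_error", "t_start must be < t_end")
  }
  predict(spline, seq(t_start, t_end, length.out = 101))
}

#' Aggregate per-cycle 101-point profiles into a mean profile
#'
#' Pointwise arithmetic mean and standard error of the mean (sample standard
#' deviation over the square root of the number of cycles) at each percent
#' increment.
#'
#' @param profiles list of numeric length-101 vectors, or a 101 x n matrix
#'   (one column per cycle).
#' @param variable,group optional labels stored on the result.
#' @return A `normalized_profile`: list with `mean` and `sem` (length 101),
#'   `n_cycles`, `percent` (0:100), `variable`, `group`.
#' @export
aggregate_profiles <- function(profiles, variable = NA_character_,
                               group = NA_character_) {
  if (is.list(profiles)) {
    if (length(profiles) == 0) gk_stop("gk_usage_error", "no profiles supplied")
    profiles <- do.call(cbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != 101) {
    gk_stop("gk_usage_error", sprintf(
      "profiles must have 101 rows (percent-cycle points), got %d", nrow(profiles)))
  }
  n <- ncol(profiles)
  if (n == 0) gk_stop("gk_usage_error", "no profiles supplied")
  mu <- rowMeans(profiles)
  sem <- if (n == 1) rep(0, 101) else apply(profiles, 1, stats::sd) / sqrt(n)
  structure(
    list(variable = variable, group = group, percent = 0:100,
         mean = as.numeric(mu), sem = as.numeric(sem), n_cycles = n),
    class = "normalized_profile"
  )
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> %s | %s | n = %d cycles | mean range [%.4g, %.4g]\n",
              x$variable, x$group, x$n_cycles, min(x$mean), max(x$mean)))
  invisible(x)
}

#' Smooth and resample every cycle of a kinematics table
#'
#' Runs the full per-cycle normalization: for each (trial, variable) trace a
#' quintic smoothing spline is fitted (GCV unless `smoothing` is given) and
#' resampled to 101 percent-cycle increments.
#'
#' @param kin long kinematics data.frame from [compute_all_variables()].
#' @param smoothing passed to [fit_quintic_spline()].
#' @return Long data.frame: `trial_id`, `behavior`, `species`,
#'   `individual_id`, `variable`, `units`, `percent` (0-100), `value`.
#'   Attribute `smoothing_log` records the GCV-selected lambda per fit.
#' @export
cycle_profiles <- function(kin, smoothing = NULL) {
  pieces <- split(kin, list(kin$trial_id, kin$variable), drop = TRUE)
  log_rows <- list()
  out <- lapply(pieces, function(d) {
    d <- d[order(d$frame_index), ]
    fit <- fit_quintic_spline(d$value, smoothing = smoothing, time = d$time_s)
    prof <- resample_to_percent_cycle(fit, d$time_s[1], d$time_s[nrow(d)])
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      trial_id = d$trial_id[1], variable = d$variable[1], lambda = fit$lambda,
      edf = fit$edf)
    data.frame(
      trial_id = d$trial_id[1], behavior = d$behavior[1], species = d$species[1],
      individual_id = d$individual_id[1], variable = d$variable[1],
      units = d$units[1], percent = 0:100, value = prof
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "smoothing_log") <- do.call(rbind, log_rows)
  res
}

#' Aggregate cycle profiles into group mean profiles
#'
#' @param cp output of [cycle_profiles()].
#' @param group_by metadata columns defining groups (default `"behavior"`;
#'   use `c("species", "behavior")` for interspecific layouts).
#' @return Long data.frame: `group`, `variable`, `units`, `percent`, `mean`,
#'   `sem`, `n_cycles`.
#' @export
group_profiles <- function(cp, group_by = "behavior") {
  cp$group <- interaction(cp[group_by], drop = TRUE, sep = ":")
  pieces <- split(cp, list(cp$group, cp$variable), drop = TRUE)
  out <- lapply(pieces, function(d) {
    m <- matrix(d$value, nrow = 101)
    ag <- aggregate_profiles(m, variable = d$variable[1],
                             group = as.character(d$group[1]))
    data.frame(
      group = ag$group, variable = ag$variable, units = d$units[1],
      percent = ag$percent, mean = ag$mean, sem = ag$sem, n_cycles = ag$n_cycles
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Down-sample a group profile table to every 5% of the cycle
#'
#' Convenience layout for plots that mark every 5% increment of cycle
#' duration.
#'
#' @param gp output of [group_profiles()].
#' @return The subset of rows with `percent` a multiple of 5.
#' @export
profile_plot_table <- function(gp) {
  gp[gp$percent %% 5 == 0, , drop = FALSE]
}
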