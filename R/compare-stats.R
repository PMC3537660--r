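# Group comparisons: nonparametric tests on per-cycle peak values and
# divergence angles between 101-dimensional mean kinematic-profile vectors.

#' Peak value of a cycle profile
#'
#' @param profile numeric vector (canonically the 101 resampled values of one
#'   cycle).
#' @return The maximum value.
#' @export
peak_value <- function(profile) {
  if (length(profile) == 0) gk_stop("gk_usage_error", "empty profile")
  max(profile)
}

#' Mann-Whitney U test between two groups
#'
#' Rank-sum test with midranks for ties. The two-sided p-value is exact (full
#' enumeration of rank configurations) when `n_a + n_b <= 12` and there are
#' no ties; otherwise the normal approximation with tie-corrected variance
#' and continuity correction is used. `U` is the statistic for the first
#' sample (number of pairs where `a` exceeds `b`, counting ties as 1/2).
#'
#' @param a,b numeric samples, each of size >= 1.
#' @return List with `U`, `p_value`, `n` (per-group sizes), `exact`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) {
    gk_stop("gk_usage_error", "both groups must be non-empty")
  }
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(c(a, b))) == 1) {
    gk_warn("gk_degenerate_warning",
            "all values identical across both groups; p = 1")
    return(list(U = U, p_value = 1, n = c(m, n), exact = FALSE,
                method = "Mann-Whitney U (degenerate)"))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (m + n) <= 12 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p_value = ht$p.value, n = c(m, n),
       exact = exact,
       method = if (exact) "Mann-Whitney U (exact)"
                else "Mann-Whitney U (normal approximation, tie-corrected)")
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic from pooled midranks with tie correction; p-value
#' from the chi-square approximation with (number of groups - 1) degrees of
#' freedom.
#'
#' @param groups list of numeric samples (>= 2 non-empty groups).
#' @return List with `H`, `df`, `p_value`, `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, as.numeric)
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (length(groups) < 2) {
    gk_stop("gk_usage_error", "need at least 2 non-empty groups")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1) {
    gk_warn("gk_degenerate_warning", "all values identical across groups; H = 0, p = 1")
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                n = vapply(groups, length, 1L)))
  }
  ht <- stats::kruskal.test(x, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = vapply(groups, length, 1L))
}

#' Divergence angle between two mean kinematic-profile vectors
#'
#' Angle (degrees) between two profiles treated as vectors in R^101:
#' `acos(dot(u, v) / (|u| |v|))`, computed on the raw (uncentered, unscaled)
#' mean profiles and clamped against floating-point overshoot of the cosine
#' bound. An angle near 0 means nearly identical profile shapes; 90 means
#' uncorrelated trajectories. The angle is symmetric and invariant to
#' positive rescaling of either vector, so it measures shape rather than
#' amplitude.
#'
#' @param u,v numeric vectors of equal length (canonically 101 mean values),
#'   each with at least one nonzero entry.
#' @return Angle in degrees, in `[0, 180]` (`[0, 90]` for nonnegative
#'   profiles).
#' @export
divergence_angle <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v) || length(u) < 2) {
    gk_stop("gk_usage_error", "profiles must be equal-length vectors")
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    gk_stop("gk_degenerate_error",
            "zero-norm profile vector (variable with identically zero mean profile)")
  }
  # equivalent to acos of the normalized dot product, but computed from the
  # chord lengths of the unit vectors, which keeps full accuracy near 0 and
  # 180 degrees where acos loses precision
  un <- u / nu; vn <- v / nv
  2 * atan2(sqrt(sum((un - vn)^2)), sqrt(sum((un + vn)^2))) * 180 / pi
}

#' Summarize a set of divergence angles
#'
#' Mean and standard error of the mean across variables, plus counts of
#' variables whose profiles diverge by less than each threshold.
#'
#' @param angles numeric vector of divergence angles (degrees).
#' @param thresholds angle thresholds in degrees (default 5 and 10).
#' @return List with `mean`, `sem`, `n`, and `counts_below` (named by
#'   threshold).
#' @export
divergence_summary <- function(angles, thresholds = c(5, 10)) {
  angles <- as.numeric(angles)
  if (length(angles) == 0) gk_stop("gk_usage_error", "no angles supplied")
  n <- length(angles)
  list(
    mean = mean(angles),
    sem = if (n > 1) stats::sd(angles) / sqrt(n) else 0,
    n = n,
    counts_below = stats::setNames(
      vapply(thresholds, function(th) sum(angles < th), 1L),
      paste0("<", thresholds, "deg"))
  )
}

#' Percent excess of one group mean over another
#'
#' `100 * (a - b) / b`: by how many percent `a` exceeds the reference `b`.
#'
#' @param a,b numeric scalars (e.g. group mean maxima).
#' @return Percent excess.
#' @export
percent_excess <- function(a, b) {
  if (b == 0) gk_stop("gk_usage_error", "reference value must be nonzero")
  100 * (a - b) / b
}

#' Full comparison report: peak tests and profile divergence angles
#'
#' Builds the two comparison layers for a study. Per variable: (i) group mean
#' maximum with s.e.m. and cycle count, compared with a Mann-Whitney U test
#' for two groups or a Kruskal-Wallis test for more; (ii) the divergence
#' angle between the group mean profiles for every group pair; (iii) summary
#' lines per pair (mean +/- s.e.m. of angles across variables, counts under
#' the angle thresholds) and optional percent-excess lines for named
#' variable/group contrasts. Variables present in only some groups are
#' excluded from tests and summaries with a warning.
#'
#' @param peaks data.frame with columns `group`, `variable`, `peak` (one row
#'   per cycle), e.g. from [cycle_peaks()].
#' @param profiles group mean profiles from [group_profiles()].
#' @param thresholds divergence-angle thresholds (degrees) for summary counts.
#' @param excess optional list of lists `list(variable=, a=, b=)` requesting
#'   percent-excess of group `a`'s mean maximum over group `b`'s.
#' @return A `kin_comparison` list: `peak_table`, `divergence_table`,
#'   `summary_table`, `excess_table`.
#' @export
comparison_report <- function(peaks, profiles, thresholds = c(5, 10),
                              excess = NULL) {
  groups <- sort(unique(as.character(peaks$group)))
  vars_by_group <- tapply(peaks$variable, peaks$group,
                          function(v) unique(as.character(v)))
  common <- Reduce(intersect, vars_by_group)
  all_vars <- unique(as.character(peaks$variable))
  dropped <- setdiff(all_vars, common)
  if (length(dropped) > 0) {
    gk_warn("gk_grouping_warning", sprintf(
      "variable(s) %s present in only some groups; excluded from comparisons",
      paste(dropped, collapse = ", ")))
  }

  peak_rows <- list(); div_rows <- list()
  for (v in common) {
    samples <- lapply(groups, function(g) {
      peaks$peak[peaks$group == g & peaks$variable == v]
    })
    names(samples) <- groups
    test <- if (length(groups) == 2) {
      mw <- mann_whitney_u(samples[[1]], samples[[2]])
      list(name = "Mann-Whitney U", stat = mw$U, p = mw$p_value)
    } else {
      kw <- kruskal_wallis(samples)
      list(name = "Kruskal-Wallis H", stat = kw$H, p = kw$p_value)
    }
    for (g in groups) {
      s <- samples[[g]]
      peak_rows[[length(peak_rows) + 1]] <- data.frame(
        variable = v, group = g, mean_max = mean(s),
        sem_max = if (length(s) > 1) stats::sd(s) / sqrt(length(s)) else 0,
        n = length(s), test = test$name, statistic = test$stat, p_value = test$p
      )
    }
    prof_v <- profiles[profiles$variable == v, ]
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        u1 <- prof_v$mean[prof_v$group == groups[i]][order(prof_v$percent[prof_v$group == groups[i]])]
        u2 <- prof_v$mean[prof_v$group == groups[j]][order(prof_v$percent[prof_v$group == groups[j]])]
        div_rows[[length(div_rows) + 1]] <- data.frame(
          variable = v, group_a = groups[i], group_b = groups[j],
          angle_deg = divergence_angle(u1, u2)
        )
      }
    }
  }
  peak_table <- do.call(rbind, peak_rows)
  divergence_table <- do.call(rbind, div_rows)

  sum_rows <- list()
  pairs <- unique(divergence_table[, c("group_a", "group_b")])
  for (k in seq_len(nrow(pairs))) {
    ang <- divergence_table$angle_deg[
      divergence_table$group_a == pairs$group_a[k] &
        divergence_table$group_b == pairs$group_b[k]]
    ds <- divergence_summary(ang, thresholds)
    sum_rows[[k]] <- data.frame(
      group_a = pairs$group_a[k], group_b = pairs$group_b[k],
      mean_angle_deg = ds$mean, sem_angle_deg = ds$sem, n_variables = ds$n,
      t(ds$counts_below), check.names = FALSE
    )
  }
  summary_table <- do.call(rbind, sum_rows)

  excess_table <- NULL
  if (!is.null(excess)) {
    excess_table <- do.call(rbind, lapply(excess, function(e) {
      ma <- peak_table$mean_max[peak_table$variable == e$variable &
                                  peak_table$group == e$a]
      mb <- peak_table$mean_max[peak_table$variable == e$variable &
                                  peak_table$group == e$b]
      data.frame(variable = e$variable, group_a = e$a, group_b = e$b,
                 excess_pct = percent_excess(ma, mb))
    }))
  }

  structure(
    list(peak_table = peak_table, divergence_table = divergence_table,
         summary_table = summary_table, excess_table = excess_table),
    class = "kin_comparison"
  )
}

#' @export
print.kin_comparison <- function(x, ...) {
  cat("<kin_comparison>\n\nMean maxima and peak-value tests:\n")
  print(x$peak_table, digits = 4, row.names = FALSE)
  cat("\nProfile divergence angles (deg):\n")
  print(x$divergence_table, digits = 4, row.names = FALSE)
  cat("\nSummary:\n")
  print(x$summary_table, digits = 3, row.names = FALSE)
  if (!is.null(x$excess_table)) {
    cat("\nPercent excess of mean maxima:\n")
    print(x$excess_table, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Per-cycle peak values from resampled profiles
#'
#' Peaks are taken from the smoothed, resampled 101-point profile of each
#' cycle (maximum over the 101 values), the canonical choice; see
#' [raw_cycle_peaks()] for raw-frame maxima.
#'
#' @param cp output of [cycle_profiles()].
#' @param group_by metadata columns defining groups.
#' @return data.frame `trial_id`, `group`, `variable`, `peak`.
#' @export
cycle_peaks <- function(cp, group_by = "behavior") {
  cp$group <- interaction(cp[group_by], drop = TRUE, sep = ":")
  pieces <- split(cp, list(cp$trial_id, cp$variable), drop = TRUE)
  out <- lapply(pieces, function(d) {
    data.frame(trial_id = d$trial_id[1], group = as.character(d$group[1]),
               variable = d$variable[1], peak = peak_value(d$value))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cycle raw-frame peak values
#'
#' Sensitivity-check companion to [cycle_peaks()]: maxima of the unsmoothed
#' per-frame traces.
#'
#' @param kin output of [compute_all_variables()].
#' @param group_by metadata columns defining groups.
#' @return data.frame `trial_id`, `group`, `variable`, `peak`.
#' @export
raw_cycle_peaks <- function(kin, group_by = "behavior") {
  kin$group <- interaction(kin[group_by], drop = TRUE, sep = ":")
  pieces <- split(kin, list(kin$trial_id, kin$variable), drop = TRUE)
  out <- lapply(pieces, function(d) {
    data.frame(trial_id = d$trial_id[1], group = as.character(d$group[1]),
               variable = d$variable[1], peak = peak_value(d$value))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
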