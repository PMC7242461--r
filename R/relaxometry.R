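# Core quantification: log-linear relaxation mapping, echo-ratio decay
# statistics, the two-point R2* estimate and echo-subtraction images.

#' Log-linear relaxation map
#'
#' Per-voxel ordinary least squares of `ln S(TE)` on TE, using the echoes
#' whose signal exceeds `signal_floor`. At least two usable echoes are
#' required, otherwise the voxel is marked invalid; an image where no voxel
#' can be fitted yields an all-false validity mask, not an error (regions of
#' heavy blooming are simply not quantified). The rate is the negative
#' slope, reported in 1/s (echo times are converted from ms); negative
#' fitted rates are retained but visible in the diagnostics rather than
#' clipped, which would bias ROI means under noise.
#'
#' @param series A [simulate_series()] result (or an object with the same
#'   fields read from disk).
#' @param signal_floor Positive signal threshold below which an echo is
#'   excluded from the fit. Default: `3 * noise_sigma` when the series
#'   records a positive noise level, otherwise a tiny positive value that
#'   only excludes non-positive signals.
#' @return An object of class `relaxation_map` with per-voxel `rate` (1/s),
#'   `intercept` (log-signal at TE = 0), `r_squared`, `valid_mask`, plus
#'   `mode` and `echo_times_used_ms`.
#' @export
fit_loglinear <- function(series, signal_floor = NULL) {
  if (is.null(signal_floor)) {
    signal_floor <- if (series$noise_sigma > 0) 3 * series$noise_sigma else 1e-12
  }
  if (!is_scalar_number(signal_floor) || signal_floor <= 0) {
    abort_qmri("`signal_floor` must be a positive number", "uteqmri_bad_input")
  }
  d <- dim(series$data)
  n_echo <- d[3]
  if (n_echo < 2L) abort_qmri("need at least 2 echoes", "uteqmri_bad_input")
  te <- ms_to_s(series$echo_times_ms)
  if (length(te) != n_echo) {
    abort_qmri("echo-time list does not match the data's echo axis",
               "uteqmri_sidecar_mismatch")
  }

  nv <- d[1] * d[2]
  v <- matrix(series$data, nv, n_echo)
  use <- v > signal_floor
  n_used <- rowSums(use)

  rate <- matrix(NA_real_, d[1], d[2])
  intercept <- matrix(NA_real_, d[1], d[2])
  r_squared <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])

  # Voxels sharing an echo-inclusion pattern share the OLS design, so the
  # fit is done pattern-by-pattern in closed form (at most 2^n_echo groups).
  pattern <- as.integer(use %*% (2^(seq_len(n_echo) - 1L)))
  fit_idx <- which(n_used >= 2L)
  if (length(fit_idx) > 0L) {
    y_all <- suppressWarnings(log(v))
    for (p in unique(pattern[fit_idx])) {
      vox <- fit_idx[pattern[fit_idx] == p]
      echoes <- which(bitwAnd(p, 2^(seq_len(n_echo) - 1L)) > 0L)
      t_sub <- te[echoes]
      y <- y_all[vox, echoes, drop = FALSE]
      n <- length(t_sub)
      t_bar <- mean(t_sub)
      s_tt <- sum((t_sub - t_bar)^2)
      y_bar <- rowMeans(y)
      if (s_tt == 0) next  # degenerate design (cannot happen for distinct TEs)
      s_ty <- as.numeric(y %*% (t_sub - t_bar))
      slope <- s_ty / s_tt
      icept <- y_bar - slope * t_bar
      fitted_ss <- slope^2 * s_tt
      tot_ss <- rowSums((y - y_bar)^2)
      r2 <- ifelse(tot_ss > 0, fitted_ss / tot_ss, 1)
      rate[vox] <- -slope
      intercept[vox] <- icept
      r_squared[vox] <- pmin(pmax(r2, 0), 1)
      valid[vox] <- TRUE
    }
  }

  structure(list(
    rate = rate, intercept = intercept, r_squared = r_squared,
    valid_mask = valid, mode = series$protocol$mode,
    echo_times_used_ms = series$echo_times_ms,
    signal_floor = signal_floor
  ), class = "relaxation_map")
}

#' Echo-ratio decay statistic
#'
#' The fractional signal loss between two echoes of a UTE series:
#' `R12 = (S1 - S2)/S1`, `R15 = (S1 - S5)/S1`, `R25 = (S2 - S5)/S2`.
#' The ratio is 0 when no signal has been lost between the echoes and
#' approaches 1 at complete signal loss; it increases with the local
#' relaxation rate. Voxels with non-positive denominator are masked invalid.
#'
#' @param series A multi-echo series with at least 5 echoes for
#'   `R15`/`R25` (2 for `R12`).
#' @param kind One of `"R12"`, `"R15"`, `"R25"`.
#' @return An object of class `ratio_map` with `value`, `echo_pair`
#'   (1-based echo indices), `kind`, `valid_mask`.
#' @export
ratio_map <- function(series, kind) {
  pairs <- list(R12 = c(1L, 2L), R15 = c(1L, 5L), R25 = c(2L, 5L))
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(pairs)) {
    abort_qmri("`kind` must be one of 'R12', 'R15', 'R25'", "uteqmri_bad_ratio_kind")
  }
  pair <- pairs[[kind]]
  if (dim(series$data)[3] < max(pair)) {
    abort_qmri(sprintf("series has %d echoes; %s needs echo %d",
                       dim(series$data)[3], kind, max(pair)),
               "uteqmri_bad_input")
  }
  s_i <- series$data[, , pair[1]]
  s_j <- series$data[, , pair[2]]
  valid <- s_i > 0
  value <- matrix(NA_real_, nrow(s_i), ncol(s_i))
  value[valid] <- (s_i[valid] - s_j[valid]) / s_i[valid]
  structure(list(
    value = value, echo_pair = pair, kind = kind, valid_mask = valid,
    echo_times_used_ms = series$echo_times_ms[pair]
  ), class = "ratio_map")
}

#' Two-point R2* estimate from an echo ratio
#'
#' Inverts the mono-exponential decay model for a single echo pair:
#' `rate = -ln(1 - R) / (TE_j - TE_i)` with the echo-time difference in
#' seconds. For noiseless mono-exponential decay this equals the full
#' log-linear fit. Voxels with `R < 0` or `R >= 1` are masked invalid.
#'
#' @param ratio A [ratio_map()] result.
#' @param echo_times_ms Echo times of the parent series, ms (the ratio's
#'   stored echo pair selects the two entries used).
#' @return A `relaxation_map` (mode `"r2star"`) for the two-point estimate.
#' @export
two_point_r2star <- function(ratio, echo_times_ms) {
  if (!inherits(ratio, "ratio_map")) {
    abort_qmri("`ratio` must be a ratio_map", "uteqmri_bad_input")
  }
  pair <- ratio$echo_pair
  if (length(echo_times_ms) < max(pair)) {
    abort_qmri("echo-time list shorter than the ratio's echo pair",
               "uteqmri_bad_input")
  }
  dte_s <- ms_to_s(echo_times_ms[pair[2]] - echo_times_ms[pair[1]])
  if (dte_s == 0) {
    abort_qmri("degenerate echo pair: echo times are equal", "uteqmri_bad_input")
  }
  ok <- ratio$valid_mask & !is.na(ratio$value) & ratio$value >= 0 & ratio$value < 1
  rate <- matrix(NA_real_, nrow(ratio$value), ncol(ratio$value))
  rate[ok] <- -log(1 - ratio$value[ok]) / dte_s
  structure(list(
    rate = rate, intercept = matrix(NA_real_, nrow(rate), ncol(rate)),
    r_squared = matrix(NA_real_, nrow(rate), ncol(rate)),
    valid_mask = ok, mode = "r2star",
    echo_times_used_ms = echo_times_ms[pair],
    signal_floor = NA_real_
  ), class = "relaxation_map")
}

#' Echo-subtraction image
#'
#' `S(TE_i) - S(TE_j)` for `i < j`, unclipped (values may be negative under
#' noise). Fast-decaying tissue (bone, SPIO-laden regions) appears
#' hyperintense, slowly decaying tissue hypointense.
#'
#' @param series A multi-echo series.
#' @param i,j 1-based echo indices with `i < j`.
#' @return Matrix of signal differences.
#' @export
subtraction_image <- function(series, i, j) {
  n_echo <- dim(series$data)[3]
  if (!is_scalar_number(i) || !is_scalar_number(j) ||
      i < 1 || j > n_echo || i != round(i) || j != round(j)) {
    abort_qmri("echo indices out of range", "uteqmri_bad_input")
  }
  if (i >= j) abort_qmri("`i` must be less than `j`", "uteqmri_bad_input")
  series$data[, , i] - series$data[, , j]
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat(sprintf("<relaxation_map> mode %s, %d x %d voxels, %.1f%% valid, rate median %.3g 1/s\n",
              x$mode, nrow(x$rate), ncol(x$rate), 100 * mean(x$valid_mask),
              stats::median(x$rate[x$valid_mask])))
  invisible(x)
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf("<ratio_map> %s (echoes %d-%d), %d x %d voxels\n",
              x$kind, x$echo_pair[1], x$echo_pair[2], nrow(x$value), ncol(x$value)))
  invisible(x)
}
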