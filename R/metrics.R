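#' Resample a stance-phase vgrf segment onto a fixed number of points
#'
#' Linear interpolation onto `n` equally spaced points over the segment, so
#' steps of different durations can be averaged and compared on a common
#' %-of-stance axis. Endpoints are preserved exactly.
#'
#' @param values numeric vector (length >= 2), the vgrf samples of one
#'   stance phase (signed, negative under load).
#' @param n number of output points, default 100.
#' @return numeric vector of length `n`.
#' @export
resample_profile <- function(values, n = 100L) {
  if (length(values) < 2L) {
    stop("segment too short to resample (need >= 2 samples)", call. = FALSE)
  }
  stats::approx(seq(0, 1, length.out = length(values)), values,
                xout = seq(0, 1, length.out = n))$y
}

#' Pointwise mean and standard-deviation contour of step profiles
#'
#' @param profiles a list of equal-length numeric vectors, or a matrix with
#'   one profile per row.
#' @return list with `mean` and `sd` vectors (sample sd, 0 for a single
#'   profile).
#' @export
average_profiles <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else do.call(rbind, profiles)
  if (nrow(m) < 1L) stop("need at least one profile", call. = FALSE)
  list(mean = colMeans(m),
       sd = if (nrow(m) > 1) apply(m, 2L, stats::sd) else rep(0, ncol(m)))
}

#' Normalized root-mean-square error between two vgrf profiles
#'
#' `RMSE / (max(a) - min(a))`, with `a` the insole profile providing the
#' normalizing range. Scale-invariant: scaling both profiles by the same
#' factor leaves it unchanged.
#'
#' @param a insole profile (provides the normalization range).
#' @param b reference profile, same length.
#' @return nonnegative number.
#' @export
nrmse <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length", call. = FALSE)
  rng <- max(a) - min(a)
  if (rng <= 0) stop("insole profile has zero range", call. = FALSE)
  sqrt(mean((a - b)^2)) / rng
}

#' Pearson correlation between two profiles
#'
#' Thin wrapper over [stats::cor()] with the degenerate cases rejected
#' explicitly (constant inputs have no defined correlation).
#'
#' @param a,b equal-length numeric vectors (length >= 2), non-constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("need two equal-length profiles of length >= 2", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Mean absolute error between paired stance durations
#'
#' @param insole_durations,reference_durations paired numeric vectors of
#'   stance durations (s), equal length.
#' @return nonnegative number (s).
#' @export
mae_stance <- function(insole_durations, reference_durations) {
  if (length(insole_durations) != length(reference_durations)) {
    stop("duration lists must be paired (equal length)", call. = FALSE)
  }
  mean(abs(insole_durations - reference_durations))
}

#' Extract resampled stance-phase vgrf profiles for a set of steps
#'
#' For each step record, takes the vgrf samples between heel strike and toe
#' off and resamples them onto `n` points.
#'
#' @param biomech data.frame from [compute_vgrf_cop()].
#' @param steps step records from [extract_steps()].
#' @param n points per profile, default 100.
#' @return matrix, one row per step, `n` columns.
#' @export
step_profiles <- function(biomech, steps, n = 100L) {
  if (nrow(steps) == 0L) return(matrix(numeric(0), 0L, n))
  out <- matrix(NA_real_, nrow(steps), n)
  for (k in seq_len(nrow(steps))) {
    idx <- biomech$time_s >= steps$t_heel_strike[k] &
      biomech$time_s < steps$t_toe_off[k]
    out[k, ] <- resample_profile(biomech$vgrf_N[idx], n)
  }
  out
}
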