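#' Calibration model for one optoelectronic pressure cell
#'
#' The force-to-voltage behaviour of each silicone cell is described by a sum
#' of two exponentials, `F(v) = A1 * exp(c1 * v) + A2 * exp(c2 * v)`, applied
#' to the de-offset output voltage `v` (volts, <= 0 under load). Voltages above
#' the noise threshold `v0` map to zero force. With the sign pattern
#' `A1 > 0, c1 > 0, A2 < 0, c2 < 0` the curve is strictly increasing in `v`,
#' so compressive load always appears as a negative force.
#'
#' @param A1,c1,A2,c2 model coefficients; `A1`, `A2` in newtons, `c1`, `c2`
#'   in 1/V. Signs are enforced: `A1 > 0`, `c1 > 0`, `A2 < 0`, `c2 < 0`.
#' @param v0 noise-threshold voltage in volts (default -0.02); voltages above
#'   `v0` are treated as no load.
#' @return an object of class `calibration_model`.
#' @seealso [default_calibration()], [force_from_voltage()]
#' @export
calibration_model <- function(A1, c1, A2, c2, v0 = -0.02) {
  vals <- c(A1 = A1, c1 = c1, A2 = A2, c2 = c2, v0 = v0)
  if (!all(is.finite(vals))) {
    stop("calibration coefficients must be finite numbers", call. = FALSE)
  }
  if (!(A1 > 0 && c1 > 0 && A2 < 0 && c2 < 0)) {
    stop("calibration model requires A1 > 0, c1 > 0, A2 < 0, c2 < 0",
         call. = FALSE)
  }
  if (v0 >= 0) stop("noise threshold v0 must be negative", call. = FALSE)
  structure(list(A1 = A1, c1 = c1, A2 = A2, c2 = c2, v0 = v0),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> F(v) = %.4g*exp(%.4g v) %+.4g*exp(%.4g v), v0 = %g V\n",
    x$A1, x$c1, x$A2, x$c2, x$v0))
  invisible(x)
}

#' Aggregate calibration model shipped with the device firmware
#'
#' One shared voltage-to-force curve used for all 64 cells, obtained by
#' pooling the characterization data of every cell. Evaluated at the noise
#' threshold (-0.02 V) it yields a force of magnitude about 3.06 N, which is
#' the per-cell worst-case error introduced by the thresholding.
#'
#' @param v0 noise-threshold voltage in volts.
#' @return a [calibration_model()].
#' @export
default_calibration <- function(v0 = -0.02) {
  calibration_model(A1 = 21.386, c1 = 4.834, A2 = -22.30, c2 = -0.401, v0 = v0)
}

#' Convert a de-offset voltage to a per-cell force
#'
#' Applies the two-exponential transduction law. Voltages above the noise
#' threshold `v0` give exactly 0 N; at and below `v0` the force is
#' `A1 * exp(c1 v) + A2 * exp(c2 v)`, negative under compression. The mapping
#' has a jump of magnitude `|F(v0)|` at `v0` (about 3.06 N for the aggregate
#' model): this is the per-cell worst-case error of the noise threshold.
#'
#' @param v numeric vector of de-offset voltages (V).
#' @param model a [calibration_model()].
#' @return numeric vector of forces in newtons (<= 0).
#' @export
force_from_voltage <- function(v, model = default_calibration()) {
  stopifnot(inherits(model, "calibration_model"))
  if (length(v) == 0L) return(numeric(0))
  if (!all(is.finite(v))) {
    stop("voltages must be finite (got NA/NaN/Inf)", call. = FALSE)
  }
  f <- model$A1 * exp(model$c1 * v) + model$A2 * exp(model$c2 * v)
  f[v > model$v0] <- 0
  f
}

#' Force at the noise threshold
#'
#' `F(v0)`, the most negative force that can be silently zeroed by the
#' threshold rule; its magnitude bounds the per-cell thresholding error.
#'
#' @inheritParams force_from_voltage
#' @return force in newtons (negative).
#' @export
threshold_force <- function(model = default_calibration()) {
  model$A1 * exp(model$c1 * model$v0) + model$A2 * exp(model$c2 * model$v0)
}

#' Invert the transduction law: voltage producing a given force
#'
#' Numeric inverse of [force_from_voltage()] on its monotone branch
#' `v <= v0`. Only forces at least as compressive as the threshold force
#' `F(v0)` are representable; anything in `(F(v0), 0]` falls in the dead band
#' of the threshold and raises a domain error.
#'
#' Implementation: a monotone lookup grid provides the starting point and
#' vectorized Newton iterations polish it to a residual below 1e-9 N.
#'
#' @param force numeric vector of target forces (N, negative).
#' @param model a [calibration_model()].
#' @return numeric vector of voltages `v <= v0`.
#' @export
voltage_from_force <- function(force, model = default_calibration()) {
  stopifnot(inherits(model, "calibration_model"))
  if (length(force) == 0L) return(numeric(0))
  if (!all(is.finite(force))) {
    stop("forces must be finite", call. = FALSE)
  }
  f0 <- threshold_force(model)
  if (any(force > f0)) {
    stop(sprintf(
      "force outside representable range: need F <= F(v0) = %.4f N", f0),
      call. = FALSE)
  }
  # bracket: expand v_lo until every target is covered
  v_lo <- model$v0 - 1
  while (force_from_voltage(v_lo, model) > min(force) && v_lo > -60) {
    v_lo <- v_lo * 2 - model$v0
  }
  grid_v <- seq(v_lo, model$v0, length.out = 4096L)
  grid_f <- model$A1 * exp(model$c1 * grid_v) + model$A2 * exp(model$c2 * grid_v)
  v <- stats::approx(grid_f, grid_v, xout = force, rule = 2)$y
  for (i in 1:6) {
    fv <- model$A1 * exp(model$c1 * v) + model$A2 * exp(model$c2 * v)
    dfv <- model$A1 * model$c1 * exp(model$c1 * v) +
      model$A2 * model$c2 * exp(model$c2 * v)
    v <- v - (fv - force) / dfv
  }
  pmin(v, model$v0)
}

#' Fit the two-exponential calibration curve to characterization data
#'
#' Nonlinear least squares of `F = A1 exp(c1 v) + A2 exp(c2 v)` on
#' (voltage, force) pairs from a quasi-static indentation of one cell.
#' Initialization is a deterministic multi-start: a coarse grid over
#' `(c1, c2)` with linear least squares for `(A1, A2)` at each node, the best
#' starts then refined by Levenberg-Marquardt with box constraints enforcing
#' `A1 > 0 > A2` and `c1 > 0 > c2` (this removes the A1/A2 swap degeneracy).
#'
#' @param voltage,force numeric vectors (V, N), at least 8 paired samples
#'   spanning a nonzero voltage range.
#' @param v0 noise threshold stored in the fitted model (V).
#' @param f_fsr per-cell full-scale force in newtons used for the
#'   %-of-full-scale conversion; 50 N = 500 kPa over 1 cm^2.
#' @return a `fit_report`: list with `model` ([calibration_model()]),
#'   `rmse_N`, `r2`, `rmse_pct_fsr`, `n`, `converged`.
#' @export
fit_calibration <- function(voltage, force, v0 = -0.02, f_fsr = 50) {
  v <- as.numeric(voltage); f <- as.numeric(force)
  if (length(v) != length(f)) stop("voltage and force lengths differ", call. = FALSE)
  ok <- is.finite(v) & is.finite(f)
  v <- v[ok]; f <- f[ok]
  if (length(v) < 8L) stop("need at least 8 valid samples", call. = FALSE)
  if (diff(range(v)) <= 0) {
    stop("degenerate input: voltages span a zero range", call. = FALSE)
  }

  # deterministic multi-start: coarse (c1, c2) grid, linear LS for (A1, A2)
  starts <- expand.grid(c1 = seq(0.5, 12, length.out = 12),
                        c2 = seq(-1.6, -0.05, length.out = 10))
  sse0 <- rep(Inf, nrow(starts))
  ab <- matrix(NA_real_, nrow(starts), 2)
  for (k in seq_len(nrow(starts))) {
    X <- cbind(exp(starts$c1[k] * v), exp(starts$c2[k] * v))
    co <- tryCatch(stats::lm.fit(X, f)$coefficients, error = function(e) NULL)
    if (is.null(co) || anyNA(co)) next
    # keep only sign-consistent starts
    if (!(co[1] > 0 && co[2] < 0)) next
    ab[k, ] <- co
    sse0[k] <- sum((X %*% co - f)^2)
  }
  ord <- order(sse0)[1:5]
  best <- NULL
  for (k in ord) {
    if (!is.finite(sse0[k])) next
    st <- list(A1 = ab[k, 1], c1 = starts$c1[k], A2 = ab[k, 2], c2 = starts$c2[k])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ A1 * exp(c1 * v) + A2 * exp(c2 * v),
        start = st,
        lower = c(A1 = 1e-8, c1 = 1e-8, A2 = -Inf, c2 = -Inf),
        upper = c(A1 = Inf, c1 = Inf, A2 = -1e-8, c2 = -1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop("calibration fit did not converge from any start; ",
         "check that the data follow a two-exponential force-voltage curve",
         call. = FALSE)
  }
  co <- stats::coef(best$fit)
  rmse <- sqrt(best$sse / length(f))
  sst <- sum((f - mean(f))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  structure(list(
    model = calibration_model(co[["A1"]], co[["c1"]], co[["A2"]], co[["c2"]], v0),
    rmse_N = rmse,
    r2 = r2,
    rmse_pct_fsr = 100 * rmse / f_fsr,
    n = length(f),
    converged = TRUE
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report>\n")
  print(x$model)
  cat(sprintf("  RMSE %.4g N (%.4g%% of f.s.r.), R^2 %.4g, n = %d\n",
              x$rmse_N, x$rmse_pct_fsr, x$r2, x$n))
  invisible(x)
}

#' Fit one aggregate calibration model to the pooled data of all cells
#'
#' The cells are cast from a single silicone mold, so their curves differ only
#' within a narrow band; a single shared model fitted to the pooled samples of
#' every cell is what the device firmware uses. Pooling (rather than averaging
#' per-cell coefficients) is the correct reading of an "aggregate" curve: its
#' residual necessarily exceeds the per-cell residuals when cells differ.
#'
#' @param per_cell_samples either a data.frame with columns
#'   `cell_id, voltage_V, force_N`, or a list of per-cell data.frames with
#'   columns `voltage_V, force_N`.
#' @inheritParams fit_calibration
#' @return a `fit_report` for the pooled fit.
#' @export
aggregate_calibration <- function(per_cell_samples, v0 = -0.02, f_fsr = 50) {
  if (is.data.frame(per_cell_samples)) {
    df <- per_cell_samples
  } else {
    df <- do.call(rbind, lapply(per_cell_samples, function(d) {
      data.frame(voltage_V = d$voltage_V, force_N = d$force_N)
    }))
  }
  stopifnot(all(c("voltage_V", "force_N") %in% names(df)))
  fit_calibration(df$voltage_V, df$force_N, v0 = v0, f_fsr = f_fsr)
}

#' Summarize a set of per-cell calibration fits
#'
#' Mean and sample standard deviation (n-1 denominator) of every model
#' coefficient and of the fit-goodness figures across cells, in the shape of
#' a per-cell characterization table.
#'
#' @param reports list of `fit_report` objects (one per cell).
#' @return data.frame with columns `parameter`, `mean`, `sd`.
#' @export
summarize_models <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "fit_report")))
  pull <- function(fn) vapply(reports, fn, numeric(1))
  cols <- list(
    A1 = pull(function(r) r$model$A1),
    c1 = pull(function(r) r$model$c1),
    A2 = pull(function(r) r$model$A2),
    c2 = pull(function(r) r$model$c2),
    rmse_N = pull(function(r) r$rmse_N),
    r2 = pull(function(r) r$r2),
    rmse_pct_fsr = pull(function(r) r$rmse_pct_fsr))
  data.frame(
    parameter = names(cols),
    mean = vapply(cols, mean, numeric(1)),
    sd = vapply(cols, function(x) if (length(x) > 1) stats::sd(x) else 0,
                numeric(1)),
    row.names = NULL)
}
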