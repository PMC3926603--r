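#' Define a synthetic walking scenario
#'
#' Parameter set for the gait simulator. Defaults reproduce steady, slow
#' ground-level walking of a 75 kg adult: stance 0.80 s, swing 0.45 s
#' (cadence 0.8 Hz), symmetric double support, and a physiological
#' double-peak vertical ground reaction force with the weight-acceptance
#' peak at 20% and the push-off peak at 75% of stance. Channel offsets sit
#' near the photodiode resting voltage (about 1.3 V) and sensor noise
#' (0.005 V) is kept at a 4-sigma margin from the -0.02 V threshold so that
#' unloaded cells do not chatter.
#'
#' @param n_steps steps per foot (intervals between successive heel strikes).
#' @param dt_stance,dt_swing stance and swing durations (s).
#' @param ds_fraction double-support duration as a fraction of the stride.
#'   `NULL` (default) gives the symmetric value
#'   `(dt_stance - dt_swing) / (2 * stride)`; feasible values lie in
#'   `[0, (dt_stance - dt_swing) / stride]`.
#' @param subject_weight_kg body mass; sets default force magnitudes.
#' @param peak1_N,peak2_N,valley_N magnitudes (N, positive) of the
#'   weight-acceptance peak, push-off peak and mid-stance valley; defaults
#'   1.15, 1.10 and 0.75 x body weight.
#' @param peak1_frac,peak2_frac,valley_frac their positions as fractions of
#'   stance time (defaults 0.20, 0.75, 0.475).
#' @param noise_sd_V Gaussian sensor noise sd (V).
#' @param offset_V mean per-channel static offset (V).
#' @param footprint_mm Gaussian footprint radius of the load distribution
#'   (mm); 30 mm loads roughly 5-15 cells at a time.
#' @param fs_hz raw sampling rate (Hz), default 1200.
#' @param seed RNG seed for offsets and noise.
#' @return an object of class `gait_scenario`.
#' @export
gait_scenario <- function(n_steps = 12L, dt_stance = 0.80, dt_swing = 0.45,
                          ds_fraction = NULL, subject_weight_kg = 75,
                          peak1_N = NULL, peak2_N = NULL, valley_N = NULL,
                          peak1_frac = 0.20, peak2_frac = 0.75,
                          valley_frac = 0.475,
                          noise_sd_V = 0.005, offset_V = 1.3,
                          footprint_mm = 30, fs_hz = 1200, seed = 1L) {
  if (!(dt_stance > 0 && dt_swing > 0)) {
    stop("stance and swing durations must be positive", call. = FALSE)
  }
  stride <- dt_stance + dt_swing
  if (is.null(ds_fraction)) ds_fraction <- (dt_stance - dt_swing) / (2 * stride)
  ds_dur <- ds_fraction * stride
  if (ds_fraction < 0 || ds_dur > dt_stance - dt_swing + 1e-12) {
    stop(sprintf(
      "infeasible double support: ds_fraction must lie in [0, %.4f] for this stance/swing",
      (dt_stance - dt_swing) / stride), call. = FALSE)
  }
  bw <- subject_weight_kg * 9.81
  if (is.null(peak1_N)) peak1_N <- 1.15 * bw
  if (is.null(peak2_N)) peak2_N <- 1.10 * bw
  if (is.null(valley_N)) valley_N <- 0.75 * bw
  if (!(peak1_N >= valley_N && peak2_N >= valley_N && valley_N >= 0)) {
    stop("need peak1_N, peak2_N >= valley_N >= 0", call. = FALSE)
  }
  if (!(0 < peak1_frac && peak1_frac < valley_frac &&
        valley_frac < peak2_frac && peak2_frac < 1)) {
    stop("need 0 < peak1_frac < valley_frac < peak2_frac < 1", call. = FALSE)
  }
  structure(list(
    n_steps = as.integer(n_steps), dt_stance = dt_stance, dt_swing = dt_swing,
    stride = stride, ds_fraction = ds_fraction, ds_dur = ds_dur,
    subject_weight_kg = subject_weight_kg,
    peak1_N = peak1_N, peak2_N = peak2_N, valley_N = valley_N,
    peak1_frac = peak1_frac, peak2_frac = peak2_frac,
    valley_frac = valley_frac,
    noise_sd_V = as.numeric(noise_sd_V), offset_V = as.numeric(offset_V),
    footprint_mm = as.numeric(footprint_mm), fs_hz = as.numeric(fs_hz),
    seed = as.integer(seed)),
    class = "gait_scenario")
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf(
    "<gait_scenario> %d steps/foot, stance %.2f s, swing %.2f s, DS %.3f s, cadence %.2f Hz\n",
    x$n_steps, x$dt_stance, x$dt_swing, x$ds_dur, 1 / x$stride))
  invisible(x)
}

#' Double-peak vgrf magnitude over one stance
#'
#' Piecewise raised-cosine curve through the control points
#' (0, 0) -> (peak1_frac, peak1) -> (valley_frac, valley) ->
#' (peak2_frac, peak2) -> (1, 0): C1-smooth, zero at both stance boundaries,
#' with exactly two local maxima at the peak fractions (one plateau in the
#' degenerate peak = valley case).
#'
#' @param scenario a [gait_scenario()].
#' @param s fractions of stance time in \[0, 1\] (vector).
#' @param step_index unused placeholder (all steps share the template).
#' @return vgrf magnitudes (N, >= 0) at `s`.
#' @export
simulate_vgrf_profile <- function(scenario, s, step_index = 1L) {
  knots <- c(0, scenario$peak1_frac, scenario$valley_frac,
             scenario$peak2_frac, 1)
  vals <- c(0, scenario$peak1_N, scenario$valley_N, scenario$peak2_N, 0)
  s <- pmin(pmax(s, 0), 1)
  k <- findInterval(s, knots, rightmost.closed = TRUE)
  u <- (s - knots[k]) / (knots[k + 1L] - knots[k])
  vals[k] + (vals[k + 1L] - vals[k]) * (1 - cos(pi * u)) / 2
}

#' Centre-of-pressure trajectory over one stance
#'
#' `cop_y` decreases monotonically from about 240 mm at heel strike to about
#' 20 mm at toe off (heel to toe), crossing the 125 mm ST1/ST2 boundary
#' exactly once; `cop_x` follows the foot centreline (a small bounded
#' medial-lateral excursion).
#'
#' @inheritParams simulate_vgrf_profile
#' @return list with vectors `x` and `y` (mm) at `s`.
#' @export
simulate_cop_trajectory <- function(scenario, s, step_index = 1L) {
  s <- pmin(pmax(s, 0), 1)
  y <- 240 - 220 * (1 - cos(pi * s)) / 2
  # foot centreline: heel ~40, arch ~50, forefoot ~45, toe ~40
  cl_y <- c(15, 65, 75, 125, 135, 195, 205, 245)
  cl_x <- c(40, 40, 45, 45, 50, 50, 45, 40)
  x <- stats::approx(cl_y, cl_x, xout = y, rule = 2)$y
  list(x = x, y = y)
}

#' Stance fraction at which the simulated CoP crosses the ST1/ST2 boundary
#'
#' Root of `cop_y(s) = copy_threshold_mm` for the trajectory of
#' [simulate_cop_trajectory()]; defines the true ST1 -> ST2 transition.
#'
#' @inheritParams simulate_vgrf_profile
#' @param copy_threshold_mm boundary (mm), default 125.
#' @return fraction of stance in (0, 1).
#' @export
st1_boundary_fraction <- function(scenario, copy_threshold_mm = 125) {
  acos(1 - 2 * (240 - copy_threshold_mm) / 220) / pi
}

# point-in-convex-hull test (boundary counts as inside)
point_in_hull <- function(px, py, x, y, tol = 1e-9) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(h)
  cr <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, numeric(1))
  all(cr <= tol) || all(cr >= -tol)
}

#' Distribute a total vertical force over the cells around the CoP
#'
#' Inverse of the vgrf/CoP computation: spreads `vgrf` as non-positive
#' per-cell forces with a Gaussian footprint centred near the CoP, confined
#' to cells within `footprint_mm` of the CoP, then shifts the Gaussian
#' centre (Newton iterations on the 2-D centroid map) until the
#' force-weighted centroid matches the requested CoP to 1e-6 mm. The forces
#' sum exactly to `vgrf`.
#'
#' @param vgrf_N total vertical force (N, <= 0); 0 gives all-zero forces.
#' @param cop length-2 vector `c(x_mm, y_mm)`; must lie inside the convex
#'   hull of the layout when `vgrf_N != 0`.
#' @param layout sensor layout.
#' @param footprint_mm Gaussian radius and support cutoff (mm).
#' @return numeric vector of 64 per-cell forces (N, <= 0).
#' @export
distribute_pressure <- function(vgrf_N, cop, layout = default_layout(),
                                footprint_mm = 30) {
  validate_layout(layout)
  ord <- order(layout$cell_id)
  x <- layout$x_mm[ord]; y <- layout$y_mm[ord]
  if (vgrf_N == 0) return(numeric(64L))
  if (vgrf_N > 0) stop("vgrf must be <= 0 (compression)", call. = FALSE)
  if (!point_in_hull(cop[1], cop[2], x, y)) {
    stop("CoP lies outside the sensed area", call. = FALSE)
  }
  r <- footprint_mm
  sup_r <- footprint_mm
  for (attempt in 1:6) {
    d2cop <- (x - cop[1])^2 + (y - cop[2])^2
    sup <- which(d2cop <= sup_r^2 + 1e-9)
    if (length(sup) > 0L) {
      w_of <- function(c0) {
        exp(-((x[sup] - c0[1])^2 + (y[sup] - c0[2])^2) / (2 * r^2))
      }
      mu_of <- function(c0) {
        w <- w_of(c0)
        c(sum(w * x[sup]), sum(w * y[sup])) / sum(w)
      }
      c0 <- cop
      ok <- FALSE
      for (it in 1:80) {
        err <- cop - mu_of(c0)
        if (max(abs(err)) < 1e-10) { ok <- TRUE; break }
        dlt <- 1e-4
        J <- cbind((mu_of(c0 + c(dlt, 0)) - mu_of(c0 - c(dlt, 0))) / (2 * dlt),
                   (mu_of(c0 + c(0, dlt)) - mu_of(c0 - c(0, dlt))) / (2 * dlt))
        sv <- svd(J)
        inv_d <- ifelse(sv$d > 1e-12 * max(sv$d, 1e-300), 1 / sv$d, 0)
        step <- sv$v %*% (inv_d * crossprod(sv$u, err))
        nrm <- sqrt(sum(step^2))
        if (nrm > 50) step <- step * (50 / nrm)
        c0 <- c0 + as.numeric(step)
      }
      if (ok) {
        # solvable only if the residual along degenerate directions vanished
        err <- cop - mu_of(c0)
        if (max(abs(err)) < 1e-7) {
          f <- numeric(64L)
          w <- w_of(c0)
          f[sup] <- vgrf_N * w / sum(w)
          return(f)
        }
      }
    }
    sup_r <- sup_r + 10
  }
  stop("could not match the requested CoP with the available cells",
       call. = FALSE)
}

#' Convert per-cell forces back to raw voltages
#'
#' Inverse of the transduction stage used by the simulator: forces at or
#' beyond the threshold force are inverted through
#' [voltage_from_force()]; forces of smaller magnitude fall in the dead band
#' of the -0.02 V rule and are mapped to the threshold voltage `v0`;
#' unloaded cells give 0 V. A per-channel static offset and Gaussian noise
#' are then added.
#'
#' @param forces numeric vector of 64 per-cell forces (N, <= 0).
#' @param model a [calibration_model()].
#' @param noise_sd_V Gaussian noise sd (V), default 0.
#' @param offset_V per-channel offsets: scalar or length-64 vector (V).
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return numeric vector of 64 raw voltages.
#' @export
forces_to_voltages <- function(forces, model = default_calibration(),
                               noise_sd_V = 0, offset_V = 0, seed = NULL) {
  if (length(forces) != 64L) stop("need 64 per-cell forces", call. = FALSE)
  if (any(forces > 0)) {
    stop("positive (tensile) forces are not representable", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fthr <- threshold_force(model)
  v <- numeric(64L)
  dead <- forces < 0 & forces > fthr
  v[dead] <- model$v0
  deep <- forces <= fthr
  if (any(deep)) v[deep] <- voltage_from_force(forces[deep], model)
  v + offset_V + if (noise_sd_V > 0) stats::rnorm(64L, 0, noise_sd_V) else 0
}

#' Draw per-cell calibration models with realistic coefficient spread
#'
#' Cells cast from one mold differ within a narrow band; this draws
#' two-exponential coefficients from normal distributions matching the
#' per-cell characterization spread (means 19.366, 6.745, -20.458, -0.596;
#' sds 5.526, 3.704, 5.569, 0.214), truncated to keep the required sign
#' pattern.
#'
#' @param n number of cells, default 64.
#' @param seed RNG seed (`NULL` uses current RNG state).
#' @return list of `n` [calibration_model()] objects.
#' @export
sample_cell_models <- function(n = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out <= lo | out >= hi)
    while (length(bad)) {
      out[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(out <= lo | out >= hi)
    }
    out
  }
  A1 <- rtnorm(n, 19.366, 5.526, lo = 1)
  c1 <- rtnorm(n, 6.745, 3.704, lo = 0.5)
  A2 <- rtnorm(n, -20.458, 5.569, hi = -1)
  c2 <- rtnorm(n, -0.596, 0.214, hi = -0.05)
  lapply(seq_len(n), function(i) calibration_model(A1[i], c1[i], A2[i], c2[i]))
}

#' Simulate a full walking trial as raw bilateral voltage streams
#'
#' Builds an alternating left/right gait at 1200 Hz with the scenario's
#' stance, swing and double-support timing, synthesises per-cell forces from
#' the double-peak vgrf template and the heel-to-toe CoP trajectory, inverts
#' the transduction law, and adds per-channel offsets plus sensor noise.
#' The streams start with 1 s of unloaded baseline (for de-offsetting) and a
#' ground-truth sidecar records every event time, per-step parameter and the
#' true per-sample vgrf/CoP.
#'
#' With a right-foot offset of `dt_stance - ds` after each left heel strike,
#' periodic gait fixes the two double supports at `DS_R = ds` and
#' `DS_L = dt_stance - dt_swing - ds`; the symmetric default
#' `ds = (dt_stance - dt_swing)/2` makes them equal.
#'
#' @param scenario a [gait_scenario()].
#' @param layout sensor layout.
#' @param model [calibration_model()] used to invert forces to voltages.
#' @return list of class `gait_trial`: `left`, `right`
#'   ([voltage_stream()]s at `fs_hz`) and `truth` (events, steps, double
#'   supports, per-sample biomechanics, scenario).
#' @export
generate_trial <- function(scenario, layout = default_layout(),
                           model = default_calibration()) {
  stopifnot(inherits(scenario, "gait_scenario"))
  set.seed(scenario$seed)
  fs <- scenario$fs_hz
  st <- scenario$dt_stance
  stride <- scenario$stride
  off <- st - scenario$ds_dur          # right HS delay after left HS
  t_lead <- 1.0
  n_hs <- scenario$n_steps + 1L        # heel strikes per foot
  hs_left <- t_lead + stride * (seq_len(n_hs) - 1L)
  hs_right <- hs_left + off
  t_end <- hs_right[n_hs] + st + 1.0
  n <- ceiling(t_end * fs)
  tt <- (seq_len(n) - 1L) / fs

  # one stance template (identical for every step of either foot)
  ns <- floor(st * fs) + 1L
  s <- ((seq_len(ns) - 1L) / fs) / st
  mag <- simulate_vgrf_profile(scenario, s)
  cop <- simulate_cop_trajectory(scenario, s)
  tmpl_f <- matrix(0, ns, 64L)
  for (j in seq_len(ns)) {
    if (mag[j] > 0) {
      tmpl_f[j, ] <- distribute_pressure(-mag[j], c(cop$x[j], cop$y[j]),
                                         layout, scenario$footprint_mm)
    }
  }
  tmpl_v <- matrix(0, ns, 64L)
  for (j in seq_len(ns)) {
    tmpl_v[j, ] <- forces_to_voltages(tmpl_f[j, ], model)
  }

  build_side <- function(hs_times) {
    ch <- matrix(0, n, 64L)
    true_vgrf <- numeric(n)
    true_x <- rep(NaN, n); true_y <- rep(NaN, n)
    for (h in hs_times) {
      i0 <- round(h * fs) + 1L
      idx <- i0:(i0 + ns - 1L)
      ch[idx, ] <- tmpl_v
      true_vgrf[idx] <- -mag
      true_x[idx] <- cop$x; true_y[idx] <- cop$y
    }
    offs <- scenario$offset_V + stats::rnorm(64L, 0, 0.05)
    noise <- if (scenario$noise_sd_V > 0) {
      matrix(stats::rnorm(n * 64L, 0, scenario$noise_sd_V), n, 64L)
    } else 0
    list(stream = voltage_stream(sweep(ch, 2L, offs, `+`) + noise,
                                 fs_hz = fs, t0 = 0),
         truth = data.frame(time_s = tt, vgrf_N = true_vgrf,
                            cop_x_mm = true_x, cop_y_mm = true_y))
  }
  left <- build_side(hs_left)
  right <- build_side(hs_right)

  events_of <- function(hs) {
    data.frame(
      event = rep(c("heel_strike", "toe_off"), each = length(hs)),
      time_s = c(hs, hs + st))[order(c(hs, hs + st)), ]
  }
  steps_of <- function(hs, side) {
    k <- seq_len(length(hs) - 1L)
    data.frame(side = side, t_heel_strike = hs[k], t_toe_off = hs[k] + st,
               t_next_heel_strike = hs[k + 1L],
               dt_stance = st, dt_swing = stride - st,
               stance_pct = 100 * st / stride,
               swing_pct = 100 * (stride - st) / stride,
               cadence_hz = 1 / stride)
  }
  ds_l <- st - scenario$dt_swing - scenario$ds_dur
  truth <- list(
    left_events = events_of(hs_left),
    right_events = events_of(hs_right),
    left_steps = steps_of(hs_left, "left"),
    right_steps = steps_of(hs_right, "right"),
    ds = rbind(
      if (scenario$ds_dur > 0) {
        data.frame(kind = "DS_R", t_start = hs_right[seq_len(n_hs)],
                   dt_s = scenario$ds_dur)
      },
      if (ds_l > 0) {
        data.frame(kind = "DS_L", t_start = hs_left[-1L],
                   dt_s = ds_l)
      }),
    st1_fraction = st1_boundary_fraction(scenario),
    biomech_left = left$truth,
    biomech_right = right$truth,
    scenario = scenario)
  structure(list(left = left$stream, right = right$stream, truth = truth),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %d steps/foot, %d raw samples @ %g Hz per foot\n",
              x$truth$scenario$n_steps, nrow(x$left$channels), x$left$fs_hz))
  invisible(x)
}
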