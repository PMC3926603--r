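#' Per-cell forces from one or more voltage frames
#'
#' Applies [force_from_voltage()] cell by cell. The shipped default is a
#' single shared (aggregate) model, matching the device firmware; a list of
#' 64 per-cell models is also accepted, which trades firmware simplicity for
#' per-cell accuracy.
#'
#' @param voltages numeric vector of 64 de-offset voltages, or a samples x 64
#'   matrix.
#' @param model a [calibration_model()], or a list of 64 of them
#'   (one per cell, in cell-id order).
#' @return forces in newtons (<= 0), same shape as `voltages`.
#' @export
frame_forces <- function(voltages, model = default_calibration()) {
  vec_in <- is.null(dim(voltages))
  v <- if (vec_in) matrix(voltages, nrow = 1L) else as.matrix(voltages)
  if (ncol(v) != 64L) stop("expected 64 voltage channels", call. = FALSE)
  if (inherits(model, "calibration_model")) {
    f <- matrix(force_from_voltage(as.numeric(v), model),
                nrow = nrow(v), ncol = 64L)
  } else {
    if (length(model) != 64L ||
        !all(vapply(model, inherits, logical(1), "calibration_model"))) {
      stop("model must be one calibration_model or a list of 64", call. = FALSE)
    }
    f <- v
    for (j in 1:64) f[, j] <- force_from_voltage(v[, j], model[[j]])
  }
  if (vec_in) as.numeric(f) else f
}

#' Vertical ground reaction force and centre of pressure
#'
#' For each frame, `vgrf = sum(F_i)` and the CoP is the force-weighted
#' centroid of the cell coordinates, `cop = sum(F_i * z_i) / vgrf`. Frames
#' whose total force is above the stance threshold (i.e. |vgrf| < 20 N) are
#' treated as no contact: vgrf is reported as 0 and the CoP is undefined
#' (NaN). The centroid is computed from the raw force sum before the
#' threshold is applied, so equality at exactly -20 N counts as loaded.
#'
#' @param forces numeric vector of 64 per-cell forces (N, <= 0) or a
#'   samples x 64 matrix.
#' @param layout a [default_layout()]-shaped sensor layout.
#' @param vgrf_threshold_N stance threshold (N), default -20; frames with
#'   `vgrf > vgrf_threshold_N` are zeroed.
#' @param time_s optional vector of frame times (s).
#' @return data.frame with columns `time_s`, `vgrf_N`, `cop_x_mm`,
#'   `cop_y_mm`; undefined CoP is `NaN`. The number of zeroed frames is
#'   attached as attribute `n_zeroed`.
#' @export
compute_vgrf_cop <- function(forces, layout = default_layout(),
                             vgrf_threshold_N = -20, time_s = NULL) {
  validate_layout(layout)
  f <- if (is.null(dim(forces))) matrix(forces, nrow = 1L) else as.matrix(forces)
  if (ncol(f) != 64L) stop("forces must have one value per layout cell", call. = FALSE)
  ord <- order(layout$cell_id)
  x <- layout$x_mm[ord]; y <- layout$y_mm[ord]
  vgrf <- rowSums(f)
  cop_x <- as.numeric(f %*% x) / vgrf
  cop_y <- as.numeric(f %*% y) / vgrf
  off <- vgrf > vgrf_threshold_N            # |vgrf| < 20 N: no contact
  vgrf[off] <- 0
  cop_x[off] <- NaN
  cop_y[off] <- NaN
  if (is.null(time_s)) time_s <- (seq_len(nrow(f)) - 1L) / 100
  out <- data.frame(time_s = time_s, vgrf_N = vgrf,
                    cop_x_mm = cop_x, cop_y_mm = cop_y)
  attr(out, "n_zeroed") <- sum(off)
  out
}

#' Reconstruct an under-sole pressure map from one force frame
#'
#' Nodal pressure at each cell is `|F_i| / area` (1 N over 1 cm^2 = 10 kPa).
#' The map connects neighbouring cells of the 10 mm lattice into squares and
#' interpolates bilinearly inside each complete square. No smoothing is
#' applied and no outliers are removed: the map shows the raw data.
#'
#' @param forces numeric vector of 64 per-cell forces (N).
#' @param layout sensor layout (cells must sit on a common 10 mm lattice).
#' @param grid_res_mm output grid resolution in mm (> 0), default 2.5.
#' @return object of class `pressure_map`: list with `x`, `y` (mm) and
#'   matrix `z` (kPa, `NA` outside the sensed area), plus `nodes`, the
#'   per-cell nodal pressures.
#' @export
pressure_map <- function(forces, layout = default_layout(), grid_res_mm = 2.5) {
  validate_layout(layout)
  if (!(grid_res_mm > 0)) stop("grid_res_mm must be > 0", call. = FALSE)
  if (length(forces) != 64L) stop("need 64 per-cell forces", call. = FALSE)
  ord <- order(layout$cell_id)
  x <- layout$x_mm[ord]; y <- layout$y_mm[ord]
  p <- 10 * abs(forces[ord]) / layout$area_cm2[ord]   # N/cm^2 -> kPa

  gx <- seq(min(x), max(x), by = grid_res_mm)
  gy <- seq(min(y), max(y), by = grid_res_mm)
  z <- matrix(NA_real_, length(gx), length(gy))

  key <- paste(x, y)
  node <- stats::setNames(seq_along(key), key)
  pitch <- 10
  for (i in seq_along(x)) {
    # square with (x_i, y_i) as lower-left corner, if all 4 corners sensed
    k10 <- node[paste(x[i] + pitch, y[i])]
    k01 <- node[paste(x[i], y[i] + pitch)]
    k11 <- node[paste(x[i] + pitch, y[i] + pitch)]
    if (anyNA(c(k10, k01, k11))) next
    ix <- which(gx >= x[i] & gx <= x[i] + pitch)
    iy <- which(gy >= y[i] & gy <= y[i] + pitch)
    if (!length(ix) || !length(iy)) next
    u <- (gx[ix] - x[i]) / pitch
    w <- (gy[iy] - y[i]) / pitch
    bil <- outer(1 - u, 1 - w) * p[i] + outer(u, 1 - w) * p[k10] +
      outer(1 - u, w) * p[k01] + outer(u, w) * p[k11]
    z[ix, iy] <- bil
  }
  # nodes always carry their exact value (covers isolated cells too)
  for (i in seq_along(x)) {
    ix <- which.min(abs(gx - x[i])); iy <- which.min(abs(gy - y[i]))
    if (abs(gx[ix] - x[i]) < 1e-9 && abs(gy[iy] - y[i]) < 1e-9) z[ix, iy] <- p[i]
  }
  structure(list(x = gx, y = gy, z = z,
                 nodes = data.frame(cell_id = layout$cell_id[ord],
                                    x_mm = x, y_mm = y, pressure_kPa = p)),
            class = "pressure_map")
}

#' @export
print.pressure_map <- function(x, ...) {
  cat(sprintf("<pressure_map> %d x %d grid, peak %.1f kPa\n",
              length(x$x), length(x$y), max(x$nodes$pressure_kPa)))
  invisible(x)
}
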