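PHASE_LEVELS <- c("SW", "ST1", "ST2")

#' Classify samples into the three gait phases
#'
#' Threshold rule on vgrf and the antero-posterior CoP coordinate:
#' * `SW` (swing) when the CoP is undefined (no contact, |vgrf| < 20 N);
#' * `ST1` (initial contact + mid-stance) when `vgrf <= -20 N` and
#'   `cop_y > 125 mm` (CoP in the rear half, heel side);
#' * `ST2` (terminal stance + pre-swing) when `vgrf <= -20 N` and
#'   `cop_y <= 125 mm`.
#'
#' The classification is total: every sample gets exactly one label.
#'
#' @param vgrf_N numeric vector of vertical ground reaction forces (N, <= 0).
#' @param cop_y_mm numeric vector of CoP y coordinates (mm), NaN when
#'   undefined.
#' @param copy_threshold_mm ST1/ST2 boundary on cop_y (mm), default 125.
#' @param vgrf_threshold_N stance threshold (N), default -20.
#' @return factor with levels `SW`, `ST1`, `ST2`.
#' @export
classify_sample <- function(vgrf_N, cop_y_mm, copy_threshold_mm = 125,
                            vgrf_threshold_N = -20) {
  stance <- is.finite(vgrf_N) & vgrf_N <= vgrf_threshold_N & is.finite(cop_y_mm)
  lab <- rep("SW", length(vgrf_N))
  lab[stance & cop_y_mm > copy_threshold_mm] <- "ST1"
  lab[stance & cop_y_mm <= copy_threshold_mm] <- "ST2"
  factor(lab, levels = PHASE_LEVELS)
}

#' Segment a biomechanical sample series into gait phases
#'
#' Causal per-sample application of [classify_sample()] (no lookahead), as
#' the real-time implementation runs it. An optional minimum-phase-duration
#' filter can suppress chatter on noisy inputs; it is off by default because
#' the -20 N threshold already rejects sensor noise.
#'
#' @param biomech data.frame as returned by [compute_vgrf_cop()]
#'   (`time_s`, `vgrf_N`, `cop_y_mm` required).
#' @param side `"left"` or `"right"`.
#' @param copy_threshold_mm,vgrf_threshold_N thresholds, see
#'   [classify_sample()].
#' @param min_phase_s minimum phase duration in seconds (0 disables,
#'   default). When positive (e.g. 0.03), runs shorter than this are merged
#'   into the preceding phase.
#' @param fs_hz sampling rate of the series (Hz), default 100.
#' @return object of class `phase_stream`: list with `time_s`, `phase`
#'   (factor), `fs_hz`, `side`.
#' @export
segment_stream <- function(biomech, side = "left", copy_threshold_mm = 125,
                           vgrf_threshold_N = -20, min_phase_s = 0,
                           fs_hz = 100) {
  stopifnot(all(c("time_s", "vgrf_N", "cop_y_mm") %in% names(biomech)))
  side <- match.arg(side, c("left", "right"))
  ph <- classify_sample(biomech$vgrf_N, biomech$cop_y_mm,
                        copy_threshold_mm, vgrf_threshold_N)
  if (min_phase_s > 0) ph <- min_phase_filter(ph, min_phase_s, fs_hz)
  structure(list(time_s = biomech$time_s, phase = ph, fs_hz = fs_hz,
                 side = side),
            class = "phase_stream")
}

#' @export
print.phase_stream <- function(x, ...) {
  cat(sprintf("<phase_stream> %s foot, %d samples @ %g Hz (SW %d, ST1 %d, ST2 %d)\n",
              x$side, length(x$phase), x$fs_hz,
              sum(x$phase == "SW"), sum(x$phase == "ST1"), sum(x$phase == "ST2")))
  invisible(x)
}

# merge phase runs shorter than min_s into the preceding run
min_phase_filter <- function(phase, min_s, fs_hz) {
  r <- rle(as.character(phase))
  min_n <- ceiling(min_s * fs_hz)
  for (i in seq_along(r$lengths)) {
    if (i > 1 && r$lengths[i] < min_n) r$values[i] <- r$values[i - 1]
  }
  factor(inverse.rle(r), levels = PHASE_LEVELS)
}

#' Detect heel-strike and toe-off events
#'
#' A heel strike is any transition out of swing into a stance phase; a toe
#' off is any transition from stance into swing. The event time is the time
#' of the first sample of the new phase (<= 10 ms quantization at 100 Hz).
#' A stream that starts mid-stance yields a toe off first; the leading
#' partial stance never forms a step. Direct SW to ST2 contacts (forefoot
#' first) still count as heel strikes but are flagged atypical.
#'
#' @param stream a `phase_stream` from [segment_stream()].
#' @return data.frame with columns `event` (`"heel_strike"`/`"toe_off"`),
#'   `time_s`, `index`, `atypical`.
#' @export
detect_events <- function(stream) {
  stopifnot(inherits(stream, "phase_stream"))
  ph <- as.character(stream$phase)
  n <- length(ph)
  if (n < 2L) {
    return(data.frame(event = character(0), time_s = numeric(0),
                      index = integer(0), atypical = logical(0)))
  }
  prev <- ph[-n]; cur <- ph[-1L]
  hs <- which(prev == "SW" & cur != "SW") + 1L
  to <- which(prev != "SW" & cur == "SW") + 1L
  ev <- data.frame(
    event = c(rep("heel_strike", length(hs)), rep("toe_off", length(to))),
    time_s = stream$time_s[c(hs, to)],
    index = c(hs, to),
    atypical = c(ph[hs] == "ST2", rep(FALSE, length(to))))
  ev[order(ev$index), , drop = FALSE]
}

#' Build per-step temporal parameters from an event list
#'
#' A step is the interval between two successive heel strikes of the same
#' foot. Stance runs heel strike to toe off, swing toe off to the next heel
#' strike; cadence is the reciprocal of the step duration. To keep only
#' steady-state gait, the first and last `trim` steps are discarded.
#'
#' @param events data.frame from [detect_events()].
#' @param trim number of steps to drop at each end (default 2).
#' @param side foot label carried into the records.
#' @return data.frame of step records: `side`, `t_heel_strike`, `t_toe_off`,
#'   `t_next_heel_strike`, `dt_stance`, `dt_swing`, `stance_pct`,
#'   `swing_pct`, `cadence_hz`. Empty (with a warning) when fewer than
#'   `2 * trim + 1` steps are available.
#' @export
extract_steps <- function(events, trim = 2L, side = "unknown") {
  empty <- data.frame(side = character(0), t_heel_strike = numeric(0),
                      t_toe_off = numeric(0), t_next_heel_strike = numeric(0),
                      dt_stance = numeric(0), dt_swing = numeric(0),
                      stance_pct = numeric(0), swing_pct = numeric(0),
                      cadence_hz = numeric(0))
  hs <- events$time_s[events$event == "heel_strike"]
  to <- events$time_s[events$event == "toe_off"]
  if (length(hs) < 2L) {
    warning("fewer than 2 heel strikes: no steps", call. = FALSE)
    return(empty)
  }
  recs <- list()
  for (k in seq_len(length(hs) - 1L)) {
    t_off <- to[to > hs[k] & to < hs[k + 1L]]
    if (length(t_off) == 0L) next
    t_off <- t_off[1L]
    dur <- hs[k + 1L] - hs[k]
    recs[[length(recs) + 1L]] <- data.frame(
      side = side,
      t_heel_strike = hs[k], t_toe_off = t_off,
      t_next_heel_strike = hs[k + 1L],
      dt_stance = t_off - hs[k],
      dt_swing = hs[k + 1L] - t_off,
      stance_pct = 100 * (t_off - hs[k]) / dur,
      swing_pct = 100 * (hs[k + 1L] - t_off) / dur,
      cadence_hz = 1 / dur)
  }
  if (length(recs) == 0L) {
    warning("no complete steps found", call. = FALSE)
    return(empty)
  }
  steps <- do.call(rbind, recs)
  if (trim > 0) {
    if (nrow(steps) <= 2L * trim) {
      warning(sprintf(
        "only %d step(s): all removed by trimming %d at each end",
        nrow(steps), trim), call. = FALSE)
      return(empty)
    }
    steps <- steps[(trim + 1L):(nrow(steps) - trim), , drop = FALSE]
  }
  rownames(steps) <- NULL
  steps
}

#' Double-support intervals from bilateral phase streams
#'
#' `DS_L` (preceding a left single support) is the interval in which the
#' left foot is in ST1 while the right foot is in ST2; `DS_R` symmetrically
#' has the left foot in ST2 and the right in ST1. Streams must share the
#' same time base.
#'
#' @param left,right `phase_stream`s for the two feet.
#' @return data.frame with `kind` (`"DS_L"`/`"DS_R"`), `t_start`, `dt_s`.
#' @export
double_support <- function(left, right) {
  stopifnot(inherits(left, "phase_stream"), inherits(right, "phase_stream"))
  if (length(left$phase) != length(right$phase) ||
      left$fs_hz != right$fs_hz ||
      max(abs(left$time_s - right$time_s)) > 1e-9) {
    stop("phase streams are not time-aligned", call. = FALSE)
  }
  runs_of <- function(mask, kind) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) {
      return(data.frame(kind = character(0), t_start = numeric(0),
                        dt_s = numeric(0)))
    }
    data.frame(kind = kind, t_start = left$time_s[starts[keep]],
               dt_s = r$lengths[keep] / left$fs_hz)
  }
  ds <- rbind(
    runs_of(left$phase == "ST1" & right$phase == "ST2", "DS_L"),
    runs_of(left$phase == "ST2" & right$phase == "ST1", "DS_R"))
  ds <- ds[order(ds$t_start), , drop = FALSE]
  rownames(ds) <- NULL
  ds
}

#' Per-trial summary of temporal gait parameters
#'
#' Mean and sample standard deviation, per side, of stance duration, swing
#' duration (seconds and % of stride), double-support duration (seconds and
#' % of the side's mean stride) and cadence.
#'
#' @param left_steps,right_steps step data.frames from [extract_steps()].
#' @param ds_records data.frame from [double_support()] (may be empty).
#' @return data.frame with columns `side`, `parameter`, `mean`, `sd`, `n`.
#' @export
trial_summary <- function(left_steps, right_steps, ds_records = NULL) {
  one_side <- function(steps, side, ds_kind) {
    if (is.null(steps) || nrow(steps) == 0L) return(NULL)
    ms <- function(x) c(mean(x), if (length(x) > 1) stats::sd(x) else 0)
    rows <- list(
      dt_stance_s = ms(steps$dt_stance),
      dt_swing_s = ms(steps$dt_swing),
      stance_pct = ms(steps$stance_pct),
      swing_pct = ms(steps$swing_pct),
      cadence_hz = ms(steps$cadence_hz))
    if (!is.null(ds_records) && nrow(ds_records) > 0L) {
      d <- ds_records$dt_s[ds_records$kind == ds_kind]
      if (length(d)) {
        stride <- mean(steps$dt_stance + steps$dt_swing)
        rows$dt_ds_s <- ms(d)
        rows$ds_pct <- ms(100 * d / stride)
      }
    }
    data.frame(side = side, parameter = names(rows),
               mean = vapply(rows, `[`, numeric(1), 1L),
               sd = vapply(rows, `[`, numeric(1), 2L),
               n = nrow(steps), row.names = NULL)
  }
  out <- rbind(one_side(left_steps, "left", "DS_L"),
               one_side(right_steps, "right", "DS_R"))
  if (is.null(out)) {
    out <- data.frame(side = character(0), parameter = character(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0))
  }
  out
}
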