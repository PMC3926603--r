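# File formats. CSV dialect is fixed throughout: comma separator, '.'
# decimal, "NaN" sentinel for undefined values, UTF-8.

#' Pipeline configuration with the device's default parameters
#'
#' All thresholds and rates of the processing chain in one overridable
#' object: noise threshold -0.02 V, stance threshold -20 N, ST1/ST2
#' boundary 125 mm, 40 Hz low-pass, 1200 -> 100 Hz, two trimmed steps at
#' each end, 100-point step resampling.
#'
#' @param layout_path,calibration_path optional file paths recorded in the
#'   config.
#' @param v0_V,vgrf_N,copy_mm thresholds (V, N, mm).
#' @param cutoff_hz,filter_order low-pass settings.
#' @param fs_in,fs_out sampling rates (Hz).
#' @param trim_steps steps discarded at each end of a trial.
#' @param resample_n points per resampled step profile.
#' @param baseline_s length of the de-offset window (s) at stream start.
#' @param seed RNG seed recorded for provenance.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(layout_path = NULL, calibration_path = NULL,
                            v0_V = -0.02, vgrf_N = -20, copy_mm = 125,
                            cutoff_hz = 40, filter_order = 2,
                            fs_in = 1200, fs_out = 100,
                            trim_steps = 2L, resample_n = 100L,
                            baseline_s = 0.5, seed = 1L) {
  structure(list(layout_path = layout_path, calibration_path = calibration_path,
                 thresholds = list(v0_V = as.numeric(v0_V),
                                   vgrf_N = as.numeric(vgrf_N),
                                   copy_mm = as.numeric(copy_mm)),
                 filter = list(cutoff_hz = as.numeric(cutoff_hz),
                               order = as.numeric(filter_order)),
                 rates = list(fs_in = as.numeric(fs_in),
                              fs_out = as.numeric(fs_out)),
                 trim_steps = as.integer(trim_steps),
                 resample_n = as.integer(resample_n),
                 baseline_s = as.numeric(baseline_s),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for writing).
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    layout_path = j$layout_path, calibration_path = j$calibration_path,
    v0_V = j$thresholds$v0_V, vgrf_N = j$thresholds$vgrf_N,
    copy_mm = j$thresholds$copy_mm,
    cutoff_hz = j$filter$cutoff_hz, filter_order = j$filter$order,
    fs_in = j$rates$fs_in, fs_out = j$rates$fs_out,
    trim_steps = j$trim_steps, resample_n = j$resample_n,
    baseline_s = j$baseline_s, seed = j$seed)
}

#' Read and write sensor layouts as JSON
#'
#' JSON array of objects `{cell_id, x_mm, y_mm, area_cm2}`.
#'
#' @param layout a sensor layout data.frame.
#' @param path file path.
#' @return the layout (read) or the path, invisibly (write).
#' @export
write_layout_json <- function(layout, path) {
  validate_layout(layout)
  jsonlite::write_json(as.data.frame(layout)[, c("cell_id", "x_mm", "y_mm",
                                                 "area_cm2")],
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  layout <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(layout) <- c("sensor_layout", "data.frame")
  validate_layout(layout)
  layout
}

#' Read and write calibration files as JSON
#'
#' Object with the aggregate model `{A1, c1, A2, c2, v0}`, an optional
#' `fit` block (rmse_N, r2, rmse_pct_fsr) and an optional `per_cell` array
#' of the same shape.
#'
#' @param model a [calibration_model()] or a `fit_report`.
#' @param per_cell optional list of per-cell `fit_report`s.
#' @param path file path.
#' @export
write_calibration_json <- function(model, path, per_cell = NULL) {
  as_block <- function(m) {
    if (inherits(m, "fit_report")) {
      c(unclass(m$model),
        list(fit = list(rmse_N = m$rmse_N, r2 = m$r2,
                        rmse_pct_fsr = m$rmse_pct_fsr, n = m$n)))
    } else unclass(m)
  }
  obj <- as_block(model)
  if (!is.null(per_cell)) obj$per_cell <- lapply(per_cell, as_block)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @return for the reader: list with `model` ([calibration_model()]) and,
#'   when present, `per_cell` (list of models).
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_model <- function(b) calibration_model(b$A1, b$c1, b$A2, b$c2, b$v0)
  out <- list(model = as_model(j))
  if (!is.null(j$per_cell)) out$per_cell <- lapply(j$per_cell, as_model)
  out
}

#' Read and write 64-channel voltage streams as CSV
#'
#' Dialect: header `time_s,ch00,...,ch63`, one row per sample, `NaN` for
#' undefined values.
#'
#' @param stream a [voltage_stream()].
#' @param path file path.
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "voltage_stream"))
  df <- data.frame(time_s = stream_time(stream), stream$channels)
  names(df) <- c("time_s", sprintf("ch%02d", 0:63))
  data.table::fwrite(df, path, na = "NaN")
  invisible(path)
}

#' @rdname write_stream_csv
#' @param fs_hz sampling rate to record; inferred from the time column when
#'   `NULL`.
#' @export
read_stream_csv <- function(path, fs_hz = NULL) {
  df <- data.table::fread(path, na.strings = "NaN")
  cols <- sprintf("ch%02d", 0:63)
  if (!all(c("time_s", cols) %in% names(df))) {
    stop("malformed stream CSV: expected columns time_s, ch00..ch63",
         call. = FALSE)
  }
  tt <- df$time_s
  if (is.null(fs_hz)) {
    fs_hz <- if (length(tt) > 1L) 1 / stats::median(diff(tt)) else 1200
    fs_hz <- round(fs_hz, 6)
  }
  voltage_stream(unname(as.matrix(df[, cols, with = FALSE])), fs_hz = fs_hz,
                 t0 = tt[1])
}

#' Read and write biomechanical series as CSV
#'
#' Dialect: `time_s,vgrf_N,cop_x_mm,cop_y_mm`; undefined CoP is `NaN`.
#'
#' @param biomech data.frame from [compute_vgrf_cop()].
#' @param path file path.
#' @export
write_biomech_csv <- function(biomech, path) {
  data.table::fwrite(
    biomech[, c("time_s", "vgrf_N", "cop_x_mm", "cop_y_mm")], path, na = "NaN")
  invisible(path)
}

#' @rdname write_biomech_csv
#' @export
read_biomech_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = "NaN"))
  req <- c("time_s", "vgrf_N", "cop_x_mm", "cop_y_mm")
  if (!all(req %in% names(df))) {
    stop("malformed biomech CSV: expected ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (cc in c("cop_x_mm", "cop_y_mm")) df[[cc]][is.na(df[[cc]])] <- NaN
  df
}

#' Read and write phase streams as CSV (`time_s,phase`)
#'
#' @param stream a `phase_stream`.
#' @param path file path.
#' @export
write_phase_csv <- function(stream, path) {
  data.table::fwrite(data.frame(time_s = stream$time_s,
                                phase = as.character(stream$phase)), path)
  invisible(path)
}

#' @rdname write_phase_csv
#' @param side,fs_hz metadata restored on read.
#' @export
read_phase_csv <- function(path, side = "left", fs_hz = 100) {
  df <- data.table::fread(path)
  if (!all(c("time_s", "phase") %in% names(df)) ||
      !all(df$phase %in% PHASE_LEVELS)) {
    stop("malformed phase CSV", call. = FALSE)
  }
  structure(list(time_s = df$time_s,
                 phase = factor(df$phase, levels = PHASE_LEVELS),
                 fs_hz = fs_hz, side = side),
            class = "phase_stream")
}

#' Read and write step records as CSV
#'
#' @param steps step records from [extract_steps()].
#' @param path file path.
#' @export
write_steps_csv <- function(steps, path) {
  data.table::fwrite(steps, path, na = "NaN")
  invisible(path)
}

#' @rdname write_steps_csv
#' @export
read_steps_csv <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = "NaN"))
}

#' Read and write gait scenarios (YAML or JSON, by extension)
#'
#' @param scenario a [gait_scenario()].
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "gait_scenario"))
  keep <- c("n_steps", "dt_stance", "dt_swing", "ds_fraction",
            "subject_weight_kg", "peak1_N", "peak2_N", "valley_N",
            "peak1_frac", "peak2_frac", "valley_frac", "noise_sd_V",
            "offset_V", "footprint_mm", "fs_hz", "seed")
  obj <- unclass(scenario)[keep]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(gait_scenario, obj)
}

#' Write the ground-truth sidecar of a simulated trial
#'
#' Events and per-step parameters as JSON, true per-sample vgrf/CoP as
#' biomech CSVs.
#'
#' @param truth the `truth` element of a [generate_trial()] result.
#' @param dir output directory.
#' @return the paths written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pj <- file.path(dir, "truth_events.json")
  jsonlite::write_json(
    list(left_events = truth$left_events, right_events = truth$right_events,
         left_steps = truth$left_steps, right_steps = truth$right_steps,
         ds = truth$ds, st1_fraction = truth$st1_fraction),
    pj, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  pl <- file.path(dir, "truth_biomech_left.csv")
  pr <- file.path(dir, "truth_biomech_right.csv")
  write_biomech_csv(truth$biomech_left, pl)
  write_biomech_csv(truth$biomech_right, pr)
  invisible(c(pj, pl, pr))
}
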