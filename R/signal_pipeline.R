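#' Construct a 64-channel voltage stream
#'
#' Container for the insole's raw or conditioned output: a samples x 64
#' matrix of voltages plus the sampling rate and start time. Raw streams are
#' sampled at 1200 Hz on the device; conditioned streams at 100 Hz.
#'
#' @param channels numeric matrix, one column per cell (64 columns), one row
#'   per sample.
#' @param fs_hz sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param baseline optional per-channel offset (V) already removed from
#'   `channels`; recorded for reproducibility.
#' @return an object of class `voltage_stream`.
#' @export
voltage_stream <- function(channels, fs_hz = 1200, t0 = 0, baseline = NULL) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 64L) stop("stream must have 64 channels", call. = FALSE)
  if (!(is.numeric(fs_hz) && fs_hz > 0)) stop("fs_hz must be > 0", call. = FALSE)
  structure(list(channels = channels, fs_hz = fs_hz, t0 = t0,
                 baseline = baseline),
            class = "voltage_stream")
}

#' @export
print.voltage_stream <- function(x, ...) {
  cat(sprintf("<voltage_stream> %d samples x 64 channels @ %g Hz, t0 = %g s%s\n",
              nrow(x$channels), x$fs_hz, x$t0,
              if (is.null(x$baseline)) "" else " (de-offset)"))
  invisible(x)
}

#' Sample times of a voltage stream
#' @param stream a [voltage_stream()].
#' @return numeric vector of times in seconds.
#' @export
stream_time <- function(stream) {
  stream$t0 + (seq_len(nrow(stream$channels)) - 1L) / stream$fs_hz
}

#' Remove the per-channel static offset
#'
#' Each photodiode sits at a nonzero resting voltage (about 1.3 V). The
#' operator records a window during which the insole is unloaded; the
#' per-channel mean over that window is subtracted so that no-load reads
#' approximately 0 V and load produces negative excursions.
#'
#' @param stream a [voltage_stream()].
#' @param baseline_window numeric length-2 vector `c(start, end)` in seconds
#'   (same clock as the stream). Default: the first 0.5 s of the stream.
#' @return the de-offset [voltage_stream()] with `$baseline` filled in.
#' @export
deoffset <- function(stream, baseline_window = NULL) {
  stopifnot(inherits(stream, "voltage_stream"))
  tt <- stream_time(stream)
  if (is.null(baseline_window)) baseline_window <- stream$t0 + c(0, 0.5)
  if (length(baseline_window) != 2L || diff(baseline_window) <= 0) {
    stop("baseline_window must be a (start, end) interval of positive duration",
         call. = FALSE)
  }
  idx <- which(tt >= baseline_window[1] & tt < baseline_window[2])
  if (length(idx) == 0L) {
    stop("baseline window contains no samples", call. = FALSE)
  }
  base <- colMeans(stream$channels[idx, , drop = FALSE])
  voltage_stream(sweep(stream$channels, 2L, base),
                 fs_hz = stream$fs_hz, t0 = stream$t0, baseline = base)
}

#' Low-pass filter and down-sample a stream
#'
#' Mirrors the on-board conditioning: a causal low-pass at 40 Hz followed by
#' decimation from 1200 Hz to 100 Hz (every 12th sample kept, starting from
#' the first). The default is a 2nd-order Butterworth applied causally, as a
#' real-time microcontroller would run it; `zero_phase = TRUE` applies it
#' forward-backward for offline use. The 40 Hz cut-off sits below the 50 Hz
#' output Nyquist, so decimation does not alias the passband.
#'
#' @param stream a [voltage_stream()].
#' @param cutoff_hz filter cut-off frequency (Hz), default 40.
#' @param out_fs_hz output rate (Hz); must divide `fs_hz`. Default 100.
#' @param order Butterworth order, default 2.
#' @param zero_phase logical; forward-backward filtering (default FALSE,
#'   causal).
#' @return a [voltage_stream()] at `out_fs_hz` with `floor(n * out_fs / fs)`
#'   samples.
#' @export
lowpass_decimate <- function(stream, cutoff_hz = 40, out_fs_hz = 100,
                             order = 2, zero_phase = FALSE) {
  stopifnot(inherits(stream, "voltage_stream"))
  ratio <- stream$fs_hz / out_fs_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("out_fs_hz must divide the stream sampling rate", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (cutoff_hz >= out_fs_hz / 2) {
    stop("cutoff must be below the output Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (stream$fs_hz / 2), type = "low")
  filt1 <- function(x) {
    if (zero_phase) as.numeric(signal::filtfilt(bf, x))
    else as.numeric(signal::filter(bf, x))
  }
  y <- apply(stream$channels, 2L, filt1)
  n_out <- floor(nrow(stream$channels) / ratio)
  if (n_out == 0L) stop("stream too short to decimate", call. = FALSE)
  keep <- seq.int(1L, by = ratio, length.out = n_out)
  voltage_stream(y[keep, , drop = FALSE], fs_hz = out_fs_hz, t0 = stream$t0,
                 baseline = stream$baseline)
}
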