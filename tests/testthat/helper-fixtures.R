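# shared fixtures, all generated in code

agg_model <- function() default_calibration()

# characterization sweep for one model (noise-free forward data)
char_sweep <- function(model, n = 30) {
  v <- seq(-1.2, -0.05, length.out = n)
  data.frame(voltage_V = v, force_N = force_from_voltage(v, model))
}

# a tiny phase stream from a character vector of labels
phase_fixture <- function(labels, fs = 100, side = "left", t0 = 0) {
  structure(list(time_s = t0 + (seq_along(labels) - 1) / fs,
                 phase = factor(labels, levels = c("SW", "ST1", "ST2")),
                 fs_hz = fs, side = side),
            class = "phase_stream")
}

# small, fast walking scenario for pipeline tests
small_scenario <- function(n_steps = 7, seed = 11, ...) {
  gait_scenario(n_steps = n_steps, seed = seed, ...)
}
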