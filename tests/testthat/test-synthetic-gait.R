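test_that("scenario validation rejects infeasible timing", {
  expect_error(gait_scenario(dt_stance = -1), "positive")
  expect_error(gait_scenario(ds_fraction = 0.5), "infeasible")
  expect_error(gait_scenario(peak1_N = 100, valley_N = 500, peak2_N = 700),
               "valley")
  sc <- gait_scenario()
  expect_equal(sc$ds_dur, (0.80 - 0.45) / 2)
  expect_equal(1 / sc$stride, 0.8)
})

test_that("simulated vgrf is double-peaked with peaks in the stated windows", {
  sc <- gait_scenario()
  s <- seq(0, 1, length.out = 2001)
  f <- simulate_vgrf_profile(sc, s)
  expect_equal(f[1], 0)
  expect_equal(f[length(f)], 0)
  expect_true(all(f >= 0))
  # interior local maxima
  pk <- which(diff(sign(diff(f))) == -2) + 1
  expect_equal(length(pk), 2L)
  expect_gte(s[pk[1]], 0.15); expect_lte(s[pk[1]], 0.25)
  expect_gte(s[pk[2]], 0.70); expect_lte(s[pk[2]], 0.80)
  expect_equal(f[pk[1]], sc$peak1_N)
  expect_equal(f[pk[2]], sc$peak2_N)
  # mid-stance valley below both peaks
  expect_equal(min(f[s >= 0.3 & s <= 0.6]), sc$valley_N)

  # degenerate plateau: equal peaks and valley, no error, no dip
  scd <- gait_scenario(peak1_N = 500, peak2_N = 500, valley_N = 500)
  fd <- simulate_vgrf_profile(scd, s)
  expect_equal(max(fd), 500)
  expect_equal(min(fd[s >= 0.2 & s <= 0.75]), 500)
})

test_that("simulated CoP runs heel to toe, crossing 125 mm exactly once", {
  sc <- gait_scenario()
  s <- seq(0, 1, length.out = 1001)
  cop <- simulate_cop_trajectory(sc, s)
  expect_true(all(diff(cop$y) <= 0))             # monotone non-increasing
  expect_gt(cop$y[1], 125)                       # heel strike: rear half
  expect_equal(cop$y[1], 240)
  expect_equal(cop$y[1001], 20)
  expect_equal(sum(diff(cop$y <= 125) != 0), 1L) # single boundary crossing
  sb <- st1_boundary_fraction(sc)
  expect_gt(sb, 0); expect_lt(sb, 1)
  expect_equal(240 - 220 * (1 - cos(pi * sb)) / 2, 125, tolerance = 1e-9)
  # lateral excursion stays small and inside the sole
  expect_true(all(cop$x >= 25 & cop$x <= 75))
})

test_that("distribute_pressure matches total force and CoP exactly", {
  lay <- default_layout()
  expect_equal(distribute_pressure(0, c(45, 100), lay), rep(0, 64))
  set.seed(14)
  for (k in 1:12) {
    s <- runif(1, 0.05, 0.95)
    cop <- simulate_cop_trajectory(gait_scenario(), s)
    f <- distribute_pressure(-runif(1, 30, 800), c(cop$x, cop$y), lay)
    expect_true(all(f <= 0))
    b <- compute_vgrf_cop(f, lay, vgrf_threshold_N = 0)
    expect_equal(b$vgrf_N, sum(f))
    expect_lt(abs(b$cop_x_mm - cop$x), 1e-6)
    expect_lt(abs(b$cop_y_mm - cop$y), 1e-6)
  }
  # tight footprint on a cell's exact coordinates: that cell dominates
  i <- 30
  f <- distribute_pressure(-100, c(lay$x_mm[i], lay$y_mm[i]), lay,
                           footprint_mm = 3)
  expect_gte(abs(f[i]) / sum(abs(f)), 0.9)
  expect_error(distribute_pressure(-100, c(-50, 400), lay), "outside")
  expect_error(distribute_pressure(100, c(45, 100), lay), "compression")
})

test_that("forces_to_voltages inverts the transduction law and is seeded", {
  m <- agg_model()
  f <- rep(0, 64)
  f[c(3, 10, 40)] <- c(-50, -120, -7)
  v <- forces_to_voltages(f, m)
  expect_equal(frame_forces(v, m), f, tolerance = 1e-6)
  # forces inside the threshold dead band land at v0 (read back as F(v0))
  f2 <- rep(0, 64); f2[5] <- -1
  v2 <- forces_to_voltages(f2, m)
  expect_equal(v2[5], m$v0)
  expect_equal(f2[-5], frame_forces(v2, m)[-5])
  expect_error(forces_to_voltages(rep(1, 64), m), "not representable")

  va <- forces_to_voltages(f, m, noise_sd_V = 0.005, seed = 99)
  vb <- forces_to_voltages(f, m, noise_sd_V = 0.005, seed = 99)
  expect_identical(va, vb)

  # noise on unloaded cells stays above the threshold (4-sigma margin):
  # Gaussian tail gives P(v <= -0.02 | sd 0.005) ~ 3.2e-5 per sample
  set.seed(5)
  hits <- 0; n_draws <- 200
  for (k in 1:n_draws) {
    vn <- forces_to_voltages(rep(0, 64), m, noise_sd_V = 0.005)
    hits <- hits + sum(frame_forces(vn, m) < 0)
  }
  expect_lt(hits / (64 * n_draws), 5e-4)
})

test_that("per-cell model sampling respects the sign pattern and spread", {
  models <- sample_cell_models(64, seed = 31)
  expect_length(models, 64L)
  a1 <- vapply(models, `[[`, numeric(1), "A1")
  c2 <- vapply(models, `[[`, numeric(1), "c2")
  expect_true(all(a1 > 0) && all(c2 < 0))
  expect_gt(stats::sd(a1), 1)               # genuine cell-to-cell spread
  expect_identical(vapply(sample_cell_models(64, seed = 31), `[[`,
                          numeric(1), "A1"), a1)
})

test_that("generated trials carry consistent ground truth and are seeded", {
  sc <- small_scenario(n_steps = 3, seed = 77)
  tr <- generate_trial(sc)
  expect_s3_class(tr$left, "voltage_stream")
  expect_equal(tr$left$fs_hz, 1200)
  tru <- tr$truth
  expect_equal(nrow(tru$left_steps), 3L)
  expect_equal(tru$left_steps$cadence_hz, rep(1 / 1.25, 3))
  expect_equal(tru$left_steps$dt_stance, rep(0.80, 3))
  # double supports: DS_R = ds, DS_L = stance - swing - ds
  expect_equal(unique(tru$ds$dt_s[tru$ds$kind == "DS_R"]), sc$ds_dur)
  expect_equal(unique(tru$ds$dt_s[tru$ds$kind == "DS_L"]),
               0.80 - 0.45 - sc$ds_dur)
  # truth biomech is consistent with the truth events
  bt <- tru$biomech_left
  in_stance <- bt$vgrf_N < 0
  expect_true(all(is.finite(bt$cop_y_mm[in_stance])))
  # same seed, same streams
  tr2 <- generate_trial(small_scenario(n_steps = 3, seed = 77))
  expect_identical(tr$left$channels, tr2$left$channels)
  tr3 <- generate_trial(small_scenario(n_steps = 3, seed = 78))
  expect_false(identical(tr$left$channels, tr3$left$channels))
})

test_that("the full pipeline recovers the scenario's timing from raw voltages", {
  sc <- small_scenario(n_steps = 7, seed = 101)
  tr <- generate_trial(sc)
  left <- process_stream(tr$left, "left")
  expect_equal(nrow(left$steps), 7 - 2 * 2)      # trim two at each end
  expect_lt(max(abs(left$steps$dt_stance - 0.80)), 0.040)
  expect_lt(max(abs(left$steps$dt_swing - 0.45)), 0.040)
  expect_lt(max(abs(left$steps$cadence_hz - 0.8)), 0.02)
})
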