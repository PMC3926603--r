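test_that("classification follows the threshold rules, boundaries included", {
  expect_equal(as.character(classify_sample(0, NaN)), "SW")
  expect_equal(as.character(classify_sample(-400, 200)), "ST1")
  expect_equal(as.character(classify_sample(-400, 125)), "ST2")  # boundary
  expect_equal(as.character(classify_sample(-400, 125.001)), "ST1")
  expect_equal(as.character(classify_sample(-20, 200)), "ST1")   # boundary
  expect_equal(as.character(classify_sample(-19.9, 200)), "SW")
  # totality on random samples
  set.seed(12)
  vg <- -runif(500, 0, 900)
  cy <- ifelse(runif(500) < 0.2, NaN, runif(500, 0, 250))
  ph <- classify_sample(vg, cy)
  expect_false(anyNA(ph))
  expect_equal(length(ph), 500L)
})

test_that("segment_stream equals naive per-sample rule evaluation", {
  set.seed(21)
  n <- 400
  bio <- data.frame(time_s = (0:(n - 1)) / 100,
                    vgrf_N = -runif(n, 0, 900),
                    cop_y_mm = ifelse(runif(n) < 0.3, NaN, runif(n, 0, 250)))
  bio$vgrf_N[is.nan(bio$cop_y_mm)] <- 0
  ps <- segment_stream(bio)
  # independent oracle: literal one-sample-at-a-time rule application
  naive <- vapply(seq_len(n), function(i) {
    if (!is.finite(bio$cop_y_mm[i]) || bio$vgrf_N[i] > -20) "SW"
    else if (bio$cop_y_mm[i] > 125) "ST1" else "ST2"
  }, character(1))
  expect_equal(as.character(ps$phase), naive)
})

test_that("phase switches ST1 to ST2 when the CoP crosses 125 mm", {
  k <- 30
  bio <- data.frame(time_s = (0:59) / 100, vgrf_N = rep(-500, 60),
                    cop_y_mm = seq(200, 50, length.out = 60))
  ps <- segment_stream(bio)
  first_st2 <- which(ps$phase == "ST2")[1]
  expect_true(all(ps$phase[seq_len(first_st2 - 1)] == "ST1"))
  expect_true(all(ps$phase[first_st2:60] == "ST2"))
  expect_equal(first_st2, which(bio$cop_y_mm <= 125)[1])
})

test_that("events are phase transitions timed at the new phase's first sample", {
  ps <- phase_fixture(c("SW", "SW", "ST1", "ST1", "ST2", "SW"))
  ev <- detect_events(ps)
  expect_equal(ev$event, c("heel_strike", "toe_off"))
  expect_equal(ev$index, c(3L, 6L))
  expect_equal(ev$time_s, c(0.02, 0.05))
  expect_false(any(ev$atypical))

  expect_equal(nrow(detect_events(phase_fixture(rep("SW", 10)))), 0L)

  # stream starting mid-stance: first event is a toe off
  ev2 <- detect_events(phase_fixture(c("ST1", "ST2", "SW", "ST1", "SW")))
  expect_equal(ev2$event[1], "toe_off")

  # forefoot-first contact still registers a (flagged) heel strike
  ev3 <- detect_events(phase_fixture(c("SW", "ST2", "ST2", "SW")))
  expect_equal(ev3$event[1], "heel_strike")
  expect_true(ev3$atypical[1])
})

test_that("event alternation holds on segmented random-walk gait", {
  set.seed(33)
  labs <- unlist(lapply(1:15, function(k) {
    c(rep("SW", sample(20:60, 1)), rep("ST1", sample(20:50, 1)),
      rep("ST2", sample(20:50, 1)))
  }))
  ev <- detect_events(phase_fixture(labs))
  expect_true(all(ev$event[-1] != ev$event[-nrow(ev)]))
})

test_that("steps form between heel strikes and trimming keeps steady state", {
  # 7 steps -> 8 heel strikes; stance 0.80 s, swing 0.45 s
  labs <- c(rep("SW", 10),
            rep(c(rep("ST1", 41), rep("ST2", 39), rep("SW", 45)), 8))
  ev <- detect_events(phase_fixture(labs))
  steps <- extract_steps(ev, trim = 2, side = "left")
  expect_equal(nrow(steps), 3L)
  steps0 <- extract_steps(ev, trim = 0)
  expect_equal(nrow(steps0), 7L)
  expect_equal(steps$dt_stance, rep(0.80, 3))
  expect_equal(steps$dt_swing, rep(0.45, 3))
  expect_equal(steps$cadence_hz, rep(1 / 1.25, 3))
  expect_equal(steps$stance_pct, rep(100 * 0.80 / 1.25, 3))
  expect_equal(steps$stance_pct + steps$swing_pct, rep(100, 3))
  # too few steps: empty result with a warning
  short <- detect_events(phase_fixture(
    c(rep("SW", 5), rep(c(rep("ST1", 10), rep("SW", 10)), 3))))
  expect_warning(out <- extract_steps(short, trim = 2), "step")
  expect_equal(nrow(out), 0L)
})

test_that("double support intersects ST1 of one foot with ST2 of the other", {
  # left ST1 over [0, 0.20) s, right ST2 over [0.10, 0.25) s -> DS_L 0.10 s
  left <- phase_fixture(c(rep("ST1", 20), rep("ST2", 10), rep("SW", 10)))
  right <- phase_fixture(c(rep("SW", 10), rep("ST2", 15), rep("SW", 15)),
                         side = "right")
  ds <- double_support(left, right)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$kind, "DS_L")
  expect_equal(ds$dt_s, 0.10)
  expect_equal(ds$t_start, 0.10)

  # no overlap of the qualifying pair: no records
  ds0 <- double_support(left, phase_fixture(rep("SW", 40), side = "right"))
  expect_equal(nrow(ds0), 0L)

  # swapping the feet maps DS_L to DS_R with the same duration
  ds_sw <- double_support(right, left)
  expect_equal(ds_sw$kind, "DS_R")
  expect_equal(ds_sw$dt_s, ds$dt_s)

  misaligned <- phase_fixture(rep("SW", 39), side = "right")
  expect_error(double_support(left, misaligned), "aligned")
})

test_that("trial summary aggregates per-side means and sample sds", {
  mk_steps <- function(stances, swings, side) {
    hs <- cumsum(c(0, head(stances + swings, -1)))
    data.frame(side = side, t_heel_strike = hs, t_toe_off = hs + stances,
               t_next_heel_strike = hs + stances + swings,
               dt_stance = stances, dt_swing = swings,
               stance_pct = 100 * stances / (stances + swings),
               swing_pct = 100 * swings / (stances + swings),
               cadence_hz = 1 / (stances + swings))
  }
  same <- mk_steps(c(0.8, 0.8), c(0.4, 0.4), "left")
  sm_same <- trial_summary(same, same)
  expect_true(all(sm_same$sd == 0))

  two <- mk_steps(c(0.6, 0.8), c(0.4, 0.4), "left")
  sm <- trial_summary(two, two)
  st <- sm[sm$side == "left" & sm$parameter == "dt_stance_s", ]
  expect_equal(st$mean, 0.7)
  expect_equal(st$sd, 0.1 * sqrt(2))
  # stance% and swing% means are complementary per side
  pct <- sm[sm$side == "left" & sm$parameter %in% c("stance_pct", "swing_pct"), ]
  expect_equal(sum(pct$mean), 100)

  expect_equal(nrow(trial_summary(same[0, ], same[0, ])), 0L)
})

test_that("the optional minimum-phase filter removes chatter when enabled", {
  bio <- data.frame(time_s = (0:99) / 100,
                    vgrf_N = c(rep(0, 10), rep(-500, 40), 0, rep(-500, 39),
                               rep(0, 10)),
                    cop_y_mm = c(rep(NaN, 10), rep(200, 40), NaN, rep(80, 39),
                                 rep(NaN, 10)))
  raw <- segment_stream(bio)                       # default: no debouncing
  expect_equal(sum(raw$phase == "SW"), 21L)
  deb <- segment_stream(bio, min_phase_s = 0.03)
  expect_equal(sum(deb$phase == "SW"), 20L)        # 1-sample dropout merged
})
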