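# build a simple synthetic recording in code: piecewise-constant voltage with
# programmed resistance and a bipolar pulse schedule
make_pulse_trace <- function(n_pairs = 10, rt_mohm = 2, area = 0.33,
                             hz = 5, amp = 0.5, dur = 2, gap = 1,
                             period = 15, v_base = 0, drift_mV_min = 0,
                             events = data.frame(time_s = numeric(),
                                                 label = character())) {
  total <- n_pairs * period + period / 2
  t <- seq(0, total, by = 1 / hz)
  cur <- numeric(length(t))
  for (k in seq_len(n_pairs)) {
    t0 <- period / 2 + (k - 1) * period
    cur[t >= t0 & t < t0 + dur] <- amp
    cur[t >= t0 + dur + gap & t < t0 + 2 * dur + gap] <- -amp
  }
  v <- v_base + cur * rt_mohm + drift_mV_min / 60 * t
  recording_trace(t, v, cur, events = events, area_cm2 = area)
}

test_that("pulse detection finds and pairs the programmed pulses", {
  tr <- make_pulse_trace(n_pairs = 10)
  p <- detect_pulses(tr)
  expect_equal(nrow(p), 20)
  expect_equal(length(unique(stats::na.omit(p$pair_id))), 10)
  expect_true(all(p$ok))
  # each pair holds one +, one -
  for (pid in unique(stats::na.omit(p$pair_id)))
    expect_equal(sort(p$polarity[!is.na(p$pair_id) & p$pair_id == pid]),
                 c(-1L, 1L))
})

test_that("a flat zero-current trace yields no pulses, with a warning", {
  tr <- recording_trace(0:100, rep(1.5, 101), numeric(101))
  expect_warning(p <- detect_pulses(tr), "no current pulses")
  expect_equal(nrow(p), 0)
})

test_that("pulses straddling a protocol event are excluded and flagged", {
  ev <- data.frame(time_s = 8.5, label = "compound_added")
  tr <- make_pulse_trace(n_pairs = 4, events = ev)  # first + pulse spans 7.5-9.5
  p <- detect_pulses(tr)
  bad <- p[!p$ok, ]
  expect_equal(nrow(bad), 1)
  expect_match(bad$reason, "compound_added")
  # its partner loses the pair and falls back to unpaired
  expect_true(is.na(p$pair_id[!p$ok]))
})

test_that("conductance follows Ohm's law: 2 mV / 1 nA / 0.33 cm^2", {
  tr <- make_pulse_trace(rt_mohm = 2)
  g <- compute_gt(tr)
  expect_true(all(g$ok))
  expect_equal(g$gt_mS_cm2, rep(1e-3 / (2 * 0.33), nrow(g)), tolerance = 1e-12)
  expect_equal(g$gt_mS_cm2[1], 1.515e-3, tolerance = 1e-3)
})

test_that("noise-free programmed resistance is recovered to 1e-9", {
  for (rt in c(0.5, 2, 7.3)) {
    g <- compute_gt(make_pulse_trace(rt_mohm = rt))
    expect_equal(max(abs(g$gt_mS_cm2 - 1e-3 / (rt * 0.33))) /
                   (1e-3 / (rt * 0.33)), 0, tolerance = 1e-9)
  }
})

test_that("bipolar pairing keeps drift error under 1%", {
  g <- compute_gt(make_pulse_trace(rt_mohm = 2, drift_mV_min = 0.1))
  truth <- 1e-3 / (2 * 0.33)
  expect_lt(max(abs(g$gt_mS_cm2 - truth)) / truth, 0.01)
})

test_that("conductance extraction is invariant to a voltage offset", {
  tr1 <- make_pulse_trace(v_base = 0)
  tr2 <- make_pulse_trace(v_base = 12.7)
  expect_equal(compute_gt(tr1)$gt_mS_cm2, compute_gt(tr2)$gt_mS_cm2,
               tolerance = 1e-12)
})

test_that("zero-deflection pulses are flagged and excluded", {
  tr <- make_pulse_trace(rt_mohm = 0)   # no voltage response
  g <- compute_gt(tr)
  expect_true(all(!g$ok))
  expect_true(all(is.na(g$gt_mS_cm2)))
  expect_match(g$reason[1], "zero deflection")
})

test_that("plateaus equal programmed levels on piecewise-constant traces", {
  ev <- data.frame(time_s = c(120, 240), label = c("dilution", "compound_added"))
  hz <- 5
  t <- seq(0, 360, by = 1 / hz)
  v <- ifelse(t < 120, 0, ifelse(t < 240, 4.2, -1.3))
  tr <- recording_trace(t, v, numeric(length(t)), events = ev)
  sm <- step_plateaus(tr)
  expect_equal(sm$v_plateau_mV, c(0, 4.2, -1.3))
  expect_equal(sm$label, c("start", "dilution", "compound_added"))
})

test_that("plateau voltages are invariant to pulse placement", {
  ev <- data.frame(time_s = 120, label = "dilution")
  tr_pulse <- make_pulse_trace(n_pairs = 12, v_base = 3, events = ev)
  sm <- step_plateaus(tr_pulse)
  expect_equal(sm$v_plateau_mV, c(3, 3), tolerance = 1e-12)
})

test_that("drifting plateau lands near the segment end value", {
  t <- seq(0, 300, by = 0.2)
  v <- 0.1 / 60 * t                     # 0.1 mV/min drift
  tr <- recording_trace(t, v, numeric(length(t)))
  expect_warning(sm <- step_plateaus(tr, window_s = 400), "shorter than window")
  sm60 <- step_plateaus(tr, window_s = 60)
  expect_equal(nrow(sm60), 1)
  expect_equal(sm60$v_plateau_mV, 0.1 / 60 * 270, tolerance = 0.01)
})

test_that("short segments fall back to the whole segment with a warning", {
  t <- seq(0, 30, by = 0.2)
  tr <- recording_trace(t, rep(2, length(t)), numeric(length(t)))
  expect_warning(sm <- step_plateaus(tr, window_s = 60), "whole segment")
  expect_equal(sm$v_plateau_mV, 2)
  expect_equal(sm$window_s_used, 30)
})

test_that("dose-response delta Gt is post minus pre", {
  expect_equal(dose_response_delta_gt(2, 5), 3)
  expect_equal(dose_response_delta_gt(2, 2), 0)
  expect_error(dose_response_delta_gt(NA, 2), "finite")
})

test_that("trace CSV round-trip through read_trace", {
  sim <- simulate_dilution_trace(synthetic_scenario(noise_sd_mV = 0, seed = 3))
  dir <- tempfile("tracefix"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_dilution_trace(sim, dir, "fix")
  tr <- read_trace(paths[["trace"]], paths[["events"]])
  expect_equal(tr$voltage_mV, sim$trace$voltage_mV, tolerance = 1e-9)
  expect_equal(tr$events$label, c("dilution", "compound_added"))
  expect_error(read_trace("nope.csv"), "not found")
})
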