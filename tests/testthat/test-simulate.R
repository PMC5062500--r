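test_that("a frozen-open channel yields a constant trace at the unitary current", {
  sch <- frozen_open_scheme(90)
  pr <- protocol(data.frame(duration_s = 0.5, voltage_mV = 120,
                            capsaicin_uM = 0, oa_uM = 0),
                 sampling_rate = 5000, filter_cutoff = 2500,
                 noise_sd = 0, seed = 1, init = "O")
  rec <- simulate_single_channel(sch, pr)
  expect_equal(unique(rec$trace$samples), 90 * 120 / 1000)
  expect_equal(nrow(rec$events), 1)
  expect_equal(rec$events$state, "open")
})

test_that("trace length and duration bookkeeping are consistent", {
  sch <- two_state_scheme(200, 50)
  pr <- protocol(data.frame(duration_s = 1.2, voltage_mV = 60,
                            capsaicin_uM = 0, oa_uM = 0),
                 sampling_rate = 5000, filter_cutoff = 2000, seed = 2)
  rec <- simulate_single_channel(sch, pr)
  expect_equal(length(rec$trace$samples), 6000)
  expect_equal(attr(rec$events, "total_duration"), 1.2, tolerance = 1e-9)
})

test_that("protocol validation rejects bad acquisition settings", {
  segs <- data.frame(duration_s = 1, voltage_mV = 0, capsaicin_uM = 0,
                     oa_uM = 0)
  expect_error(protocol(segs[0, ]), "positive durations")
  expect_error(protocol(transform(segs, duration_s = 0)),
               "positive durations")
  expect_error(protocol(segs, sampling_rate = 1000, filter_cutoff = 2000),
               "2 x filter_cutoff")
})

test_that("per-sweep open probability is near 1 at saturating capsaicin", {
  sch <- build_default_scheme()
  po <- vapply(1:5, function(s) {
    pr <- protocol(data.frame(duration_s = 1.2, voltage_mV = 120,
                              capsaicin_uM = 4, oa_uM = 0),
                   sampling_rate = 5000, filter_cutoff = 2000,
                   noise_sd = 0, seed = s)
    open_probability(simulate_single_channel(sch, pr)$events)
  }, numeric(1))
  expect_gt(mean(po), 0.95)
})

test_that("mean dwell durations match the reciprocal exit rates", {
  opening <- 40; closing <- 10
  sch <- two_state_scheme(opening, closing)
  pr <- protocol(data.frame(duration_s = 200, voltage_mV = 10,
                            capsaicin_uM = 0, oa_uM = 0),
                 sampling_rate = 1000, filter_cutoff = 500, seed = 7)
  ev <- simulate_single_channel(sch, pr)$events
  for (st in c("open", "closed")) {
    d <- ev$duration_s[ev$state == st]
    d <- d[-c(1, length(d))]  # drop boundary-truncated dwells
    expected <- if (st == "open") 1 / closing else 1 / opening
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - expected), 3 * se)
  }
})

test_that("identical seeds reproduce traces bit for bit", {
  sch <- build_default_scheme()
  segs <- data.frame(duration_s = 2, voltage_mV = 120, capsaicin_uM = 4,
                     oa_uM = 2)
  pr <- protocol(segs, noise_sd = 1, seed = 99)
  r1 <- simulate_single_channel(sch, pr)
  r2 <- simulate_single_channel(sch, pr)
  expect_identical(r1$trace$samples, r2$trace$samples)
  expect_identical(r1$events$duration_s, r2$events$duration_s)
  m1 <- simulate_macroscopic(sch, 20, pr)
  m2 <- simulate_macroscopic(sch, 20, pr)
  expect_identical(m1$samples, m2$samples)
})

test_that("unitary open-level amplitude is independent of inhibitor", {
  sch <- build_default_scheme()
  lev <- vapply(c(0, 5), function(oa) {
    pr <- protocol(data.frame(duration_s = 5, voltage_mV = 120,
                              capsaicin_uM = 4, oa_uM = oa),
                   sampling_rate = 5000, filter_cutoff = 2500,
                   noise_sd = 0, seed = 3,
                   init = list(voltage = 120, capsaicin = 4, oa = 0))
    max(simulate_single_channel(sch, pr)$trace$samples)
  }, numeric(1))
  expect_equal(lev[1], lev[2], tolerance = 1e-12)
})

test_that("macroscopic simulation picks its method by ensemble size", {
  sch <- build_default_scheme()
  segs <- data.frame(duration_s = 0.2, voltage_mV = 120,
                     capsaicin_uM = 4, oa_uM = 0)
  pr <- protocol(segs, sampling_rate = 1000, filter_cutoff = 500, seed = 5)
  expect_identical(simulate_macroscopic(sch, 10, pr)$meta$method,
                   "stochastic_sum")
  expect_identical(simulate_macroscopic(sch, 1000, pr)$meta$method, "ode")
})

test_that("ensemble steady currents track the stationary conducting mass", {
  sch <- build_default_scheme()
  # equilibrate with and without inhibitor, compare late-time currents
  cur <- vapply(c(0, 5), function(oa) {
    pr <- protocol(data.frame(duration_s = 2, voltage_mV = 120,
                              capsaicin_uM = 4, oa_uM = oa),
                   sampling_rate = 100, filter_cutoff = 50,
                   noise_sd = 0, seed = 1,
                   init = list(voltage = 120, capsaicin = 4, oa = oa))
    tr <- simulate_macroscopic(sch, 1000, pr)
    mean(utils::tail(tr$samples, 50))
  }, numeric(1))
  p0 <- stationary_distribution(sch, 120, 4, 0)$p_open
  p5 <- stationary_distribution(sch, 120, 4, 5)$p_open
  expect_equal(cur[2] / cur[1], p5 / p0, tolerance = 0.02)
})

test_that("n = 1 macroscopic simulation reduces to the single-channel case", {
  sch <- two_state_scheme(100, 100)
  pr <- protocol(data.frame(duration_s = 50, voltage_mV = 10,
                            capsaicin_uM = 0, oa_uM = 0),
                 sampling_rate = 1000, filter_cutoff = 500, seed = 21)
  tr <- simulate_macroscopic(sch, 1, pr)
  # same conducting statistics as the analytic occupancy
  frac_open <- mean(tr$samples > max(tr$samples) / 2)
  expect_lt(abs(frac_open - 0.5), 0.05)
})

test_that("generators hit their analytic anchors and respect seeds", {
  gv0 <- generate_gv_dataset(-63, 0.54, 2, c(-163, -113, -63, -13, 37))
  expect_equal(gv0$conductance[3], 1, tolerance = 1e-12)  # g_max/2 at v_half
  gv_sat <- generate_gv_dataset(-63, 0.54, 2, 1e4)
  expect_equal(gv_sat$conductance, 2, tolerance = 1e-9)
  dr <- generate_dose_response(2.2, 2, c(0, 2.2, 5))
  expect_equal(dr$inhibited, c(0, 0.5, 25 / 29.84), tolerance = 1e-4)
  d1 <- generate_dose_response(2.2, 2, c(1, 5), reps = 3, noise_sd = 0.05,
                               seed = 11)
  d2 <- generate_dose_response(2.2, 2, c(1, 5), reps = 3, noise_sd = 0.05,
                               seed = 11)
  expect_identical(d1, d2)
  expect_true(all(d1$inhibited >= 0 & d1$inhibited <= 1))
})
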