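test_that("levels of a clean bimodal trace are recovered exactly", {
  x <- rep(c(0, 10), each = 50, times = 20)
  lv <- estimate_levels(gk_trace(x, 2e-4))
  expect_true(lv$has_openings)
  expect_equal(lv$baseline, 0, tolerance = 1e-12)
  expect_equal(lv$open_level, 10, tolerance = 1e-12)
  expect_equal(lv$threshold, 5, tolerance = 1e-12)
})

test_that("an all-baseline trace reports no openings", {
  lv <- estimate_levels(gk_trace(rep(0, 2000), 2e-4))
  expect_false(lv$has_openings)
  expect_true(is.na(lv$open_level))
  lv2 <- estimate_levels(gk_trace(rnorm(5000, 0, 1), 2e-4))
  expect_false(lv2$has_openings)
})

test_that("open level is recovered within 0.5 pA on a noisy simulation", {
  sch <- build_default_scheme()
  pr <- protocol(data.frame(duration_s = 5, voltage_mV = 120,
                            capsaicin_uM = 4, oa_uM = 0),
                 sampling_rate = 5000, filter_cutoff = 2000,
                 noise_sd = 1, seed = 8)
  lv <- estimate_levels(simulate_single_channel(sch, pr)$trace)
  expect_true(lv$has_openings)
  expect_lt(abs(lv$open_level - 90 * 120 / 1000), 0.5)
})

test_that("a square pulse idealizes to a single open dwell", {
  dt <- 2e-4
  x <- c(rep(0, 100), rep(10, 10), rep(0, 100))
  lv <- list(baseline = 0, open_level = 10, threshold = 5,
             baseline_sd = 0, has_openings = TRUE)
  ev <- idealize_half_threshold(gk_trace(x, dt), lv)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$state, c("closed", "open", "closed"))
  expect_equal(ev$duration_s[2], 10 * dt, tolerance = 1e-12)
})

test_that("samples exactly at threshold count as closed", {
  lv <- list(baseline = 0, open_level = 10, threshold = 5,
             baseline_sd = 0, has_openings = TRUE)
  ev <- idealize_half_threshold(gk_trace(rep(5, 100), 1e-3), lv,
                                dead_time = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$state, "closed")
})

test_that("undefined open level yields one all-closed dwell", {
  lv <- estimate_levels(gk_trace(rep(0, 2000), 1e-3))
  ev <- idealize_half_threshold(gk_trace(rep(0, 2000), 1e-3), lv)
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "total_duration"), 2)
})

test_that("idealization conserves duration and alternates labels", {
  sch <- build_default_scheme()
  for (seed in 1:3) {
    pr <- protocol(data.frame(duration_s = 2.4, voltage_mV = 120,
                              capsaicin_uM = 4, oa_uM = 0),
                   sampling_rate = 5000, filter_cutoff = 2000,
                   noise_sd = 1, seed = seed)
    tr <- simulate_single_channel(sch, pr)$trace
    ev <- idealize_half_threshold(tr, estimate_levels(tr))
    expect_equal(attr(ev, "total_duration"),
                 length(tr$samples) * tr$dt, tolerance = 1e-9)
    if (nrow(ev) > 1)
      expect_true(all(ev$state[-1] != ev$state[-nrow(ev)]))
  }
})

test_that("noiseless idealization equals per-sample thresholding exactly", {
  set.seed(31)
  # dwells well above the dead time, no noise
  dw <- trace_from_dwells(runif(40, 0.004, 0.02), dt = 2e-4)
  lv <- list(baseline = 0, open_level = 10, threshold = 5,
             baseline_sd = 0, has_openings = TRUE)
  ev <- idealize_half_threshold(dw$trace, lv)
  # brute-force classification oracle
  r <- rle(dw$trace$samples > 5)
  expect_equal(nrow(ev), length(r$lengths))
  expect_equal(ev$duration_s, r$lengths * dw$trace$dt, tolerance = 1e-12)
  expect_equal(nrow(ev), nrow(dw$events))
})

test_that("dwell boundaries survive noise at high SNR", {
  set.seed(77)
  dw <- trace_from_dwells(runif(30, 0.005, 0.03), dt = 2e-4,
                          open_pA = 10, noise_sd = 2)  # SNR 5
  lv <- list(baseline = 0, open_level = 10, threshold = 5,
             baseline_sd = 2, has_openings = TRUE)
  ev <- idealize_half_threshold(dw$trace, lv)
  expect_equal(nrow(ev), nrow(dw$events))
  expect_lt(max(abs(cumsum(ev$duration_s) - cumsum(dw$events$duration_s))),
            2 * dw$trace$dt + 1e-12)
})

test_that("open probability is scale-invariant and correct on anchors", {
  x <- c(rep(0, 50), rep(10, 150))
  lv <- estimate_levels(gk_trace(rep(c(0, 10), each = 50, times = 11), 1e-3))
  ev <- idealize_half_threshold(gk_trace(x, 1e-3), lv)
  expect_equal(open_probability(ev), 0.75, tolerance = 1e-9)
  # scaling the trace scales the levels; Po is unchanged
  lv3 <- estimate_levels(gk_trace(3 * rep(c(0, 10), each = 50, times = 11),
                                  1e-3))
  ev3 <- idealize_half_threshold(gk_trace(3 * x, 1e-3), lv3)
  expect_equal(open_probability(ev3), open_probability(ev))
  expect_equal(open_probability(event_list("open", 1.2)), 1)
})

test_that("symmetric two-state kinetics give Po near one half", {
  sch <- two_state_scheme(80, 80)
  po <- vapply(1:6, function(s) {
    pr <- protocol(data.frame(duration_s = 10, voltage_mV = 10,
                              capsaicin_uM = 0, oa_uM = 0),
                   sampling_rate = 2000, filter_cutoff = 1000, seed = s)
    open_probability(simulate_single_channel(sch, pr)$events)
  }, numeric(1))
  se <- stats::sd(po) / sqrt(length(po))
  expect_lt(abs(mean(po) - 0.5), 3 * se + 0.02)
})

test_that("multichannel patches are detected from overlapping openings", {
  sch <- build_default_scheme()
  pr1 <- protocol(data.frame(duration_s = 3, voltage_mV = 120,
                             capsaicin_uM = 4, oa_uM = 0),
                  sampling_rate = 5000, filter_cutoff = 2500,
                  noise_sd = 0, seed = 13)
  one <- simulate_single_channel(sch, pr1)$trace
  lv <- estimate_levels(one)
  expect_false(detect_multichannel(one, lv))
  pr2 <- protocol(data.frame(duration_s = 3, voltage_mV = 120,
                             capsaicin_uM = 4, oa_uM = 0),
                  sampling_rate = 5000, filter_cutoff = 2500,
                  noise_sd = 0, seed = 14)
  two <- simulate_single_channel(sch, pr2)$trace
  summed <- gk_trace(one$samples + two$samples, one$dt, one$voltage)
  expect_true(detect_multichannel(summed, lv))
  # empty trace: nothing to flag
  lv0 <- estimate_levels(gk_trace(rep(0, 2000), 2e-4))
  expect_false(detect_multichannel(gk_trace(rep(0, 2000), 2e-4), lv0))
})

test_that("inhibitor never increases the mean per-sweep open probability", {
  sch <- build_default_scheme()
  mean_po <- function(oa) {
    mean(vapply(1:4, function(s) {
      pr <- protocol(data.frame(duration_s = 6, voltage_mV = 120,
                                capsaicin_uM = 4, oa_uM = oa),
                     sampling_rate = 5000, filter_cutoff = 2000,
                     noise_sd = 1, seed = 40 + s,
                     init = list(voltage = 120, capsaicin = 4, oa = oa))
      tr <- simulate_single_channel(sch, pr)$trace
      lv <- estimate_levels(tr)
      sweeps <- chop_trace(tr, 1.2)
      mean(vapply(lapply(sweeps, idealize_half_threshold, levels = lv),
                  open_probability, numeric(1)))
    }, numeric(1)))
  }
  expect_gt(mean_po(0), mean_po(5))
})

test_that("open-probability time courses round-trip a noiseless decay", {
  sweep_s <- 1.2
  times <- (0:19) * sweep_s
  po_true <- exp(-times / 6.2)
  sweeps <- lapply(po_true, function(p) {
    if (p >= 1) event_list("open", sweep_s)
    else if (p <= 0) event_list("closed", sweep_s)
    else event_list(c("open", "closed"), c(p, 1 - p) * sweep_s)
  })
  ptc <- po_timecourse(sweeps, times)
  expect_equal(ptc$timecourse$po, po_true, tolerance = 1e-9)
  expect_equal(unname(ptc$fit$params["tau"]), 6.2, tolerance = 1e-6)
  # constant sweeps with jitter: amplitude ~ 0
  set.seed(5)
  flat <- lapply(runif(8, 0.49, 0.51), function(p)
    event_list(c("open", "closed"), c(p, 1 - p) * sweep_s))
  ptc2 <- po_timecourse(flat, (0:7) * sweep_s)
  expect_lt(abs(ptc2$fit$params["amplitude"]), 0.05)
  # fewer than four sweeps: table only
  ptc3 <- po_timecourse(sweeps[1:3], times[1:3])
  expect_null(ptc3$fit)
  expect_equal(nrow(ptc3$timecourse), 3)
})
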