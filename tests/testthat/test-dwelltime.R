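test_that("histograms conserve counts and locate a lone dwell", {
  ev <- event_list(c("closed", "open", "closed"), c(0.01, 0.001, 0.02))
  h <- build_log_histogram(ev, "open")
  expect_equal(h$n_events, 1L)
  expect_equal(sum(h$counts), 1)
  expect_equal(sum(h$counts > 0), 1)
  # the single count sits in the bin containing log10(1 ms)
  i <- which(h$counts == 1)
  expect_true(h$bin_edges[i] <= log10(0.001) &&
                log10(0.001) <= h$bin_edges[i + 1])
})

test_that("histogram counts are conserved for large samples", {
  set.seed(2)
  d <- rexp(5000, 1 / 0.01)
  h <- build_log_histogram(d, "closed", bins_per_decade = 10)
  expect_equal(sum(h$counts), h$n_events)
  expect_equal(h$n_events, 5000L)
  expect_true(all(diff(h$bin_edges) > 0))
  expect_equal(diff(h$bin_edges)[1], 0.1, tolerance = 1e-12)
})

test_that("an exponential's log-time histogram peaks near its time constant", {
  set.seed(3)
  d <- rexp(2e4, 1 / 0.01)
  h <- build_log_histogram(d, "open")
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  # smooth over 3 bins to read the density mode off the sampled counts
  sm <- stats::filter(h$counts, rep(1 / 3, 3), sides = 2)
  peak <- mids[which.max(sm)]
  expect_lt(abs(peak - log10(0.01)), 0.15 + 1e-9)  # within 1.5 bins
})

test_that("pooled dwells give one histogram with pooled counts", {
  set.seed(4)
  d1 <- rexp(500, 1 / 0.01); d2 <- rexp(700, 1 / 0.01)
  h12 <- build_log_histogram(c(d1, d2), "closed")
  expect_equal(h12$n_events, 1200L)
  expect_equal(sum(h12$counts), 1200)
})

test_that("dwells below the dead time are excluded", {
  ev <- event_list(rep(c("closed", "open"), 10),
                   rep(c(0.0001, 0.01), 10),
                   origin = list(dead_time = 4e-4))
  h <- build_log_histogram(ev, "closed")
  expect_equal(h$n_events, 0L)
  h2 <- build_log_histogram(ev, "open")
  expect_equal(h2$n_events, 10L)
})

test_that("a noiseless single-exponential histogram is recovered by a 2-component fit", {
  # bins filled with the exact expected counts of tau = 10 ms
  tau <- 0.01; N <- 1e4
  edges <- seq(log10(tau) - 2, log10(tau) + 1.5, by = 0.1)
  lo <- 10^edges[-length(edges)]; hi <- 10^edges[-1]
  h <- structure(list(state = "closed", bin_edges = edges,
                      counts = N * (exp(-lo / tau) - exp(-hi / tau)),
                      n_events = as.integer(N), bins_per_decade = 10),
                 class = "dwell_histogram")
  f <- fit_exponential_mixture(h, 2)
  expect_true(f$converged)
  dominant <- which.max(f$amplitudes)
  expect_equal(f$taus[dominant], tau, tolerance = 0.02)
  # the second component is either negligible or degenerate at the same tau
  minor <- setdiff(1:2, dominant)
  expect_true(f$amplitudes[minor] < 0.1 ||
                abs(log10(f$taus[minor] / tau)) < 0.05)
})

test_that("two well-separated components are recovered from sampled dwells", {
  taus_err <- c(); w_err <- c()
  for (seed in 1:5) {
    set.seed(seed)
    d <- c(rexp(7000, 1 / 0.001), rexp(3000, 1 / 0.1))
    f <- fit_exponential_mixture(build_log_histogram(d, "closed"), 2)
    expect_true(f$converged)
    taus_err <- c(taus_err, abs(f$taus / c(0.001, 0.1) - 1))
    w_err <- c(w_err, abs(f$amplitudes - c(0.7, 0.3)))
  }
  expect_lt(max(taus_err), 0.15)
  expect_lt(max(w_err), 0.1)
})

test_that("fit self-consistency: the fitted mixture integrates to the event count", {
  set.seed(6)
  d <- c(rexp(6000, 1 / 0.002), rexp(4000, 1 / 0.05))
  h <- build_log_histogram(d, "closed")
  f <- fit_exponential_mixture(h, 2)
  pred <- gatekin:::.mixture_expected(h$bin_edges, f$taus, f$scale)
  expect_lt(abs(sum(pred) / h$n_events - 1), 0.05)
})

test_that("refitting from a previous fit is a fixed point", {
  set.seed(7)
  d <- c(rexp(5000, 1 / 0.001), rexp(5000, 1 / 0.05))
  h <- build_log_histogram(d, "closed")
  f1 <- fit_exponential_mixture(h, 2)
  f2 <- fit_exponential_mixture(h, 2,
                                start = list(taus = f1$taus,
                                             amplitudes = f1$amplitudes))
  expect_equal(f2$taus, f1$taus, tolerance = 1e-4)
  expect_equal(f2$amplitudes, f1$amplitudes, tolerance = 1e-4)
})

test_that("component-count selection follows parsimony and separation", {
  set.seed(8)
  one <- rexp(5000, 1 / 0.01)
  expect_equal(select_component_count(build_log_histogram(one, "open"))$n_components, 2L)
  two <- c(rexp(6000, 1 / 0.001), rexp(4000, 1 / 0.1))
  expect_equal(select_component_count(build_log_histogram(two, "closed"))$n_components, 2L)
  three <- c(rexp(4000, 1 / 5e-4), rexp(3000, 1 / 0.01), rexp(3000, 1 / 0.3))
  sel3 <- select_component_count(build_log_histogram(three, "closed"))
  expect_equal(sel3$n_components, 3L)
  expect_true(min(diff(sort(log10(sel3$fit$taus)))) >= 0.3)
})

test_that("inhibitor lengthens closed dwells and shortens open dwells", {
  sch <- build_default_scheme()
  # pool steady-state records at each condition (the true dwell sequence
  # does not depend on the sampling rate, so sample coarsely)
  pool <- function(oa, seeds, state) {
    unlist(lapply(seeds, function(s) {
      pr <- protocol(data.frame(duration_s = 60, voltage_mV = 120,
                                capsaicin_uM = 4, oa_uM = oa),
                     sampling_rate = 200, filter_cutoff = 100,
                     noise_sd = 0, seed = s,
                     init = list(voltage = 120, capsaicin = 4, oa = oa))
      ev <- simulate_single_channel(sch, pr)$events
      ev$duration_s[ev$state == state]
    }))
  }
  stats <- lapply(c(0, 5), function(oa) {
    d <- pool(oa, 300 + oa * 20 + 1:20, "closed")
    f <- fit_exponential_mixture(
      build_log_histogram(d, "closed", dead_time = 4e-4), 2)
    # "slow" components: closures beyond the gating timescale
    list(slow_tau = max(f$taus),
         slow_w = sum(f$amplitudes[f$taus > 0.1]))
  })
  expect_gt(stats[[2]]$slow_tau, stats[[1]]$slow_tau)
  expect_gt(stats[[2]]$slow_w, stats[[1]]$slow_w)
  # open dwells shorten on average under the inhibitor (capture pathway)
  open0 <- pool(0, 361:363, "open")
  open5 <- pool(5, 364:366, "open")
  expect_gt(mean(open0), mean(open5))
})

test_that("empty and undersized histograms are handled explicitly", {
  ev <- event_list("closed", 0.5)
  h <- build_log_histogram(ev, "open")
  expect_equal(h$n_events, 0L)
  small <- build_log_histogram(rexp(15, 100), "open")
  expect_error(fit_exponential_mixture(small, 2), "at least 20")
})
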