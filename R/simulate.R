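# Stochastic and deterministic current simulation.

# Gaussian low-pass FIR kernel emulating the recording filter. The -3 dB
# cutoff fc maps to a time-domain sigma of sqrt(ln 2)/(2 pi fc); near the
# Nyquist limit the kernel degenerates to (almost) the identity.
.gaussian_lowpass <- function(x, sampling_rate, cutoff) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * sampling_rate  # in samples
  if (sigma < 0.25) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))  # edge padding
  as.numeric(stats::filter(xp, k, sides = 2)[(half + 1):(half + n)])
}

# Resolve a protocol's initial condition to a probability vector.
.initial_distribution <- function(scheme, prot) {
  init <- prot$init
  seg1 <- prot$segments[1, ]
  if (is.null(init))
    init <- list(voltage = seg1$voltage_mV, capsaicin = seg1$capsaicin_uM,
                 oa = seg1$oa_uM)
  if (is.character(init)) {
    p0 <- as.numeric(scheme$state_names == init)
    if (sum(p0) != 1) stop("unknown initial state: ", init)
    return(p0)
  }
  if (is.numeric(init)) {
    stopifnot(length(init) == length(scheme$state_names), all(init >= 0))
    return(init / sum(init))
  }
  sd <- stationary_distribution(scheme, init$voltage, init$capsaicin, init$oa)
  if (!sd$ergodic) {
    # start in the (unique) closed communicating class if there is one
    if (length(sd$components) != 1)
      stop("non-ergodic initial condition with multiple closed classes; ",
           "give an explicit initial state")
    p0 <- rep(0, length(scheme$state_names))
    names(p0) <- scheme$state_names
    p0[names(sd$components[[1]])] <- sd$components[[1]]
    return(as.numeric(p0))
  }
  as.numeric(sd$pi)
}

# Exact-jump (Gillespie) trajectory over all protocol segments. Returns
# the piecewise-constant state path as parallel vectors of dwell start
# times and state indices. Draws from the current RNG stream.
.gillespie_path <- function(scheme, prot, state0) {
  segs <- prot$segments
  t_abs <- 0
  state <- state0
  starts <- t_abs
  states <- state
  for (i in seq_len(nrow(segs))) {
    Q <- rate_matrix(scheme, segs$voltage_mV[i], segs$capsaicin_uM[i],
                     segs$oa_uM[i])
    t_end <- t_abs + segs$duration_s[i]
    repeat {
      exit <- -Q[state, state]
      if (exit <= 0) { t_abs <- t_end; break }  # absorbing at this condition
      t_jump <- t_abs + stats::rexp(1, exit)
      if (t_jump >= t_end) { t_abs <- t_end; break }
      rates <- Q[state, ]; rates[state] <- 0
      state <- sample.int(length(rates), 1L, prob = rates)
      t_abs <- t_jump
      starts <- c(starts, t_abs)
      states <- c(states, state)
    }
  }
  list(starts = starts, states = states, total = t_abs)
}

# Per-sample state indices of a jump path on the protocol's time base.
.sample_states <- function(path, sample_times) {
  path$states[findInterval(sample_times, path$starts)]
}

# Per-sample voltage vector for a protocol.
.sample_voltage <- function(prot, sample_times) {
  bounds <- cumsum(prot$segments$duration_s)
  idx <- findInterval(sample_times, c(0, utils::head(bounds, -1)))
  prot$segments$voltage_mV[idx]
}

# True (unfiltered) dwell sequence from a jump path, collapsed to
# open/closed classes.
.path_to_events <- function(scheme, path) {
  cls <- ifelse(scheme$conductance[path$states] > 0, "open", "closed")
  durations <- diff(c(path$starts, path$total))
  event_list(cls, durations, origin = list(source = "simulation"))
}

#' Simulate a single-channel recording
#'
#' Draws one exact-jump (Gillespie) trajectory of the scheme's Markov
#' chain through every protocol segment, converts the state path to
#' current (per-state conductance times driving force), applies the
#' emulated recording filter and adds Gaussian noise. The unfiltered true
#' dwell sequence is returned alongside the trace so downstream event
#' detection can be validated against ground truth.
#'
#' @param scheme A [gating_scheme()].
#' @param protocol A [protocol()]. Exactly one channel is simulated.
#' @return List with `trace` (a [gk_trace()]) and `events` (the true
#'   [event_list()]).
#' @examples
#' sch <- build_default_scheme()
#' prot <- protocol(
#'   data.frame(duration_s = 1.2, voltage_mV = 120,
#'              capsaicin_uM = 4, oa_uM = 0),
#'   noise_sd = 1, seed = 42)
#' rec <- simulate_single_channel(sch, prot)
#' open_probability(rec$events)
#' @export
simulate_single_channel <- function(scheme, protocol) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(protocol, "gk_protocol"))
  set.seed(protocol$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  p0 <- .initial_distribution(scheme, protocol)
  state0 <- sample.int(length(p0), 1L, prob = p0)
  path <- .gillespie_path(scheme, protocol, state0)
  dt <- 1 / protocol$sampling_rate
  total <- sum(protocol$segments$duration_s)
  ts <- seq(0, total - dt / 2, by = dt)
  v <- .sample_voltage(protocol, ts)
  states <- .sample_states(path, ts)
  current <- scheme$conductance[states] * (v - scheme$e_rev) / 1000  # pA
  current <- .gaussian_lowpass(current, protocol$sampling_rate,
                               protocol$filter_cutoff)
  if (protocol$noise_sd > 0)
    current <- current + stats::rnorm(length(current), 0, protocol$noise_sd)
  meta <- list(segments = protocol$segments,
               sampling_rate = protocol$sampling_rate,
               filter_cutoff = protocol$filter_cutoff,
               noise_sd = protocol$noise_sd,
               seed = protocol$seed,
               n_channels = 1L,
               method = "gillespie",
               states = scheme$state_names)
  voltage <- if (length(unique(v)) == 1) v[1] else v
  list(trace = gk_trace(current, dt, voltage, meta),
       events = .path_to_events(scheme, path))
}

#' Simulate a macroscopic (multi-channel) current
#'
#' For small ensembles (`n_channels` at or below `stochastic_limit`) the
#' current is the sum of independent single-channel Gillespie
#' trajectories; for large ensembles channel noise is negligible relative
#' to fit tolerances and the deterministic occupancy solution (matrix
#' exponential of the piecewise-constant generator) scaled by the channel
#' count is used instead. The method actually used is recorded in the
#' trace metadata.
#'
#' @inheritParams simulate_single_channel
#' @param n_channels Number of channels in the patch (>= 1).
#' @param stochastic_limit Largest ensemble simulated stochastically.
#' @return A [gk_trace()] of the ensemble current in pA.
#' @export
simulate_macroscopic <- function(scheme, n_channels, protocol,
                                 stochastic_limit = 500) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(protocol, "gk_protocol"),
            n_channels >= 1)
  set.seed(protocol$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  p0 <- .initial_distribution(scheme, protocol)
  dt <- 1 / protocol$sampling_rate
  total <- sum(protocol$segments$duration_s)
  ts <- seq(0, total - dt / 2, by = dt)
  v <- .sample_voltage(protocol, ts)
  if (n_channels <= stochastic_limit) {
    method <- "stochastic_sum"
    current <- numeric(length(ts))
    for (ch in seq_len(n_channels)) {
      state0 <- sample.int(length(p0), 1L, prob = p0)
      path <- .gillespie_path(scheme, protocol, state0)
      states <- .sample_states(path, ts)
      current <- current + scheme$conductance[states]
    }
    current <- current * (v - scheme$e_rev) / 1000
  } else {
    method <- "ode"
    segs <- protocol$segments
    occ <- matrix(NA_real_, length(scheme$state_names), length(ts))
    p_seg <- p0
    t0 <- 0
    for (i in seq_len(nrow(segs))) {
      t1 <- t0 + segs$duration_s[i]
      idx <- which(ts >= t0 - dt / 4 & ts < t1 - dt / 4)
      Q <- rate_matrix(scheme, segs$voltage_mV[i], segs$capsaicin_uM[i],
                       segs$oa_uM[i])
      if (length(idx))
        occ[, idx] <- .evolve_occupancy(Q, p_seg, ts[idx] - t0)
      p_seg <- as.numeric(.evolve_occupancy(Q, p_seg, segs$duration_s[i]))
      t0 <- t1
    }
    g_mean <- as.numeric(scheme$conductance %*% occ)
    current <- n_channels * g_mean * (v - scheme$e_rev) / 1000
  }
  current <- .gaussian_lowpass(current, protocol$sampling_rate,
                               protocol$filter_cutoff)
  if (protocol$noise_sd > 0)
    current <- current + stats::rnorm(length(current), 0, protocol$noise_sd)
  meta <- list(segments = protocol$segments,
               sampling_rate = protocol$sampling_rate,
               filter_cutoff = protocol$filter_cutoff,
               noise_sd = protocol$noise_sd,
               seed = protocol$seed,
               n_channels = as.integer(n_channels),
               method = method,
               states = scheme$state_names)
  voltage <- if (length(unique(v)) == 1) v[1] else v
  gk_trace(current, dt, voltage, meta)
}
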