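# Shared fixtures: small schemes, synthetic traces, and brute-force
# oracles used across the suite.

# Minimal two-state C <-> O scheme with constant rates (1/s).
two_state_scheme <- function(opening = 100, closing = 100, g_open = 10) {
  gating_scheme(
    state_names = c("C", "O"),
    rate_matrix_fn = function(voltage, capsaicin, oa) {
      Q <- matrix(c(-opening, opening, closing, -closing), 2, 2,
                  byrow = TRUE)
      dimnames(Q) <- list(c("C", "O"), c("C", "O"))
      Q
    },
    conductance = c(0, g_open))
}

# Scheme frozen in the open state (degenerate chain, no transitions).
frozen_open_scheme <- function(g_open = 90) {
  gating_scheme(
    state_names = c("C", "O"),
    rate_matrix_fn = function(voltage, capsaicin, oa) matrix(0, 2, 2),
    conductance = c(0, g_open))
}

# Random irreducible scheme for property tests (seeded by caller).
random_scheme <- function(n_states = sample(3:5, 1)) {
  repeat {
    Q <- matrix(0, n_states, n_states)
    for (i in seq_len(n_states)) for (j in seq_len(n_states)) {
      if (i != j && stats::runif(1) < 0.7)
        Q[i, j] <- stats::runif(1, 1, 100)
    }
    # guarantee irreducibility with a cycle
    for (i in seq_len(n_states)) {
      j <- if (i == n_states) 1L else i + 1L
      if (Q[i, j] == 0) Q[i, j] <- stats::runif(1, 1, 100)
    }
    diag(Q) <- -rowSums(Q)
    g <- numeric(n_states)
    g[sample(n_states, max(1, n_states %/% 2))] <- 10
    if (any(g > 0) && any(g == 0)) {
      return(gating_scheme(
        state_names = paste0("S", seq_len(n_states)),
        rate_matrix_fn = function(voltage, capsaicin, oa) Q,
        conductance = g))
    }
  }
}

# Textbook Welch two-sample t statistic and dof.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

# Square-wave trace built from a known dwell sequence (states alternate
# starting closed), with optional Gaussian noise.
trace_from_dwells <- function(durations_s, dt = 2e-4, open_pA = 10,
                              noise_sd = 0, first = "closed") {
  states <- rep(c(first, setdiff(c("open", "closed"), first)),
                length.out = length(durations_s))
  samp <- unlist(lapply(seq_along(durations_s), function(i) {
    n <- round(durations_s[i] / dt)
    rep(if (states[i] == "open") open_pA else 0, n)
  }))
  if (noise_sd > 0) samp <- samp + stats::rnorm(length(samp), 0, noise_sd)
  list(trace = gk_trace(samp, dt),
       events = event_list(states, round(durations_s / dt) * dt))
}

# Open-class occupancy and its Monte-Carlo standard error from the true
# dwell sequence of a long simulation, by chunked means.
occupancy_with_se <- function(events, n_chunks = 10) {
  ends <- cumsum(events$duration_s)
  total <- ends[length(ends)]
  bounds <- seq(0, total, length.out = n_chunks + 1)
  po <- vapply(seq_len(n_chunks), function(k) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    starts <- c(0, ends[-length(ends)])
    ov <- pmin(ends, t1) - pmax(starts, t0)
    ov[ov < 0] <- 0
    sum(ov[events$state == "open"]) / (t1 - t0)
  }, numeric(1))
  list(mean = mean(po), se = stats::sd(po) / sqrt(n_chunks))
}
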