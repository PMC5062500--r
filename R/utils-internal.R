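# Internal numerical helpers shared by the simulator and the scheme
# calibration.

# Propagate state occupancy under a constant generator: p(t) = p0 exp(Q t),
# evaluated at all times in `ts` via one eigendecomposition. Returns a
# matrix with one column per time point and one row per state.
.evolve_occupancy <- function(Q, p0, ts) {
  e <- eigen(t(Q))
  Vi <- solve(e$vectors)
  c0 <- Vi %*% p0
  out <- vapply(ts, function(t) {
    Re(e$vectors %*% (exp(e$values * t) * c0))
  }, numeric(nrow(Q)))
  out <- matrix(out, nrow = nrow(Q))
  out[out < 0 & out > -1e-12] <- 0
  out
}

# Quick single-exponential least-squares fit used only inside the scheme
# calibration (the user-facing fitter is fit_single_exponential).
.quick_exp_tau <- function(t, y) {
  f <- function(p) sum((y - (p[3] + p[1] * exp(-t / p[2])))^2)
  o <- stats::optim(c(y[1] - y[length(y)], max(t) / 4, y[length(y)]), f,
                    control = list(reltol = 1e-12, maxit = 5000))
  o$par[2]
}
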