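# Nonlinear least-squares fits: Boltzmann activation, Hill dose-response,
# single-exponential relaxations, and closed-state energetics.

.new_fit <- function(class, params, se, sse, converged, extra = list()) {
  structure(c(list(params = params, se = se, sse = sse,
                   converged = converged), extra),
            class = c(class, "gk_fit"))
}

#' @export
print.gk_fit <- function(x, ...) {
  cat("<", class(x)[1], "> ", if (x$converged) "converged" else
    "NOT converged", "; sse = ", signif(x$sse, 5), "\n", sep = "")
  est <- rbind(estimate = x$params, std.error = x$se)
  print(signif(est, 5))
  invisible(x)
}

# Deterministic multi-start nlsLM wrapper: returns the converged fit with
# the smallest residual sum of squares, or the best effort with
# converged = FALSE if no start converges.
.multistart_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL; best_sse <- Inf; any_conv <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    conv <- fit$convInfo$isConv %||% TRUE
    if (sse < best_sse - 1e-8 * max(1, best_sse) ||
        (conv && !any_conv)) {
      best <- fit; best_sse <- sse
    }
    any_conv <- any_conv || conv
  }
  if (is.null(best)) return(NULL)
  co <- summary(best)$coefficients
  list(params = co[, 1], se = co[, 2], sse = best_sse,
       converged = any_conv, fit = best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conductance from current by Ohm's law
#'
#' `G = I / (V - E_rev)`; with current in pA and voltage in mV the result
#' is in nS.
#'
#' @param current_pA Current, pA (vectorized).
#' @param voltage_mV Membrane potential, mV.
#' @param e_rev Reversal potential, mV.
#' @return Conductance in nS.
#' @examples
#' conductance_from_iv(120, 120, 0) # 1 nS
#' @export
conductance_from_iv <- function(current_pA, voltage_mV, e_rev = 0) {
  if (any(voltage_mV == e_rev))
    stop("undefined conductance at reversal")
  current_pA / (voltage_mV - e_rev)
}

#' Fit a Boltzmann activation curve to conductance-voltage data
#'
#' Least-squares fit of `G(V) = G_max / (1 + exp(-q_a (V - V_half)/kT))`
#' with `q_a` constrained positive. Raw (unnormalized) conductances are
#' internally scaled to unit maximum for conditioning and the fitted
#' `g_max` rescaled back. Starting values form a deterministic grid of
#' `v_half` seeds at the voltage quartiles crossed with two `q_a` seeds.
#'
#' @param gv Data frame with columns `voltage_mV` and `conductance`
#'   (at least 5 points spanning at least 100 mV).
#' @param temperature Absolute temperature in kelvin.
#' @return A `boltzmann_fit`: parameters `g_max`, `v_half` (mV), `q_a`
#'   (e0) with standard errors, residual sum of squares and a convergence
#'   flag.
#' @examples
#' gv <- generate_gv_dataset(-63, 0.54, 1, seq(-200, 200, 20))
#' fit_boltzmann(gv)$params
#' @export
fit_boltzmann <- function(gv, temperature = .GK_TEMPERATURE_K) {
  stopifnot(is.data.frame(gv),
            all(c("voltage_mV", "conductance") %in% names(gv)))
  gv <- gv[stats::complete.cases(gv[, c("voltage_mV", "conductance")]), ]
  if (nrow(gv) < 5 || diff(range(gv$voltage_mV)) < 100)
    stop("need at least 5 points spanning at least 100 mV")
  kT <- kT_mV(temperature)
  scale <- max(abs(gv$conductance))
  if (scale <= 0) stop("all conductances are zero")
  normalized <- scale < 1.2
  d <- data.frame(V = gv$voltage_mV, G = gv$conductance / scale)
  if (all(diff(d$G[order(d$V)]) <= 0))
    warning("conductance decreases monotonically with voltage; ",
            "fitting with q_a > 0 anyway")
  vq <- stats::quantile(d$V, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  starts <- list()
  for (v0 in vq) for (q0 in c(0.3, 1))
    starts[[length(starts) + 1]] <- list(g_max = max(d$G), v_half = v0,
                                         q_a = q0)
  r <- .multistart_nls(
    G ~ g_max / (1 + exp(-q_a * (V - v_half) / kT)),
    data = d, starts = starts,
    lower = c(g_max = 1e-8, v_half = -1e4, q_a = 1e-6),
    upper = c(g_max = Inf, v_half = 1e4, q_a = 20))
  if (is.null(r)) stop("Boltzmann fit failed from every start")
  params <- r$params; se <- r$se
  params["g_max"] <- params["g_max"] * scale
  se["g_max"] <- se["g_max"] * scale
  .new_fit("boltzmann_fit", params, se, r$sse * scale^2, r$converged,
           list(temperature = temperature, normalized = normalized))
}

#' Fit the Hill equation to dose-response data
#'
#' Least-squares fit of the inhibited fraction
#' `f(c) = c^n / (c^n + K_D^n)` with `K_D > 0` and `n > 0`, from a
#' deterministic grid of starts (`K_D` at the concentration quartiles,
#' two Hill-coefficient seeds).
#'
#' @param dose Data frame with columns `conc_uM` and `inhibited`
#'   (fraction in `[0, 1]`); at least 4 distinct concentrations.
#' @return A `hill_fit` with parameters `k_d` (uM) and `n_hill`.
#' @examples
#' dr <- generate_dose_response(2.2, 2, c(0.5, 1, 2, 5, 10, 20))
#' fit_hill(dr)$params
#' @export
fit_hill <- function(dose) {
  stopifnot(is.data.frame(dose),
            all(c("conc_uM", "inhibited") %in% names(dose)))
  dose <- dose[stats::complete.cases(dose[, c("conc_uM", "inhibited")]), ]
  if (length(unique(dose$conc_uM)) < 4)
    stop("need at least 4 distinct concentrations")
  if (all(dose$inhibited == 0)) stop("no inhibition to fit")
  d <- data.frame(conc = dose$conc_uM, f = dose$inhibited)
  cpos <- d$conc[d$conc > 0]
  kq <- stats::quantile(cpos, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  starts <- list()
  for (k0 in kq) for (n0 in c(1, 3))
    starts[[length(starts) + 1]] <- list(k_d = k0, n_hill = n0)
  r <- .multistart_nls(
    f ~ conc^n_hill / (conc^n_hill + k_d^n_hill),
    data = d, starts = starts,
    lower = c(k_d = 1e-8, n_hill = 1e-3),
    upper = c(k_d = Inf, n_hill = 50))
  if (is.null(r)) stop("Hill fit failed from every start")
  .new_fit("hill_fit", r$params, r$se, r$sse, r$converged)
}

#' Predicted Hill inhibition at a concentration
#'
#' Evaluates `c^n / (c^n + K_D^n)` for given Hill parameters; convenience
#' companion to [fit_hill()].
#'
#' @param conc Concentration(s), uM.
#' @param k_d Apparent dissociation constant, uM.
#' @param n_hill Hill coefficient.
#' @return Inhibited fraction(s).
#' @examples
#' hill_inhibition(5, 2.2, 2) # ~0.838
#' @export
hill_inhibition <- function(conc, k_d, n_hill) {
  stopifnot(k_d > 0, n_hill > 0)
  conc^n_hill / (conc^n_hill + k_d^n_hill)
}

#' Fit a single-exponential relaxation to a time course
#'
#' Least-squares fit of `y(t) = y_inf + A exp(-t / tau)`; a positive
#' fitted `A` describes a decay, a negative one a recovery of the form
#' `y0 + A' (1 - exp(-t/tau))`. The direction is auto-detected from the
#' data trend and recorded. Because amplitude and offset enter linearly,
#' the fit profiles them out and optimizes the residual over `tau` alone
#' (coarse geometric grid over the observation window, then a bracketed
#' 1-D refinement), which is robust even on step-like relaxations where
#' general-purpose nonlinear solvers collapse to degenerate time
#' constants.
#'
#' @param timecourse Data frame with columns `t` (s, non-decreasing;
#'   ties mark replicate measurements) and `y`; at least 4 points.
#' @return An `exp_fit` with parameters `tau` (s), `amplitude`, `offset`,
#'   plus a `direction` field (`"decay"` or `"recovery"`).
#' @examples
#' tc <- data.frame(t = 0:40, y = exp(-(0:40) / 6.2))
#' fit_single_exponential(tc)$params[["tau"]]
#' @export
fit_single_exponential <- function(timecourse) {
  stopifnot(is.data.frame(timecourse),
            all(c("t", "y") %in% names(timecourse)))
  d <- timecourse[stats::complete.cases(timecourse[, c("t", "y")]), ]
  if (nrow(d) < 4) stop("need at least 4 time points")
  # ties are allowed: replicate sweeps at the same application time pool
  # into one least-squares problem
  if (is.unsorted(d$t)) stop("t must be non-decreasing")
  if (max(d$y) == min(d$y)) stop("no relaxation")
  n <- nrow(d)
  head_mean <- mean(d$y[seq_len(max(2, n %/% 3))])
  tail_mean <- mean(d$y[(n - max(2, n %/% 3) + 1):n])
  direction <- if (head_mean >= tail_mean) "decay" else "recovery"
  t0 <- d$t - d$t[1]
  # profiled SSE: for fixed tau, (amplitude, offset) solve linearly
  prof <- function(log_tau) {
    b <- exp(-t0 / exp(log_tau))
    X <- cbind(b, 1)
    co <- tryCatch(qr.coef(qr(X), d$y), error = function(e) c(NA, NA))
    if (any(!is.finite(co))) return(list(sse = Inf, co = co))
    r <- d$y - X %*% co
    list(sse = sum(r^2), co = co)
  }
  span <- diff(range(d$t))
  dt_min <- min(diff(unique(d$t)))
  grid <- exp(seq(log(dt_min / 4), log(span * 20), length.out = 60))
  sses <- vapply(log(grid), function(lt) prof(lt)$sse, numeric(1))
  i <- which.min(sses)
  lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(length(grid), i + 1)])
  opt <- stats::optimize(function(lt) prof(lt)$sse, c(lo, hi), tol = 1e-12)
  tau <- exp(opt$minimum)
  pr <- prof(opt$minimum)
  params <- c(tau = tau, amplitude = unname(pr$co[1]),
              offset = unname(pr$co[2]))
  # standard errors from the Jacobian at the optimum
  b <- exp(-t0 / tau)
  J <- cbind(params["amplitude"] * b * t0 / tau^2, b, 1)
  dof <- n - 3
  se <- rep(NA_real_, 3)
  if (dof > 0) {
    JtJ <- crossprod(J)
    cv <- tryCatch(solve(JtJ) * pr$sse / dof, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  names(se) <- names(params)
  .new_fit("exp_fit", params, se, pr$sse, TRUE,
           list(direction = direction))
}

#' Closed-state stabilization free energy from a G-V shift
#'
#' An inhibitor that shifts the half-activation voltage by `delta_v_half`
#' at (approximately) constant gating charge biases the open/closed
#' equilibrium by `ddG = q_a x delta_v_half`. The product of an
#' elementary charge and a voltage is converted to kcal/mol
#' (1 eV = 23.0609 kcal/mol). Positive values mean the closed state is
#' favoured.
#'
#' @param q_a Apparent gating charge, elementary charges.
#' @param delta_v_half Shift of the half-activation voltage, mV.
#' @param temperature Absolute temperature in kelvin (kept for interface
#'   symmetry; the product `q_a x delta_v_half` is itself the energy).
#' @return Free-energy difference in kcal/mol.
#' @examples
#' closed_state_energy(0.5, 108) # ~1.245 kcal/mol
#' @export
closed_state_energy <- function(q_a, delta_v_half,
                                temperature = .GK_TEMPERATURE_K) {
  stopifnot(temperature > 0)
  q_a * delta_v_half / 1000 * .GK_EV_TO_KCAL_MOL
}

#' Fraction of current remaining after a treatment
#'
#' `i_after / i_before`, the normalization used to express inhibition
#' (`1 - fraction` is the fractional inhibition). Both currents must be
#' measured at the same voltage and agonist condition.
#'
#' @param i_after Current after treatment, pA.
#' @param i_before Current before treatment, pA (non-zero).
#' @return Fraction remaining; the corresponding percent inhibition is
#'   attached as attribute `percent_inhibition`.
#' @examples
#' fraction_remaining(15, 100) # 0.15 (85% inhibition)
#' @export
fraction_remaining <- function(i_after, i_before) {
  if (any(i_before == 0)) stop("i_before must be non-zero")
  if (any(i_after * i_before < 0))
    stop("sign mismatch; check E_rev/voltage")
  f <- i_after / i_before
  attr(f, "percent_inhibition") <- 100 * (1 - f)
  f
}
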