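# Logarithmic dwell-time histograms and exponential-mixture fitting.
#
# Dwell durations are binned on a log10 time axis, where an exponential
# component of time constant tau appears as a skewed bump peaking at
# t = tau; mixtures of two or three such components are fitted by
# weighted least squares.

#' Build a logarithmic dwell-time histogram
#'
#' Collects the dwells of one conductance class into uniform log10-time
#' bins spanning `[min dwell / 2, max dwell x 2]`. Dwells shorter than
#' the idealization dead time (taken from the event list's provenance
#' unless given explicitly) are excluded.
#'
#' @param events An [event_list()], or a plain numeric vector of dwell
#'   durations in seconds (e.g. dwells pooled across sweeps), in which
#'   case `state` is only a label.
#' @param state `"open"` or `"closed"`.
#' @param bins_per_decade Number of bins per decade of time.
#' @param dead_time Exclusion threshold in seconds; defaults to the dead
#'   time recorded by [idealize_half_threshold()], else 0.
#' @return An object of class `dwell_histogram`: list with `state`,
#'   `bin_edges` (log10 s, strictly increasing), `counts`, `n_events`
#'   and `bins_per_decade`. With no qualifying dwells an empty histogram
#'   (`n_events = 0`) is returned.
#' @export
build_log_histogram <- function(events, state = c("closed", "open"),
                                bins_per_decade = 10, dead_time = NULL) {
  stopifnot(bins_per_decade >= 1)
  state <- match.arg(state)
  if (is.numeric(events)) {
    stopifnot(all(events > 0))
    if (is.null(dead_time)) dead_time <- 0
    d <- events[events >= dead_time]
  } else {
    stopifnot(inherits(events, "event_list"))
    if (is.null(dead_time))
      dead_time <- attr(events, "origin")$dead_time %||% 0
    d <- events$duration_s[events$state == state &
                             events$duration_s >= dead_time]
  }
  if (!length(d)) {
    return(structure(list(state = state, bin_edges = numeric(0),
                          counts = integer(0), n_events = 0L,
                          bins_per_decade = bins_per_decade),
                     class = "dwell_histogram"))
  }
  # the lower edge never extends below the dead time: dwells there are
  # censored, and bins the model cannot populate would distort the fit
  lo <- log10(max(min(d) / 2, dead_time))
  hi <- log10(max(d) * 2)
  nbin <- max(1L, ceiling((hi - lo) * bins_per_decade))
  edges <- lo + (0:nbin) / bins_per_decade
  idx <- findInterval(log10(d), edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L; idx[idx > nbin] <- nbin
  counts <- tabulate(idx, nbins = nbin)
  structure(list(state = state, bin_edges = edges, counts = counts,
                 n_events = length(d), bins_per_decade = bins_per_decade),
            class = "dwell_histogram")
}

#' @export
print.dwell_histogram <- function(x, ...) {
  cat("<dwell_histogram> ", x$state, ", ", x$n_events, " events in ",
      length(x$counts), " bins (", x$bins_per_decade,
      "/decade)\n", sep = "")
  invisible(x)
}

# Expected counts per log10 bin for component time constants `taus` and
# component event counts `A` (exact integral of the exponential density
# over each bin).
.mixture_expected <- function(edges, taus, A) {
  lo <- 10^edges[-length(edges)]
  hi <- 10^edges[-1]
  pred <- numeric(length(lo))
  for (i in seq_along(taus))
    pred <- pred + A[i] * (exp(-lo / taus[i]) - exp(-hi / taus[i]))
  pred
}

# Weighted SSE of a parameter vector p = c(log taus, log A).
.mixture_sse <- function(p, hist, n_components) {
  taus <- exp(p[seq_len(n_components)])
  A <- exp(p[n_components + seq_len(n_components)])
  pred <- .mixture_expected(hist$bin_edges, taus, A)
  sum((hist$counts - pred)^2 / pmax(hist$counts, 1))
}

# Start amplitudes for given tau seeds: each bin's counts go to the
# nearest seed on the log-time axis, so a component seeded in a sparse
# tail starts with a realistically small amplitude.
.start_amplitudes <- function(hist, taus) {
  mids <- (hist$bin_edges[-1] +
             hist$bin_edges[-length(hist$bin_edges)]) / 2
  nearest <- vapply(mids, function(m) which.min(abs(m - log10(taus))),
                    integer(1))
  A <- vapply(seq_along(taus), function(i)
    sum(hist$counts[nearest == i]), numeric(1))
  pmax(A, 1)
}

# Approximate dwell-time quantiles from the histogram itself.
.hist_quantiles <- function(hist, probs) {
  mids <- 10^((hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2)
  cum <- cumsum(hist$counts) / sum(hist$counts)
  vapply(probs, function(q) mids[which(cum >= q)[1]], numeric(1))
}

#' Fit a sum of exponential components to a dwell-time histogram
#'
#' Weighted least squares on the log-binned counts: the model for each
#' bin is the exact integral of `sum_i A_i exp(-t/tau_i)/tau_i` over the
#' bin, weighted by `1/max(count, 1)` (square-root-count weighting, the
#' usual variance stabilization for histogram fits). Initialization is a
#' deterministic multi-start over time constants placed at histogram
#' percentiles; the start with the lowest converged SSE wins. Components
#' are reported sorted by time constant with fractional amplitudes
#' summing to one.
#'
#' @param hist A [build_log_histogram()] result with at least
#'   `10 x n_components` events.
#' @param n_components 2 or 3.
#' @param start Optional explicit start, a list with `taus` (s) and
#'   `amplitudes` (fractions); added to the start grid, e.g. to refit
#'   from a previous fit's parameters.
#' @return A `mixture_fit`: list with `taus` (s, ascending),
#'   `amplitudes` (fractional event weights within the binned range,
#'   summing to 1), `component_counts` (events per component),
#'   `scale` (raw per-component scale factors of the fitted model),
#'   `n_components`, `sse`, `converged` and `n_events`. If no start
#'   converges the best-effort parameters are returned with
#'   `converged = FALSE`.
#' @export
fit_exponential_mixture <- function(hist, n_components = 2, start = NULL) {
  stopifnot(inherits(hist, "dwell_histogram"),
            n_components %in% c(2, 3))
  if (hist$n_events < 10 * n_components)
    stop("need at least ", 10 * n_components, " events for ",
         n_components, " components")
  qsets <- if (n_components == 2)
    list(c(0.25, 0.75), c(0.10, 0.90), c(0.10, 0.50), c(0.50, 0.90))
  else
    list(c(0.10, 0.50, 0.90), c(0.05, 0.50, 0.95),
         c(0.25, 0.50, 0.75), c(0.10, 0.30, 0.90))
  p0s <- list()
  if (!is.null(start)) {
    stopifnot(length(start$taus) == n_components,
              length(start$amplitudes) == n_components)
    p0s[[1]] <- c(log(start$taus),
                  log(pmax(start$amplitudes, 1e-12) * hist$n_events))
  }
  best <- NULL; best_sse <- Inf; any_conv <- FALSE
  for (qs in qsets) {
    tau0 <- .hist_quantiles(hist, qs)
    tau0 <- pmax(tau0, 1e-9) * (1 + 1e-6 * seq_along(tau0)) # break ties
    p0s[[length(p0s) + 1]] <-
      c(log(tau0), log(.start_amplitudes(hist, tau0)))
  }
  # starts spread over the binned range, for components that hold little
  # of the total mass (e.g. rare long closures)
  rng <- range(hist$bin_edges)
  for (pos in list(seq(0.2, 0.8, length.out = n_components),
                   seq(0.1, 0.95, length.out = n_components))) {
    tau_rng <- 10^(rng[1] + pos * diff(rng))
    p0s[[length(p0s) + 1]] <-
      c(log(tau_rng), log(.start_amplitudes(hist, tau_rng)))
  }
  for (p0 in p0s) {
    o <- tryCatch(
      stats::optim(p0, .mixture_sse, hist = hist,
                   n_components = n_components, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(o)) next
    conv <- o$convergence == 0
    if (o$value < best_sse) { best <- o; best_sse <- o$value }
    any_conv <- any_conv || conv
  }
  n_components <- as.integer(n_components)
  if (is.null(best)) stop("mixture fit failed from every start")
  taus <- exp(best$par[seq_len(n_components)])
  A <- exp(best$par[n_components + seq_len(n_components)])
  ord <- order(taus)
  # events each component contributes within the binned range; a
  # component pushed outside the range carries (correctly) ~zero weight
  cover <- exp(-10^hist$bin_edges[1] / taus) -
    exp(-10^hist$bin_edges[length(hist$bin_edges)] / taus)
  counts <- A * cover
  structure(list(taus = taus[ord],
                 amplitudes = (counts / sum(counts))[ord],
                 component_counts = counts[ord],
                 scale = A[ord],
                 n_components = n_components, sse = best_sse,
                 converged = any_conv, n_events = hist$n_events),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", x$n_components, " components",
      if (!x$converged) " (NOT converged)", "; sse = ",
      signif(x$sse, 5), "\n", sep = "")
  print(data.frame(tau_s = signif(x$taus, 4),
                   weight = signif(x$amplitudes, 4)))
  invisible(x)
}

#' Choose between two and three exponential components
#'
#' Fits both component counts and keeps three only when it is genuinely
#' warranted: the three-component residual must improve on the
#' two-component one by more than 10% and all three time constants must
#' be mutually separated by at least 0.3 decades. Otherwise two
#' components are kept (parsimony). Both fits are returned so the
#' decision can be audited.
#'
#' @param hist A [build_log_histogram()] result.
#' @return List with `n_components` (2 or 3), `fit` (the chosen
#'   `mixture_fit`), `fit2`, `fit3` and `reason`.
#' @export
select_component_count <- function(hist) {
  fit2 <- fit_exponential_mixture(hist, 2)
  fit3 <- tryCatch(fit_exponential_mixture(hist, 3), error = function(e) NULL)
  if (is.null(fit3)) {
    return(list(n_components = 2L, fit = fit2, fit2 = fit2, fit3 = NULL,
                reason = "too few events for 3 components"))
  }
  sep_ok <- min(diff(sort(log10(fit3$taus)))) >= 0.3
  sse_ok <- fit3$sse < 0.9 * fit2$sse
  if (sep_ok && sse_ok) {
    list(n_components = 3L, fit = fit3, fit2 = fit2, fit3 = fit3,
         reason = "SSE improved >10% with separated components")
  } else {
    reason <- if (!sse_ok) "SSE improvement below 10%" else
      "time constants separated by < 0.3 decades"
    list(n_components = 2L, fit = fit2, fit2 = fit2, fit3 = fit3,
         reason = reason)
  }
}
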