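#' Define a recording protocol
#'
#' A protocol is an ordered list of constant-condition segments plus the
#' acquisition settings of the emulated patch-clamp rig: sampling rate,
#' low-pass filter cutoff, additive Gaussian recording noise and the RNG
#' seed. The same protocol and seed always reproduce the same recording
#' bit for bit.
#'
#' @param segments Data frame with columns `duration_s`, `voltage_mV`,
#'   `capsaicin_uM`, `oa_uM`; one row per constant-condition segment.
#' @param sampling_rate Sampling rate in Hz; must be at least twice the
#'   filter cutoff.
#' @param filter_cutoff Low-pass (-3 dB) cutoff in Hz of the emulated
#'   recording filter.
#' @param noise_sd Standard deviation of additive Gaussian recording
#'   noise, pA.
#' @param seed Integer RNG seed.
#' @param init Initial condition: `NULL` (stationary distribution at the
#'   first segment's conditions), a list with `voltage`, `capsaicin`,
#'   `oa` (stationary distribution at those conditions), a state name, or
#'   a probability vector over states.
#' @return An object of class `gk_protocol`.
#' @examples
#' prot <- protocol(
#'   data.frame(duration_s = 1.2, voltage_mV = 120,
#'              capsaicin_uM = 4, oa_uM = 0),
#'   sampling_rate = 5000, filter_cutoff = 2000, noise_sd = 1, seed = 7)
#' @export
protocol <- function(segments, sampling_rate = 5000, filter_cutoff = 2000,
                     noise_sd = 0, seed = 1, init = NULL) {
  req <- c("duration_s", "voltage_mV", "capsaicin_uM", "oa_uM")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("segments must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(segments) == 0 || any(segments$duration_s <= 0))
    stop("protocol segments must have positive durations")
  if (sampling_rate < 2 * filter_cutoff)
    stop("sampling_rate must be at least 2 x filter_cutoff")
  stopifnot(noise_sd >= 0, length(seed) == 1, is.finite(seed))
  structure(list(segments = segments[, req],
                 sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 init = init),
            class = "gk_protocol")
}

#' @export
print.gk_protocol <- function(x, ...) {
  cat("<gk_protocol> ", nrow(x$segments), " segment(s), total ",
      sum(x$segments$duration_s), " s; fs = ", x$sampling_rate,
      " Hz, fc = ", x$filter_cutoff, " Hz, noise = ", x$noise_sd,
      " pA, seed = ", x$seed, "\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Construct a current trace
#'
#' The in-memory form of a recording: current samples in pA on a uniform
#' time base, plus provenance metadata.
#'
#' @param samples Numeric vector of current values, pA.
#' @param dt Sampling interval in seconds.
#' @param voltage Holding voltage in mV; a scalar, or a per-sample vector
#'   for protocols that change the voltage.
#' @param meta Named list of provenance metadata.
#' @return An object of class `gk_trace`.
#' @export
gk_trace <- function(samples, dt, voltage = NA_real_, meta = list()) {
  stopifnot(is.numeric(samples), all(is.finite(samples)),
            is.numeric(dt), dt > 0)
  structure(list(samples = as.numeric(samples), dt = dt,
                 voltage = voltage, meta = meta),
            class = "gk_trace")
}

#' @export
print.gk_trace <- function(x, ...) {
  cat("<gk_trace> ", length(x$samples), " samples, dt = ", x$dt,
      " s (", signif(length(x$samples) * x$dt, 6), " s total)\n", sep = "")
  invisible(x)
}

#' Split a trace into consecutive fixed-length sweeps
#'
#' @param trace A [gk_trace()].
#' @param sweep_s Sweep length in seconds.
#' @return List of `gk_trace` sweeps; each carries `sweep_start` (s) in
#'   its metadata. A trailing partial sweep is dropped.
#' @export
chop_trace <- function(trace, sweep_s) {
  stopifnot(inherits(trace, "gk_trace"), sweep_s > 0)
  n_per <- round(sweep_s / trace$dt)
  n_sweeps <- length(trace$samples) %/% n_per
  lapply(seq_len(n_sweeps), function(k) {
    idx <- ((k - 1) * n_per + 1):(k * n_per)
    meta <- trace$meta
    meta$sweep_start <- (k - 1) * n_per * trace$dt
    v <- if (length(trace$voltage) > 1) trace$voltage[idx] else trace$voltage
    gk_trace(trace$samples[idx], trace$dt, v, meta)
  })
}
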