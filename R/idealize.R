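# Half-amplitude threshold idealization of single-channel traces.

#' Estimate baseline and open current levels of a trace
#'
#' Builds an all-points current histogram (bin width
#' `max(0.1 pA, 0.05 x span)`), smooths it with a 5-bin moving average and
#' takes the two dominant local maxima as the baseline and open levels.
#' The baseline is the mode closer to 0 pA; the detection threshold is the
#' midpoint of the two levels (half-amplitude criterion). If fewer than
#' two modes are found, or the modes are separated by less than three
#' baseline standard deviations, the trace is reported as containing no
#' openings (this is a result, not an error).
#'
#' @param trace A [gk_trace()] with at least 1000 samples.
#' @return An object of class `amplitude_levels`: list with `baseline`,
#'   `open_level`, `threshold` (all pA; `open_level`/`threshold` are `NA`
#'   when no openings are detected), `baseline_sd` and `has_openings`.
#' @export
estimate_levels <- function(trace) {
  stopifnot(inherits(trace, "gk_trace"))
  x <- trace$samples
  if (length(x) < 1000)
    stop("estimate_levels needs at least 1000 samples")
  span <- diff(range(x))
  no_openings <- function(sd0) {
    structure(list(baseline = stats::median(x), open_level = NA_real_,
                   threshold = NA_real_, baseline_sd = sd0,
                   has_openings = FALSE),
              class = "amplitude_levels")
  }
  if (span == 0) return(no_openings(0))
  bw <- max(0.1, 0.05 * span)
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  padded <- c(0, 0, h$counts, 0, 0)  # keep edge bins eligible as modes
  counts <- as.numeric(stats::filter(padded, rep(1 / 5, 5),
                                     sides = 2))[3:(length(h$counts) + 2)]
  mids <- h$mids
  n <- length(counts)
  is_max <- counts > 0 &
    counts >= c(-Inf, counts[-n]) & counts >= c(counts[-1], -Inf)
  # collapse plateaus of equal smoothed counts to a single mode each,
  # placed at the raw-count maximum within the plateau
  idx <- which(is_max)
  peak_idx <- integer(0)
  if (length(idx)) {
    run <- cumsum(c(1L, diff(idx) > 1))
    peak_idx <- vapply(split(idx, run), function(ii) {
      ii[order(h$counts[ii], decreasing = TRUE)][1]
    }, integer(1))
  }
  if (length(peak_idx) < 2) return(no_openings(stats::sd(x)))
  top2 <- peak_idx[order(counts[peak_idx], decreasing = TRUE)][1:2]
  # refine each mode to the mean of samples within one bin width of it
  levels2 <- vapply(mids[top2], function(m) {
    near <- abs(x - m) <= bw
    if (any(near)) mean(x[near]) else m
  }, numeric(1))
  baseline <- levels2[which.min(abs(levels2))]
  open_level <- levels2[which.max(abs(levels2))]
  # baseline noise from samples nearer the baseline than the open level
  near_base <- abs(x - baseline) < abs(x - open_level)
  baseline_sd <- stats::sd(x[near_base])
  if (!is.finite(baseline_sd)) baseline_sd <- 0
  if (abs(open_level - baseline) < 3 * baseline_sd)
    return(no_openings(baseline_sd))
  structure(list(baseline = baseline, open_level = open_level,
                 threshold = (baseline + open_level) / 2,
                 baseline_sd = baseline_sd, has_openings = TRUE),
            class = "amplitude_levels")
}

#' @export
print.amplitude_levels <- function(x, ...) {
  if (x$has_openings)
    cat("<amplitude_levels> baseline ", signif(x$baseline, 4),
        " pA, open ", signif(x$open_level, 4), " pA, threshold ",
        signif(x$threshold, 4), " pA (sd ", signif(x$baseline_sd, 3),
        ")\n", sep = "")
  else
    cat("<amplitude_levels> no openings detected (baseline ",
        signif(x$baseline, 4), " pA)\n", sep = "")
  invisible(x)
}

# Merge dwells shorter than the dead time into their neighbours,
# shortest first, preserving total duration and alternation.
.apply_dead_time <- function(states, durations, dead_time) {
  repeat {
    if (length(durations) <= 1) break
    short <- which(durations < dead_time)
    if (!length(short)) break
    i <- short[which.min(durations[short])]
    if (i == 1) {
      durations[2] <- durations[2] + durations[1]
      states <- states[-1]; durations <- durations[-1]
    } else if (i == length(durations)) {
      durations[i - 1] <- durations[i - 1] + durations[i]
      states <- states[-i]; durations <- durations[-i]
    } else {
      # absorb into both neighbours, which then merge (same class)
      durations[i - 1] <- durations[i - 1] + durations[i] + durations[i + 1]
      keep <- setdiff(seq_along(durations), c(i, i + 1))
      states <- states[keep]; durations <- durations[keep]
    }
  }
  list(states = states, durations = durations)
}

#' Idealize a trace by half-amplitude threshold crossing
#'
#' Classifies every sample as open or closed against the half-amplitude
#' threshold (samples exactly at threshold count as closed), collapses
#' runs into dwells, and merges dwells shorter than the dead time into
#' their neighbours. Total duration is conserved exactly.
#'
#' @param trace A [gk_trace()].
#' @param levels An [estimate_levels()] result (or compatible list). If
#'   the levels carry no open level, a single all-closed dwell is
#'   returned.
#' @param dead_time Shortest resolvable dwell, in seconds. Defaults to
#'   two sampling intervals.
#' @return An [event_list()].
#' @export
idealize_half_threshold <- function(trace, levels,
                                    dead_time = 2 * trace$dt) {
  stopifnot(inherits(trace, "gk_trace"))
  n <- length(trace$samples)
  if (!isTRUE(levels$has_openings) || !is.finite(levels$threshold))
    return(event_list("closed", n * trace$dt,
                      origin = list(source = "idealization",
                                    note = "no open level defined")))
  sgn <- sign(levels$open_level - levels$baseline)
  is_open <- sgn * (trace$samples - levels$threshold) > 0  # tie -> closed
  r <- rle(is_open)
  states <- ifelse(r$values, "open", "closed")
  durations <- r$lengths * trace$dt
  m <- .apply_dead_time(states, durations, dead_time)
  event_list(m$states, m$durations,
             origin = list(source = "idealization",
                           threshold = levels$threshold,
                           dead_time = dead_time))
}

#' Flag traces containing more than one active channel
#'
#' A second conductance level is evidenced by samples beyond
#' `open_level + (open_level - baseline) / 2` (in the opening direction)
#' sustained for at least a dead time. Flagged traces are excluded from
#' single-channel kinetic analysis.
#'
#' @inheritParams idealize_half_threshold
#' @return `TRUE` if a sustained second level is present.
#' @export
detect_multichannel <- function(trace, levels, dead_time = 2 * trace$dt) {
  stopifnot(inherits(trace, "gk_trace"))
  if (!isTRUE(levels$has_openings)) return(FALSE)
  sgn <- sign(levels$open_level - levels$baseline)
  lim <- levels$open_level + (levels$open_level - levels$baseline) / 2
  beyond <- sgn * (trace$samples - lim) > 0
  r <- rle(beyond)
  any(r$values & r$lengths * trace$dt >= dead_time)
}

#' Open-probability time course across sweeps
#'
#' Computes the per-sweep open probability against application time and,
#' given at least four sweeps, fits a single-exponential relaxation via
#' [fit_single_exponential()].
#'
#' @param sweeps List of [event_list()] objects, one per sweep.
#' @param sweep_times Numeric vector of sweep times in seconds (same
#'   length as `sweeps`).
#' @return List with `timecourse` (data frame `t`, `po`) and `fit` (an
#'   `exp_fit`, or `NULL` when fewer than four sweeps are available or
#'   the time course carries no relaxation).
#' @export
po_timecourse <- function(sweeps, sweep_times) {
  stopifnot(is.list(sweeps), length(sweeps) == length(sweep_times))
  po <- vapply(sweeps, open_probability, numeric(1))
  tc <- data.frame(t = sweep_times, po = po)
  fit <- NULL
  if (length(sweeps) >= 4) {
    fit <- tryCatch(fit_single_exponential(data.frame(t = tc$t, y = tc$po)),
                    error = function(e) NULL)
  }
  list(timecourse = tc, fit = fit)
}
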