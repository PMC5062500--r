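#' Construct an idealized event list
#'
#' An event list is the idealized form of a single-channel trace: an
#' ordered sequence of dwells, each labelled `open` or `closed` with a
#' positive duration. Consecutive dwells of the same class are merged on
#' construction so that labels strictly alternate.
#'
#' @param states Character vector of dwell labels (`"open"`/`"closed"`).
#' @param durations_s Numeric vector of dwell durations in seconds.
#' @param origin Named list of provenance metadata.
#' @return An object of class `event_list`, a data frame with columns
#'   `state` and `duration_s` plus attributes `total_duration` and
#'   `origin`.
#' @export
event_list <- function(states, durations_s, origin = list()) {
  stopifnot(length(states) == length(durations_s),
            all(states %in% c("open", "closed")),
            all(durations_s > 0))
  if (length(states) > 1) {
    grp <- cumsum(c(1L, states[-1] != states[-length(states)]))
    durations_s <- as.numeric(tapply(durations_s, grp, sum))
    states <- states[!duplicated(grp)]
  }
  df <- data.frame(state = states, duration_s = durations_s,
                   stringsAsFactors = FALSE)
  structure(df,
            total_duration = sum(durations_s),
            origin = origin,
            class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  cat("<event_list> ", nrow(x), " dwell(s), ",
      signif(attr(x, "total_duration"), 6), " s total, ",
      sum(x$state == "open"), " open\n", sep = "")
  NextMethod()
}

#' Open probability of an idealized sweep
#'
#' Total open time divided by the sweep duration.
#'
#' @param events An [event_list()].
#' @return Fraction in `[0, 1]`.
#' @export
open_probability <- function(events) {
  stopifnot(inherits(events, "event_list"))
  tot <- attr(events, "total_duration")
  if (tot <= 0) return(0)
  sum(events$duration_s[events$state == "open"]) / tot
}
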