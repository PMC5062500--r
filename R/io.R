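# Plain-text persistence: CSV traces and event lists with JSON metadata
# sidecars. All dialects are comma-separated, header row, UTF-8,
# '.' decimal.

.sidecar_path <- function(path) paste0(sub("\\.[Cc][Ss][Vv]$", "", path),
                                       ".meta.json")

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Write / read a current trace as CSV plus JSON sidecar
#'
#' The trace samples go to a CSV with columns `time_s`, `current_pA`;
#' acquisition metadata (voltage, sampling and filter rates, noise, seed,
#' solution segments) goes to a `.meta.json` sidecar next to it. The
#' round trip is lossless to float precision.
#'
#' @param trace A [gk_trace()].
#' @param path Output CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [gk_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gk_trace"))
  n <- length(trace$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) * trace$dt,
                   current_pA = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- trace$meta
  meta$dt <- trace$dt
  meta$voltage_mV <- trace$voltage
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("time_s", "current_pA"), path)
  meta <- list()
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                     error = function(e)
                       stop("malformed metadata sidecar '", sp, "': ",
                            conditionMessage(e)))
  }
  dt <- meta$dt %||%
    (if (nrow(df) > 1) stats::median(diff(df$time_s)) else
      stop("cannot infer dt from a single sample and no sidecar"))
  voltage <- meta$voltage_mV %||% NA_real_
  meta$dt <- NULL; meta$voltage_mV <- NULL
  if (!is.null(meta$segments)) meta$segments <- as.data.frame(meta$segments)
  gk_trace(df$current_pA, dt, voltage, meta)
}

#' Write / read an idealized event list as CSV
#'
#' Columns `start_s`, `duration_s`, `state`; starts are redundant
#' (cumulative durations) and recomputed on read.
#'
#' @param events An [event_list()].
#' @param path Output CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` an
#'   [event_list()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  df <- data.frame(start_s = cumsum(c(0, events$duration_s))[seq_len(nrow(events))],
                   duration_s = events$duration_s,
                   state = events$state)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("start_s", "duration_s", "state"), path)
  event_list(df$state, df$duration_s, origin = list(source = path))
}

#' Read / write a generic CSV data table
#'
#' Thin wrappers around base CSV I/O that validate required columns and
#' fail with the missing column named.
#'
#' @param path CSV path.
#' @param required Character vector of columns that must be present.
#' @param table Data frame to write.
#' @return `read_table` returns a data frame; `write_table` the path,
#'   invisibly.
#' @export
read_table <- function(path, required = character()) {
  df <- utils::read.csv(path)
  .check_columns(df, required, path)
  df
}

#' @rdname read_table
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
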