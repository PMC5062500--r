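# Orchestration, group statistics and reporting.

#' Summarize replicate groups with pairwise t-tests
#'
#' Reports each group as mean +/- s.e.m. (`sd/sqrt(n)`) and compares all
#' pairs with two-sample t-tests. The unequal-variance (Welch) form is
#' the default; set `paired = TRUE` for before/after designs on the same
#' patches (groups must then have equal lengths). Groups with fewer than
#' two values are excluded with a warning.
#'
#' @param groups Named list of numeric vectors.
#' @param paired Use a paired t-test for the comparisons.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `group_summary`: list with `summary` (data
#'   frame `label`, `n`, `mean`, `sem`) and `comparisons` (data frame
#'   `group1`, `group2`, `t`, `df`, `p`, `significant`).
#' @examples
#' summarize_groups(list(ctrl = c(1, 1.2, 0.9), drug = c(0.2, 0.25, 0.15)))
#' @export
summarize_groups <- function(groups, paired = FALSE, alpha = 0.01) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (!length(groups)) stop("no groups with n >= 2")
  summ <- data.frame(
    label = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1)),
    row.names = NULL)
  cmp <- NULL
  labs <- names(groups)
  if (length(labs) >= 2) {
    pairs <- utils::combn(labs, 2)
    cmp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      tt <- stats::t.test(groups[[a]], groups[[b]], paired = paired,
                          var.equal = FALSE)
      data.frame(group1 = a, group2 = b,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, significant = tt$p.value < alpha)
    }))
  }
  structure(list(summary = summ, comparisons = cmp, paired = paired,
                 alpha = alpha),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> mean +/- s.e.m.",
      if (x$paired) "(paired t-tests)" else "(Welch t-tests)", "\n")
  s <- x$summary
  s$mean <- signif(s$mean, 5); s$sem <- signif(s$sem, 4)
  print(s)
  if (!is.null(x$comparisons)) {
    cat("comparisons (alpha =", x$alpha, "):\n")
    cm <- x$comparisons
    cm$t <- signif(cm$t, 4); cm$df <- signif(cm$df, 4)
    cm$p <- signif(cm$p, 3)
    print(cm)
  }
  invisible(x)
}

# ---- pipeline ----------------------------------------------------------

.pipe_segments <- function(seglist) {
  do.call(rbind, lapply(seglist, function(s)
    data.frame(duration_s = s$duration_s, voltage_mV = s$voltage_mV,
               capsaicin_uM = s$capsaicin_uM, oa_uM = s$oa_uM)))
}

#' Run a configured simulate/idealize/dwell/fit pipeline
#'
#' Executes the requested stages in order, persisting every intermediate
#' artifact (trace CSVs, event CSVs, fit JSONs) under `out_dir` so every
#' reported number is traceable to a file. Re-running the same
#' configuration with the same seed reproduces all numbers exactly.
#'
#' The configuration is a list (or path to a JSON file) with fields
#' `seed`, `out_dir` and `stages`, a list of stage specs executed in
#' order. Supported stages:
#' \describe{
#'   \item{simulate}{fields `scheme` (only `"default"`), `n_channels`,
#'     `segments` (list of segment specs), `sampling_rate`,
#'     `filter_cutoff`, `noise_sd`; produces the working trace (and, for
#'     a single channel, the true events).}
#'   \item{idealize}{optional `sweep_s` to split into sweeps and
#'     `dead_time`; produces event lists and per-sweep open
#'     probabilities from the working trace.}
#'   \item{dwell}{fields `state`, `components` (2, 3 or `"auto"`);
#'     log-histogram and mixture fit of the idealized dwells.}
#'   \item{timecourse_fit}{single-exponential fit of the per-sweep open
#'     probability time course.}
#'   \item{gv_fit}{either `file` (CSV with `voltage_mV`, `conductance`)
#'     or generator fields (`v_half`, `q_a`, `g_max`, `voltages`,
#'     `noise_sd`); Boltzmann fit.}
#'   \item{dose_fit}{either `file` (CSV with `conc_uM`, `inhibited`) or
#'     generator fields (`k_d`, `n_hill`, `concentrations`, `reps`,
#'     `noise_sd`); Hill fit.}
#'   \item{energy}{fields `q_a`, `delta_v_half`; closed-state
#'     stabilization energy.}
#' }
#'
#' @param config Named list or path to a JSON configuration file.
#' @return The report, a named list of per-stage results (also written to
#'   `out_dir/report.json` and a plain-text `out_dir/report.txt`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()
  report <- list(seed = seed, stages = list())
  state <- new.env(parent = emptyenv())
  log_lines <- character()
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
  }

  for (k in seq_along(stages)) {
    sp <- stages[[k]]
    name <- sp$stage %||% stop("stage ", k, " has no 'stage' field")
    tag <- sprintf("%02d_%s", k, name)
    res <- tryCatch(
      switch(name,
        simulate = {
          segs <- .pipe_segments(sp$segments)
          prot <- protocol(segs,
                           sampling_rate = sp$sampling_rate %||% 5000,
                           filter_cutoff = sp$filter_cutoff %||% 2000,
                           noise_sd = sp$noise_sd %||% 0,
                           seed = sp$seed %||% seed)
          scheme <- build_default_scheme()
          n_ch <- sp$n_channels %||% 1
          if (n_ch == 1) {
            rec <- simulate_single_channel(scheme, prot)
            state$trace <- rec$trace
            state$true_events <- rec$events
            write_events(rec$events,
                         file.path(out_dir, paste0(tag, "_true_events.csv")))
          } else {
            state$trace <- simulate_macroscopic(scheme, n_ch, prot)
          }
          write_trace(state$trace, file.path(out_dir, paste0(tag, ".csv")))
          log(tag, ": simulated ", n_ch, " channel(s), seed ",
              prot$seed, ", method ", state$trace$meta$method)
          list(n_samples = length(state$trace$samples),
               method = state$trace$meta$method,
               seed = prot$seed)
        },
        idealize = {
          if (is.null(state$trace)) stop("no trace; run simulate first")
          levels <- estimate_levels(state$trace)
          dead <- sp$dead_time %||% (2 * state$trace$dt)
          if (!is.null(sp$sweep_s)) {
            sweeps <- chop_trace(state$trace, sp$sweep_s)
            evs <- lapply(sweeps, idealize_half_threshold,
                          levels = levels, dead_time = dead)
            state$sweep_events <- evs
            state$sweep_times <- vapply(sweeps, function(s)
              s$meta$sweep_start + sp$sweep_s / 2, numeric(1))
            po <- vapply(evs, open_probability, numeric(1))
            write_table(data.frame(t = state$sweep_times, po = po),
                        file.path(out_dir, paste0(tag, "_po.csv")))
          } else {
            evs <- list(idealize_half_threshold(state$trace, levels,
                                                dead_time = dead))
            state$sweep_events <- evs
            state$sweep_times <- 0
          }
          for (i in seq_along(evs))
            write_events(evs[[i]],
                         file.path(out_dir,
                                   sprintf("%s_events_%03d.csv", tag, i)))
          log(tag, ": dead time ", dead, " s; levels: baseline ",
              signif(levels$baseline, 4), ", open ",
              signif(levels$open_level, 4), "; mean Po ",
              signif(mean(vapply(evs, open_probability, numeric(1))), 4))
          list(n_sweeps = length(evs),
               baseline = levels$baseline, open_level = levels$open_level,
               mean_po = mean(vapply(evs, open_probability, numeric(1))))
        },
        dwell = {
          if (is.null(state$sweep_events)) stop("no events; run idealize first")
          st <- sp$state %||% "closed"
          dwells <- unlist(lapply(state$sweep_events, function(e)
            e$duration_s[e$state == st]))
          if (is.null(dwells) || !length(dwells))
            stop("no '", st, "' dwells available")
          h <- build_log_histogram(dwells, state = st,
                                   bins_per_decade = sp$bins_per_decade %||% 10)
          comp <- sp$components %||% "auto"
          fit <- if (identical(comp, "auto")) {
            sel <- select_component_count(h)
            log(tag, ": auto component count -> ", sel$n_components,
                " (", sel$reason, ")")
            sel$fit
          } else fit_exponential_mixture(h, as.integer(comp))
          jsonlite::write_json(
            list(state = st, taus = fit$taus, amplitudes = fit$amplitudes,
                 sse = fit$sse, converged = fit$converged,
                 n_events = h$n_events,
                 histogram = list(bin_edges = h$bin_edges,
                                  counts = h$counts)),
            file.path(out_dir, paste0(tag, ".json")),
            auto_unbox = TRUE, digits = NA)
          list(state = st, taus = fit$taus, amplitudes = fit$amplitudes,
               n_components = fit$n_components, converged = fit$converged)
        },
        timecourse_fit = {
          if (is.null(state$sweep_events) || length(state$sweep_events) < 4)
            stop("need at least 4 idealized sweeps")
          ptc <- po_timecourse(state$sweep_events, state$sweep_times)
          write_table(ptc$timecourse,
                      file.path(out_dir, paste0(tag, "_po.csv")))
          if (is.null(ptc$fit)) stop("open-probability fit failed")
          list(tau = unname(ptc$fit$params["tau"]),
               amplitude = unname(ptc$fit$params["amplitude"]),
               offset = unname(ptc$fit$params["offset"]),
               direction = ptc$fit$direction,
               converged = ptc$fit$converged)
        },
        gv_fit = {
          gv <- if (!is.null(sp$file))
            read_table(sp$file, c("voltage_mV", "conductance"))
          else
            generate_gv_dataset(sp$v_half, sp$q_a, sp$g_max %||% 1,
                                unlist(sp$voltages),
                                noise_sd = sp$noise_sd %||% 0,
                                seed = sp$seed %||% seed)
          write_table(gv, file.path(out_dir, paste0(tag, "_data.csv")))
          fit <- fit_boltzmann(gv)
          list(g_max = unname(fit$params["g_max"]),
               v_half = unname(fit$params["v_half"]),
               q_a = unname(fit$params["q_a"]),
               converged = fit$converged)
        },
        dose_fit = {
          dr <- if (!is.null(sp$file))
            read_table(sp$file, c("conc_uM", "inhibited"))
          else
            generate_dose_response(sp$k_d, sp$n_hill,
                                   unlist(sp$concentrations),
                                   reps = sp$reps %||% 1,
                                   noise_sd = sp$noise_sd %||% 0,
                                   seed = sp$seed %||% seed)
          write_table(dr, file.path(out_dir, paste0(tag, "_data.csv")))
          fit <- fit_hill(dr)
          list(k_d = unname(fit$params["k_d"]),
               n_hill = unname(fit$params["n_hill"]),
               converged = fit$converged)
        },
        energy = {
          list(ddG_kcal_mol = closed_state_energy(sp$q_a, sp$delta_v_half))
        },
        stop("unknown stage '", name, "'")),
      error = function(e)
        stop("stage '", name, "' (", k, ") failed: ",
             conditionMessage(e), call. = FALSE))
    report$stages[[tag]] <- res
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c(paste0("pipeline run, seed ", seed),
           log_lines,
           vapply(names(report$stages), function(nm) {
             vals <- report$stages[[nm]]
             paste0(nm, ": ",
                    paste(names(vals),
                          vapply(vals, function(v) {
                            v <- unlist(v)
                            if (is.numeric(v)) v <- signif(v, 6)
                            paste(v, collapse = ",")
                          }, character(1)),
                          sep = "=", collapse = "; "))
           }, character(1)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
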