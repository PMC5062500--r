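#' Construct a continuous-time Markov gating scheme
#'
#' A gating scheme bundles the state space of a channel, a generator
#' (rate-matrix) function of the experimental conditions, and the unitary
#' conductance of each state. The rate matrix `Q` returned by
#' `rate_matrix_fn(voltage, capsaicin, oa)` must be a square matrix of
#' transition rates in 1/s with non-negative off-diagonal entries and rows
#' summing to zero (the diagonal holds minus the total exit rate).
#'
#' @param state_names Character vector of state labels.
#' @param rate_matrix_fn Function `(voltage_mV, capsaicin_uM, oa_uM) -> Q`.
#' @param conductance Numeric vector of per-state conductances in pS. At
#'   least one state must conduct and at least one must not.
#' @param temperature Absolute temperature in kelvin.
#' @param e_rev Reversal potential in mV used to convert occupancy to
#'   current.
#' @param params Optional named list of scheme parameters, kept for
#'   provenance.
#' @return An object of class `gating_scheme`.
#' @seealso [build_default_scheme()], [stationary_distribution()]
#' @export
gating_scheme <- function(state_names, rate_matrix_fn, conductance,
                          temperature = .GK_TEMPERATURE_K, e_rev = 0,
                          params = list()) {
  stopifnot(is.character(state_names), length(state_names) >= 2,
            is.function(rate_matrix_fn),
            is.numeric(conductance),
            length(conductance) == length(state_names),
            all(conductance >= 0),
            is.numeric(temperature), temperature > 0)
  if (!any(conductance > 0) || !any(conductance == 0))
    stop("scheme needs at least one conducting and one non-conducting state")
  scheme <- structure(
    list(state_names = state_names,
         rate_matrix_fn = rate_matrix_fn,
         conductance = conductance,
         temperature = temperature,
         e_rev = e_rev,
         params = params),
    class = "gating_scheme")
  # sanity-check the generator at a benign condition
  validate_rate_matrix(rate_matrix(scheme, 0, 0, 0))
  scheme
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("<gating_scheme> ", length(x$state_names), " states: ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  conductance (pS): ", paste(x$conductance, collapse = ", "),
      "; E_rev = ", x$e_rev, " mV; T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Evaluate the generator matrix of a scheme at given conditions
#'
#' @param scheme A [gating_scheme()].
#' @param voltage Membrane potential in mV (|V| <= 200 for physiological
#'   use; larger values are allowed but unchecked).
#' @param capsaicin Capsaicin concentration in uM.
#' @param oa Oleic acid concentration in uM.
#' @return The rate matrix Q (1/s), rows summing to zero.
#' @export
rate_matrix <- function(scheme, voltage, capsaicin, oa) {
  stopifnot(inherits(scheme, "gating_scheme"),
            is.finite(voltage), capsaicin >= 0, oa >= 0)
  Q <- scheme$rate_matrix_fn(voltage, capsaicin, oa)
  validate_rate_matrix(Q)
  Q
}

validate_rate_matrix <- function(Q, tol = 1e-9) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("rate matrix must be square")
  if (!all(is.finite(Q)))
    stop("rate matrix contains non-finite entries")
  off <- Q; diag(off) <- 0
  if (any(off < 0))
    stop("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > tol * max(1, max(abs(Q)))))
    stop("rate-matrix rows must sum to zero")
  invisible(Q)
}

# Strongly connected components of the positive-rate graph, by boolean
# reachability (state spaces here are tiny).
.communicating_classes <- function(Q, tol = 0) {
  n <- nrow(Q)
  A <- (Q > tol); diag(A) <- TRUE
  R <- A
  for (i in seq_len(n)) R <- (R %*% R) > 0   # transitive closure
  mutual <- R & t(R)
  classes <- integer(n); k <- 0L
  for (i in seq_len(n)) {
    if (classes[i] == 0L) {
      k <- k + 1L
      classes[mutual[i, ]] <- k
    }
  }
  classes
}

#' Stationary distribution of a gating scheme
#'
#' Solves pi Q = 0 with sum(pi) = 1 by linear least squares. If the scheme
#' is not ergodic at the given conditions (the positive-rate graph is not
#' strongly connected) the result is flagged and a conditional stationary
#' distribution is reported for every closed communicating class; the
#' overall distribution is still unique (transient states carry zero
#' mass) whenever exactly one closed class exists, and `pi` is reported
#' in that case.
#'
#' @inheritParams rate_matrix
#' @return An object of class `stationary_dist`: a list with `pi` (named
#'   probability vector; `NA` when several closed classes make it
#'   non-unique), `ergodic` (strong-connectivity flag), `p_open` (total
#'   conducting probability, `NA` when `pi` is), and `components`
#'   (per-closed-class conditional distributions when non-ergodic).
#' @examples
#' sch <- build_default_scheme()
#' stationary_distribution(sch, voltage = 120, capsaicin = 4, oa = 0)$p_open
#' @export
stationary_distribution <- function(scheme, voltage, capsaicin, oa) {
  Q <- rate_matrix(scheme, voltage, capsaicin, oa)
  n <- nrow(Q)
  cls <- .communicating_classes(Q)
  # a class is closed if no positive rate leaves it
  closed <- vapply(unique(cls), function(k) {
    idx <- cls == k
    all(Q[idx, !idx, drop = FALSE] <= 0)
  }, logical(1))
  names(closed) <- unique(cls)
  ergodic <- length(unique(cls)) == 1L
  solve_pi <- function(idx) {
    Qs <- Q[idx, idx, drop = FALSE]
    A <- rbind(t(Qs), rep(1, sum(idx)))
    p <- qr.solve(A, c(rep(0, sum(idx)), 1))
    p[p < 0 & p > -1e-12] <- 0
    p / sum(p)
  }
  if (ergodic) {
    p <- solve_pi(rep(TRUE, n))
    names(p) <- scheme$state_names
    structure(list(pi = p, ergodic = TRUE,
                   p_open = sum(p[scheme$conductance > 0]),
                   components = NULL),
              class = "stationary_dist")
  } else {
    comps <- lapply(unique(cls)[closed], function(k) {
      idx <- cls == k
      p <- solve_pi(idx)
      names(p) <- scheme$state_names[idx]
      p
    })
    if (length(comps) == 1) {
      # unique stationary distribution: transient states carry no mass
      p <- rep(0, n); names(p) <- scheme$state_names
      p[names(comps[[1]])] <- comps[[1]]
      structure(list(pi = p, ergodic = FALSE,
                     p_open = sum(p[scheme$conductance > 0]),
                     components = comps),
                class = "stationary_dist")
    } else {
      pi_na <- rep(NA_real_, n); names(pi_na) <- scheme$state_names
      structure(list(pi = pi_na, ergodic = FALSE, p_open = NA_real_,
                     components = comps),
                class = "stationary_dist")
    }
  }
}

#' @export
print.stationary_dist <- function(x, ...) {
  if (x$ergodic) {
    cat("<stationary_dist> ergodic; P(open) =", signif(x$p_open, 4), "\n")
    print(signif(x$pi, 4))
  } else if (!any(is.na(x$pi))) {
    cat("<stationary_dist> unique (some states transient); P(open) =",
        signif(x$p_open, 4), "\n")
    print(signif(x$pi, 4))
  } else {
    cat("<stationary_dist> NON-ergodic;", length(x$components),
        "closed communicating class(es)\n")
    for (p in x$components) print(signif(p, 4))
  }
  invisible(x)
}
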