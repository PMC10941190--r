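# Two-state first-order exchange kinetics from binary state traces.

#' Extract dwell times from a state trace
#'
#' Converts maximal constant-state runs into durations (run length times
#' the frame spacing). The first and last runs touch the trajectory
#' boundary and are flagged censored: their true durations are only known
#' to exceed the observed ones.
#'
#' @param states a `state_trace` (uniform frame spacing required) or a 0/1
#'   vector combined with `dt`.
#' @param dt frame spacing in ps; inferred from the trace times when
#'   omitted.
#' @return list of class `dwell_times`: `hb`, `non` (durations, ps),
#'   `hb_censored`, `non_censored` (logical), and `dt`.
#' @export
extract_dwells <- function(states, dt = NULL) {
  if (inherits(states, "state_trace")) {
    tt <- states$times
    if (length(tt) >= 2) {
      steps <- diff(tt)
      if (any(abs(steps - steps[1]) > 1e-9 * max(steps[1], 1))) {
        stop("state trace has non-uniform frame spacing")
      }
      if (is.null(dt)) dt <- steps[1]
    }
    s <- states$states
  } else {
    s <- as.integer(states)
  }
  if (length(s) < 2) stop("need >= 2 frames to extract dwells")
  if (is.null(dt) || dt <= 0) stop("frame spacing `dt` must be > 0")
  r <- rle(s)
  dur <- r$lengths * dt
  censored <- seq_along(dur) %in% c(1L, length(dur))
  hb <- r$values == 1L
  structure(list(hb = dur[hb], non = dur[!hb],
                 hb_censored = censored[hb], non_censored = censored[!hb],
                 dt = dt),
            class = "dwell_times")
}

#' @export
print.dwell_times <- function(x, ...) {
  cat(sprintf(
    "dwell_times: %d H-bonded (%d censored), %d non-H-bonded (%d censored), dt = %g ps\n",
    length(x$hb), sum(x$hb_censored), length(x$non), sum(x$non_censored),
    x$dt))
  invisible(x)
}

exp_lifetime <- function(dur, censored, method) {
  if (method == "mean") {
    d <- dur[!censored]
    if (length(d) == 0) {
      stop("insufficient-events: no uncensored dwells for this state")
    }
    mean(d)
  } else {
    # exponential MLE with right censoring: total observed time over the
    # number of completed (uncensored) events
    nev <- sum(!censored)
    if (nev == 0) {
      stop("insufficient-events: no completed dwells for this state")
    }
    sum(dur) / nev
  }
}

#' Fit the two-state exchange model to dwell times
#'
#' Estimates the H-bonded and non-H-bonded lifetimes and derives the
#' one-way rates `k = 1/tau` and the two-state relaxation (exchange) rate
#' `k_exchange = 1/tau_hb + 1/tau_non`. The `"mean"` method averages
#' uncensored dwells only; `"censored-mle"` is the exponential maximum
#' likelihood estimate treating boundary dwells as right-censored (total
#' observed time divided by completed events), which coincides with the
#' mean method when nothing is censored.
#'
#' @param dwells a `dwell_times` object.
#' @param method `"mean"` or `"censored-mle"`.
#' @return list of class `exchange_model`: `tau_hb`, `tau_non` (ps),
#'   `k_hb_to_non`, `k_non_to_hb`, `k_exchange` (ps^-1), `method`, event
#'   counts.
#' @export
fit_lifetimes <- function(dwells, method = c("mean", "censored-mle")) {
  method <- match.arg(method)
  stopifnot(inherits(dwells, "dwell_times"))
  tau_hb <- exp_lifetime(dwells$hb, dwells$hb_censored, method)
  tau_non <- exp_lifetime(dwells$non, dwells$non_censored, method)
  structure(list(
    tau_hb = tau_hb, tau_non = tau_non,
    k_hb_to_non = 1 / tau_hb, k_non_to_hb = 1 / tau_non,
    k_exchange = 1 / tau_hb + 1 / tau_non,
    method = method,
    n_hb = sum(!dwells$hb_censored), n_non = sum(!dwells$non_censored)
  ), class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf("exchange_model (%s)\n", x$method))
  cat(sprintf("  tau_hb  = %.3g ps  (k = %.3g ps^-1, %d events)\n",
              x$tau_hb, x$k_hb_to_non, x$n_hb))
  cat(sprintf("  tau_non = %.3g ps  (k = %.3g ps^-1, %d events)\n",
              x$tau_non, x$k_non_to_hb, x$n_non))
  cat(sprintf("  k_exchange = %.3g ps^-1\n", x$k_exchange))
  cat(sprintf("  predicted H-bonded fraction = %.1f %%\n",
              predicted_fraction(x)))
  invisible(x)
}

#' Equilibrium H-bonded fraction predicted by an exchange model
#'
#' For first-order two-state exchange the stationary H-bonded occupancy is
#' `tau_hb / (tau_hb + tau_non)`.
#'
#' @param model an `exchange_model`.
#' @return predicted fraction in percent.
#' @export
predicted_fraction <- function(model) {
  stopifnot(inherits(model, "exchange_model"))
  100 * model$tau_hb / (model$tau_hb + model$tau_non)
}

#' Root-mean-square deviation between predicted and observed fractions
#'
#' @param predicted,observed numeric vectors of percentages, equal length.
#' @return RMSD in percentage points.
#' @export
fraction_rmsd <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Classify the exchange regime against vibrational dephasing
#'
#' Compares the exchange rate with the inverse of a dephasing time (default
#' 4 ps, a typical nitrile value): exchange much faster than dephasing
#' collapses two bands into one at the population-weighted frequency.
#'
#' @param k_exchange exchange rate in ps^-1 (or an `exchange_model`).
#' @param dephasing_time vibrational dephasing time in ps.
#' @return `"fast"`, `"intermediate"` or `"slow"`.
#' @export
exchange_regime <- function(k_exchange, dephasing_time = 4) {
  if (inherits(k_exchange, "exchange_model")) {
    k_exchange <- k_exchange$k_exchange
  }
  ratio <- k_exchange * dephasing_time
  if (ratio > 1) "fast" else if (ratio > 0.2) "intermediate" else "slow"
}
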