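# Comparison of experimentally derived (TDM-based) and simulation-derived
# projected nitrile fields: linear TDM calibration, calibration-transfer
# offset lines, and errors-in-both-variables (York) weighted regression
# with pointwise 2-sigma confidence bands.

#' Linear TDM-field calibration
#'
#' The transition dipole observable is modeled as an affine function of the
#' projected field, `tdm = slope * F + intercept`; inverting it converts a
#' measured TDM value into an experimental field.
#'
#' @param slope calibration slope (TDM units per MV/cm), nonzero.
#' @param intercept calibration intercept (TDM units).
#' @param source `"FC"` or `"POL"`, the parameter-set family the
#'   calibration was built with.
#' @return list of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept, source = c("FC", "POL")) {
  source <- match.arg(source)
  if (slope == 0) stop("calibration slope must be nonzero")
  structure(list(slope = slope, intercept = intercept, source = source),
            class = "calibration_line")
}

#' Convert a TDM observable to a field
#'
#' @param tdm TDM-proportional value(s).
#' @param calibration a [calibration_line].
#' @return field(s) in MV/cm: `(tdm - intercept) / slope`.
#' @export
tdm_to_field <- function(tdm, calibration) {
  stopifnot(inherits(calibration, "calibration_line"))
  (tdm - calibration$intercept) / calibration$slope
}

#' Calibration-transfer offsets between small-molecule and in-protein probes
#'
#' Transferring a small-molecule TDM-field calibration to a probe covalently
#' attached to a protein leaves a constant field offset per parameter-set
#' family. The defaults are the offsets used throughout this package:
#' 6.4 MV/cm for the fixed-charge family and 4.1 MV/cm for the polarizable
#' family.
#'
#' @param offset_fc,offset_pol offsets in MV/cm.
#' @return list of class `offset_spec`.
#' @export
offset_spec <- function(offset_fc = 6.4, offset_pol = 4.1) {
  structure(list(FC = offset_fc, POL = offset_pol), class = "offset_spec")
}

#' Ideal-correlation reference line for a parameter-set family
#'
#' The line of perfect agreement between TDM-derived and simulated fields:
#' unit slope, shifted down by the calibration-transfer offset, i.e.
#' `F_MD = F_TDM - offset`.
#'
#' @param offsets an [offset_spec].
#' @param source `"FC"` or `"POL"`.
#' @return list with `slope` (1) and `intercept` (-offset), class
#'   `reference_line`.
#' @export
reference_line <- function(offsets = offset_spec(), source = c("FC", "POL")) {
  source <- match.arg(source)
  stopifnot(inherits(offsets, "offset_spec"))
  structure(list(slope = 1, intercept = -offsets[[source]], source = source),
            class = "reference_line")
}

#' Assemble TDM-vs-simulation comparison points
#'
#' @param f_tdm,f_md fields in MV/cm (x and y of the comparison).
#' @param sd_tdm,sd_md positive 1-sigma uncertainties.
#' @param label point labels.
#' @return data frame of class `comparison_points` with columns `x`, `sx`,
#'   `y`, `sy`, `label`.
#' @export
comparison_points <- function(f_tdm, f_md, sd_tdm, sd_md, label = NULL) {
  n <- length(f_tdm)
  stopifnot(length(f_md) == n)
  sd_tdm <- rep_len(sd_tdm, n)
  sd_md <- rep_len(sd_md, n)
  if (any(sd_tdm <= 0) || any(sd_md <= 0)) {
    stop("uncertainties must be > 0 for regression use")
  }
  if (is.null(label)) label <- paste0("p", seq_len(n))
  out <- data.frame(x = f_tdm, sx = sd_tdm, y = f_md, sy = sd_md,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("comparison_points", "data.frame")
  out
}

#' Errors-in-both-variables weighted straight-line fit (York)
#'
#' Iterative least squares with per-point weights
#' `W_i = 1 / (sy_i^2 + b^2 sx_i^2)` (uncorrelated x/y errors), the unified
#' York formulation: the slope is refined from the weighted deviations
#' until it changes by less than `tol`, and parameter uncertainties and
#' covariance come from the standard York variance expressions built on the
#' adjusted abscissae.
#'
#' @param points a [comparison_points] data frame (or any data frame with
#'   columns `x`, `sx`, `y`, `sy`), `n >= 3`.
#' @param tol convergence threshold on the slope change.
#' @param max_iter iteration cap.
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `sigma_slope`, `sigma_intercept`, `covariance` (2x2 matrix for
#'   (intercept, slope)), `n`, `iterations`, `method`.
#' @export
york_regression <- function(points, tol = 1e-10, max_iter = 200L) {
  x <- points$x; y <- points$y; sx <- points$sx; sy <- points$sy
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (any(sx <= 0) || any(sy <= 0)) stop("errors must be positive")
  if (diff(range(x)) == 0) stop("degenerate x spread")
  wx <- 1 / sx^2
  wy <- 1 / sy^2
  b <- stats::coef(stats::lm(y ~ x))[[2]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    W <- wx * wy / (wx + b^2 * wy)
    xbar <- sum(W * x) / sum(W)
    ybar <- sum(W * y) / sum(W)
    U <- x - xbar
    V <- y - ybar
    beta <- W * (U / wy + b * V / wx)
    bnew <- sum(W * beta * V) / sum(W * beta * U)
    if (!is.finite(bnew)) stop("York iteration diverged")
    done <- abs(bnew - b) < tol
    b <- bnew
    if (done || iter >= max_iter) break
  }
  if (iter >= max_iter && !done) {
    stop(sprintf("York regression did not converge in %d iterations",
                 max_iter))
  }
  W <- wx * wy / (wx + b^2 * wy)
  xbar <- sum(W * x) / sum(W)
  ybar <- sum(W * y) / sum(W)
  U <- x - xbar
  V <- y - ybar
  beta <- W * (U / wy + b * V / wx)
  a <- ybar - b * xbar
  xadj <- xbar + beta
  xadj_bar <- sum(W * xadj) / sum(W)
  u <- xadj - xadj_bar
  var_b <- 1 / sum(W * u^2)
  var_a <- 1 / sum(W) + xadj_bar^2 * var_b
  cov_ab <- -xadj_bar * var_b
  covm <- matrix(c(var_a, cov_ab, cov_ab, var_b), 2, 2,
                 dimnames = list(c("intercept", "slope"),
                                 c("intercept", "slope")))
  structure(list(slope = b, intercept = a,
                 sigma_slope = sqrt(var_b), sigma_intercept = sqrt(var_a),
                 covariance = covm, n = n, iterations = iter,
                 method = "york"),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression (n = %d)\n", x$method, x$n))
  cat(sprintf("  slope     = %.4f +/- %.4f\n", x$slope, x$sigma_slope))
  cat(sprintf("  intercept = %.2f +/- %.2f MV/cm\n",
              x$intercept, x$sigma_intercept))
  invisible(x)
}

#' Alternative weighted straight-line fits
#'
#' Companion estimators to [york_regression] for sensitivity reporting:
#' `"deming"` (errors in both variables with the variance ratio fixed by
#' the mean squared uncertainties) and `"wls-y"` (weights `1/sy^2`,
#' x treated as exact).
#'
#' @inheritParams york_regression
#' @param method `"deming"` or `"wls-y"`.
#' @return a `regression_result` (Deming uncertainties via jackknife).
#' @export
alt_regression <- function(points, method = c("deming", "wls-y")) {
  method <- match.arg(method)
  x <- points$x; y <- points$y; sy <- points$sy
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (method == "wls-y") {
    w <- 1 / sy^2
    fit <- stats::lm(y ~ x, weights = w)
    sm <- summary(fit)
    covm <- stats::vcov(fit)
    dimnames(covm) <- list(c("intercept", "slope"), c("intercept", "slope"))
    res <- list(slope = stats::coef(fit)[[2]],
                intercept = stats::coef(fit)[[1]],
                sigma_slope = sm$coefficients[2, 2],
                sigma_intercept = sm$coefficients[1, 2],
                covariance = covm, n = n, iterations = 1L,
                method = "wls-y")
  } else {
    deming_est <- function(x, y, lambda) {
      sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
      b <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
        (2 * sxy)
      c(slope = b, intercept = mean(y) - b * mean(x))
    }
    lambda <- mean(points$sy^2) / mean(points$sx^2)
    est <- deming_est(x, y, lambda)
    jack <- vapply(seq_len(n), function(i) {
      deming_est(x[-i], y[-i], lambda)
    }, numeric(2))
    jse <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
    covm <- matrix(c(jse[2]^2, 0, 0, jse[1]^2), 2, 2,
                   dimnames = list(c("intercept", "slope"),
                                   c("intercept", "slope")))
    res <- list(slope = unname(est["slope"]),
                intercept = unname(est["intercept"]),
                sigma_slope = unname(jse[1]),
                sigma_intercept = unname(jse[2]),
                covariance = covm, n = n, iterations = 1L,
                method = "deming")
  }
  structure(res, class = "regression_result")
}

#' Side-by-side report of regression variants
#'
#' Fits the York, Deming and weighted-y estimators to the same comparison
#' points, for judging how sensitive the slope/intercept are to the
#' weighting scheme.
#'
#' @inheritParams york_regression
#' @return data frame with one row per variant.
#' @export
regression_variants <- function(points) {
  fits <- list(york_regression(points),
               alt_regression(points, "deming"),
               alt_regression(points, "wls-y"))
  do.call(rbind, lapply(fits, function(f) {
    data.frame(method = f$method, slope = f$slope,
               sigma_slope = f$sigma_slope, intercept = f$intercept,
               sigma_intercept = f$sigma_intercept,
               stringsAsFactors = FALSE)
  }))
}

#' Pointwise 2-sigma confidence band of a fitted line
#'
#' Half-width at abscissa x is
#' `2 * sqrt(Var[a] + 2 x Cov[a, b] + x^2 Var[b])`, from the parameter
#' covariance of the fit (pointwise, not simultaneous). With
#' `use_covariance = FALSE` the cross term is dropped, treating slope and
#' intercept as independent; that envelope is wider inside the data range
#' and is the construction that matches bands commonly drawn around
#' uncentered slope/intercept pairs.
#'
#' @param result a `regression_result`.
#' @param xs abscissae (MV/cm).
#' @param use_covariance include the intercept-slope covariance term
#'   (default `TRUE`).
#' @return data frame with `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(result, xs, use_covariance = TRUE) {
  stopifnot(inherits(result, "regression_result"))
  cv <- result$covariance
  cross <- if (use_covariance) cv[1, 2] else 0
  fit <- result$intercept + result$slope * xs
  hw <- 2 * sqrt(cv[1, 1] + 2 * xs * cross + xs^2 * cv[2, 2])
  data.frame(x = xs, fit = fit, lower = fit - hw, upper = fit + hw)
}

#' Does a reference line lie inside the 2-sigma band?
#'
#' @param result a `regression_result`.
#' @param line a [reference_line] (or any list with `slope`/`intercept`).
#' @param xs abscissae to test, typically spanning the data's x range.
#' @param use_covariance passed to [confidence_band].
#' @return list with `inside` (logical per x) and `verdict` (`TRUE` when
#'   inside everywhere).
#' @export
line_in_band <- function(result, line, xs, use_covariance = TRUE) {
  band <- confidence_band(result, xs, use_covariance = use_covariance)
  yl <- line$intercept + line$slope * xs
  inside <- yl >= band$lower & yl <= band$upper
  list(inside = inside, verdict = all(inside))
}
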