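# 2D H-bond geometry histograms (theta_CNX vs d_NX) and Gaussian-surface
# fits extracting average angles, distances and widths.

#' 2D histogram of H-bond geometry samples
#'
#' Bins `(theta, d)` pairs on a regular grid and normalizes the counts to
#' unit maximum, the convention used for contour plots of H-bond geometry.
#' Samples outside the stated ranges are dropped (with a note in the
#' `n_dropped` attribute).
#'
#' @param samples data frame with columns `theta` (deg) and `d` (Angstrom),
#'   e.g. from [gen_geometry_samples] or the records of [classify_trace].
#' @param theta_bin,d_bin bin widths (default 2 deg and 0.05 A).
#' @param theta_range,d_range histogram ranges (default 90-180 deg and
#'   2.5-4.0 A, the ranges over which nitrile H-bond geometries
#'   concentrate).
#' @return list of class `histogram2d`: `theta_edges`, `d_edges`,
#'   `theta_mids`, `d_mids`, `counts` (normalized, unit max), `raw_counts`,
#'   `n`.
#' @export
hist2d <- function(samples, theta_bin = 2, d_bin = 0.05,
                   theta_range = c(90, 180), d_range = c(2.5, 4.0)) {
  if (nrow(samples) == 0) stop("`samples` must be nonempty")
  if (theta_bin <= 0 || d_bin <= 0) stop("bin widths must be > 0")
  theta_edges <- seq(theta_range[1], theta_range[2], by = theta_bin)
  d_edges <- seq(d_range[1], d_range[2], by = d_bin)
  it <- findInterval(samples$theta, theta_edges, rightmost.closed = TRUE)
  id <- findInterval(samples$d, d_edges, rightmost.closed = TRUE)
  ok <- it >= 1 & it <= length(theta_edges) - 1 &
    id >= 1 & id <= length(d_edges) - 1
  counts <- matrix(0L, length(theta_edges) - 1, length(d_edges) - 1)
  tab <- table(factor(it[ok], levels = seq_len(nrow(counts))),
               factor(id[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  if (max(counts) == 0) stop("no samples fall inside the histogram ranges")
  structure(list(
    theta_edges = theta_edges, d_edges = d_edges,
    theta_mids = theta_edges[-1] - theta_bin / 2,
    d_mids = d_edges[-1] - d_bin / 2,
    counts = counts / max(counts), raw_counts = counts,
    n = sum(counts)
  ), class = "histogram2d")
}

gauss_surface <- function(theta, d, amplitude, theta0, d0, sigma_theta,
                          sigma_d, rho, baseline) {
  zt <- (theta - theta0) / sigma_theta
  zd <- (d - d0) / sigma_d
  baseline + amplitude *
    exp(-(zt^2 - 2 * rho * zt * zd + zd^2) / (2 * (1 - rho^2)))
}

#' Fit a Gaussian surface to a 2D geometry histogram
#'
#' Nonlinear least squares of a bivariate Gaussian (optional correlation
#' term, optional flat baseline) to the normalized bin counts, initialized
#' from the histogram's weighted moments. The fitted `theta0` / `d0` are
#' the average H-bond angle and distance; `sigma_theta` / `sigma_d` are the
#' distribution widths.
#'
#' @param hist a `histogram2d`.
#' @param with_rho include a correlation parameter (default `FALSE`).
#' @param with_baseline include a flat baseline (default `TRUE`).
#' @return list of class `gaussian_surface_fit`: `amplitude`, `theta0`,
#'   `d0`, `sigma_theta`, `sigma_d`, `rho`, `baseline`, `rms_residual`,
#'   standard errors where estimable, and the `nls` fit object.
#' @export
fit_surface <- function(hist, with_rho = FALSE, with_baseline = TRUE) {
  stopifnot(inherits(hist, "histogram2d"))
  df <- expand.grid(theta = hist$theta_mids, d = hist$d_mids)
  df$z <- as.vector(hist$counts)
  n_par <- 5 + with_rho + with_baseline
  informative <- sum(df$z > 0.01)
  if (informative < n_par + 1) {
    stop(sprintf("too few informative bins (%d) for a %d-parameter surface",
                 informative, n_par))
  }
  # moment-based initialization
  w <- df$z / sum(df$z)
  t0 <- sum(w * df$theta)
  d0 <- sum(w * df$d)
  st <- sqrt(max(sum(w * (df$theta - t0)^2), 1e-6))
  sd0 <- sqrt(max(sum(w * (df$d - d0)^2), 1e-8))
  start <- list(amplitude = max(df$z), theta0 = t0, d0 = d0,
                sigma_theta = st, sigma_d = sd0)
  lower <- c(amplitude = 1e-6, theta0 = min(df$theta), d0 = min(df$d),
             sigma_theta = 1e-3, sigma_d = 1e-5)
  upper <- c(amplitude = Inf, theta0 = max(df$theta), d0 = max(df$d),
             sigma_theta = diff(range(df$theta)),
             sigma_d = diff(range(df$d)))
  form <- "z ~ gauss_surface(theta, d, amplitude, theta0, d0, sigma_theta, sigma_d, %s, %s)"
  if (with_rho) {
    start$rho <- 0
    lower <- c(lower, rho = -0.95)
    upper <- c(upper, rho = 0.95)
  }
  if (with_baseline) {
    start$baseline <- 0
    lower <- c(lower, baseline = -Inf)
    upper <- c(upper, baseline = Inf)
  }
  formula <- stats::as.formula(sprintf(
    form, if (with_rho) "rho" else "0",
    if (with_baseline) "baseline" else "0"))
  fit <- minpack.lm::nlsLM(formula, data = df, start = start,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(
    amplitude = unname(cf["amplitude"]),
    theta0 = unname(cf["theta0"]), d0 = unname(cf["d0"]),
    sigma_theta = unname(cf["sigma_theta"]),
    sigma_d = unname(cf["sigma_d"]),
    rho = if (with_rho) unname(cf["rho"]) else 0,
    baseline = if (with_baseline) unname(cf["baseline"]) else 0,
    rms_residual = sqrt(mean(stats::resid(fit)^2)),
    se = se, fit = fit
  ), class = "gaussian_surface_fit")
}

#' @export
print.gaussian_surface_fit <- function(x, ...) {
  cat("gaussian_surface_fit\n")
  cat(sprintf("  center: theta0 = %.1f deg, d0 = %.3f A\n", x$theta0, x$d0))
  cat(sprintf("  widths: sigma_theta = %.1f deg, sigma_d = %.3f A, rho = %.2f\n",
              x$sigma_theta, x$sigma_d, x$rho))
  cat(sprintf("  baseline = %.3g, rms residual = %.3g\n",
              x$baseline, x$rms_residual))
  invisible(x)
}

#' Ratio of angular widths of two Gaussian-surface fits
#'
#' @param fit_a,fit_b `gaussian_surface_fit` objects.
#' @return `sigma_theta(a) / sigma_theta(b)`.
#' @export
width_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "gaussian_surface_fit"),
            inherits(fit_b, "gaussian_surface_fit"))
  fit_a$sigma_theta / fit_b$sigma_theta
}
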