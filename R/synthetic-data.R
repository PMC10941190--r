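# Synthetic-data generators: two-state switching traces with
# state-conditional fields, toy probe/donor scenes, H-bond geometry samples
# and multi-band IR spectra. Every generator takes an explicit integer seed
# and is bit-reproducible; none touches the caller's RNG state.

#' Parameters of a two-state H-bond switching process
#'
#' Describes a nitrile that alternates between an H-bonded and a free
#' (non-H-bonded) state with exponentially distributed dwell times, and
#' whose projected field is drawn from a state-conditional Gaussian.
#'
#' @param tau_hb,tau_non mean dwell times of the H-bonded / non-H-bonded
#'   state (ps), `> 0`.
#' @param field_hb_mean,field_hb_sd H-bonded field distribution (MV/cm).
#' @param field_non_mean,field_non_sd non-H-bonded field distribution
#'   (MV/cm). Standard deviations must be `>= 0`.
#' @param dt frame spacing (ps), `> 0`.
#' @param seed integer seed used by the generators.
#' @return list of class `switching_params`.
#' @export
switching_params <- function(tau_hb, tau_non,
                             field_hb_mean = -60, field_hb_sd = 10,
                             field_non_mean = -20, field_non_sd = 8,
                             dt = 0.1, seed = 1L) {
  if (tau_hb <= 0 || tau_non <= 0) stop("dwell time means must be > 0")
  if (dt <= 0) stop("`dt` must be > 0")
  if (field_hb_sd < 0 || field_non_sd < 0) stop("field sds must be >= 0")
  structure(list(tau_hb = tau_hb, tau_non = tau_non,
                 field_hb_mean = field_hb_mean, field_hb_sd = field_hb_sd,
                 field_non_mean = field_non_mean,
                 field_non_sd = field_non_sd,
                 dt = dt, seed = as.integer(seed)),
            class = "switching_params")
}

#' Generate a binary H-bond state trace
#'
#' Samples alternating H-bonded / non-H-bonded dwell segments with
#' exponentially distributed durations (means `tau_hb`, `tau_non`) in
#' continuous time, then discretizes at frame spacing `dt`: frame k carries
#' the state occupied at time `k * dt`. Dwells shorter than `dt` can vanish
#' from the discretized trace, which mirrors the sampling bias of
#' finite-interval trajectory output. The initial state is drawn from the
#' stationary distribution `tau_hb / (tau_hb + tau_non)`.
#'
#' @param params a [switching_params] object.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; defaults to `params$seed`.
#' @return An object of class `state_trace`: list with `times` (ps) and
#'   integer `states` (1 = H-bonded, 0 = non-H-bonded). The continuous
#'   dwell durations actually sampled and the initial state are attached
#'   as attributes `dwells` and `start_hb` for diagnostics.
#' @export
gen_state_trace <- function(params, n_frames, seed = params$seed) {
  stopifnot(inherits(params, "switching_params"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2) stop("`n_frames` must be >= 2")
  total <- n_frames * params$dt
  withr::with_seed(as.integer(seed), {
    start_hb <- stats::runif(1) < params$tau_hb / (params$tau_hb + params$tau_non)
    # draw dwells in blocks until the trajectory length is covered
    mean_pair <- params$tau_hb + params$tau_non
    dwells <- numeric(0)
    while (sum(dwells) < total) {
      nblk <- max(64L, ceiling(2 * (total - sum(dwells)) / mean_pair) * 2L)
      first_hb <- if (length(dwells) == 0) start_hb
                  else (length(dwells) %% 2 == 0) == start_hb
      means <- rep_len(if (first_hb) c(params$tau_hb, params$tau_non)
                       else c(params$tau_non, params$tau_hb), nblk)
      dwells <- c(dwells, stats::rexp(nblk, rate = 1 / means))
    }
  })
  bounds <- cumsum(dwells)
  times <- seq_len(n_frames) * params$dt
  seg <- findInterval(times, bounds, left.open = TRUE) # 0-based segment index
  seg_hb <- if (start_hb) seg %% 2 == 0 else seg %% 2 == 1
  out <- structure(list(times = times, states = as.integer(seg_hb)),
                   class = "state_trace")
  # continuous-time ground truth, kept for diagnostics: the sampled dwell
  # durations (before discretization) and the initial state
  used <- min(which(bounds >= total))
  attr(out, "dwells") <- dwells[seq_len(used)]
  attr(out, "start_hb") <- start_hb
  out
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("state_trace: %d frames, dt = %g ps, H-bonded occupancy %.3f\n",
              length(x$states), x$times[2] - x$times[1], mean(x$states)))
  invisible(x)
}

#' Generate a field trace conditioned on a state trace
#'
#' Each frame's projected field is drawn independently from its state's
#' Gaussian, so the marginal distribution is the two-component mixture with
#' weights given by the state occupancies.
#'
#' @param states a `state_trace`.
#' @param params a [switching_params] object.
#' @param seed integer seed; defaults to `params$seed + 1` so that the
#'   state and field streams of one parameter set are decoupled.
#' @return An object of class `field_trace`: list with `times` and `fields`
#'   (MV/cm).
#' @export
gen_field_trace <- function(states, params, seed = params$seed + 1L) {
  stopifnot(inherits(states, "state_trace"),
            inherits(params, "switching_params"))
  n <- length(states$states)
  if (n == 0) stop("empty state trace")
  mean_v <- ifelse(states$states == 1L, params$field_hb_mean,
                   params$field_non_mean)
  sd_v <- ifelse(states$states == 1L, params$field_hb_sd,
                 params$field_non_sd)
  fields <- withr::with_seed(as.integer(seed), stats::rnorm(n, mean_v, sd_v))
  structure(list(times = states$times, fields = fields),
            class = "field_trace")
}

#' Specify a toy probe + donor scene
#'
#' Geometry of a single H-bond donor placed near a nitrile probe, in the
#' three descriptors used throughout: the N-to-heavy-atom distance `d_nx`,
#' the C=N...X angle `theta_cnx` (vertex at N) and the N...X-H angle
#' `theta_nxh` (vertex at X).
#'
#' @param d_nx donor heavy atom to nitrile N distance (Angstrom), `> 0`.
#' @param theta_cnx C=N...X angle in degrees, in `[0, 180]`.
#' @param theta_nxh N...X-H angle in degrees, in `[0, 180]`.
#' @param donor_class `"solvent"` or `"protein"`.
#' @param parameter_level `"charges-only"`, `"multipoles"` or
#'   `"multipoles+polarizabilities"`.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(d_nx, theta_cnx = 180, theta_nxh = 0,
                       donor_class = c("solvent", "protein"),
                       parameter_level = c("charges-only", "multipoles",
                                           "multipoles+polarizabilities")) {
  donor_class <- match.arg(donor_class)
  parameter_level <- match.arg(parameter_level)
  if (d_nx <= 0) stop("`d_nx` must be > 0")
  if (theta_cnx < 0 || theta_cnx > 180 || theta_nxh < 0 || theta_nxh > 180) {
    stop("angles must lie in [0, 180] degrees")
  }
  structure(list(d_nx = d_nx, theta_cnx = theta_cnx, theta_nxh = theta_nxh,
                 donor_class = donor_class,
                 parameter_level = parameter_level),
            class = "scene_spec")
}

deg2rad <- function(x) x * pi / 180

#' Build a frame realizing a scene specification
#'
#' Constructs a rigid three-site nitrile fragment (ring carbon, nitrile C,
#' nitrile N; C=N length 1.16 A along +z with N at the top) and a rigid
#' three-site water-like donor placed so the re-measured `d_NX`,
#' `theta_CNX` and `theta_NXH` equal the specification to 1e-6. The donor
#' carries toy parameters at the requested level: charges O -0.834 e /
#' H +0.417 e, plus (at multipole levels) a small permanent dipole and
#' traceless quadrupole on O, plus (at the polarizable level) isotropic
#' polarizabilities on all donor atoms. These are illustrative values, not
#' a fit to any published water model.
#'
#' @param spec a [scene_spec].
#' @param time frame time stamp (ps).
#' @return An [md_frame] with the probe in exclusion group `"probe"` and
#'   the donor in group `"donor"`.
#' @export
gen_scene <- function(spec, time = 0) {
  stopifnot(inherits(spec, "scene_spec"))
  cn <- 1.16
  ring_c <- c(0, 0, -1.43)
  cpos <- c(0, 0, 0)
  npos <- c(0, 0, cn)
  # donor heavy atom: angle theta_cnx at N between N->C (-z) and N->X,
  # placed in the xz-plane
  th <- deg2rad(spec$theta_cnx)
  u_nx <- c(sin(th), 0, -cos(th))
  xpos <- npos + spec$d_nx * u_nx
  # hydrogens: O-H 0.9572 A, H-O-H 104.52 deg, in the xz-plane; the first
  # H makes the requested angle with X->N
  u_xn <- -u_nx
  rot_in_plane <- function(v, ang) {
    # rotation about +y keeps vectors in the xz-plane
    c(cos(ang) * v[1] + sin(ang) * v[3], 0,
      -sin(ang) * v[1] + cos(ang) * v[3])
  }
  oh <- 0.9572
  h1 <- xpos + oh * rot_in_plane(u_xn, deg2rad(spec$theta_nxh))
  h2 <- xpos + oh * rot_in_plane(u_xn, deg2rad(spec$theta_nxh + 104.52))
  pos <- rbind(ring_c, cpos, npos, xpos, h1, h2)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  # donor may not overlap the probe fragment
  if (min(d[1:3, 4:6]) < 0.8) {
    stop("infeasible-geometry: donor overlaps the probe fragment")
  }
  n <- 6L
  dip <- matrix(0, n, 3)
  quad <- matrix(0, n, 6)
  alpha <- rep(0, n)
  if (spec$parameter_level != "charges-only") {
    # toy O lone-pair-like dipole along the local H-H bisector, plus a
    # small traceless quadrupole with principal axis on z
    bis <- (h1 + h2) / 2 - xpos
    bis <- bis / sqrt(sum(bis^2))
    dip[4, ] <- 0.05 * bis
    quad[4, ] <- c(-0.1, 0, 0, -0.1, 0, 0.2)
  }
  if (spec$parameter_level == "multipoles+polarizabilities") {
    alpha[4] <- 0.837
    alpha[5:6] <- 0.496
  }
  sites <- atom_sites(
    element = c("C", "C", "N", "O", "H", "H"),
    position = pos,
    charge = c(0.0, 0.28, -0.28, -0.834, 0.417, 0.417),
    dipole = dip, quadrupole = quad, polarizability = alpha,
    group = c("probe", "probe", "probe", "donor", "donor", "donor")
  )
  md_frame(sites, probe = c(1L, 2L, 3L), time = time)
}

#' Measure H-bond descriptors of a scene-like frame
#'
#' Returns `d_nx`, `theta_cnx` and `theta_nxh` (degrees/Angstrom) for a
#' donor identified by its heavy-atom and hydrogen indices. `theta_nxh` is
#' the minimum over the supplied hydrogens.
#'
#' @param frame an [md_frame].
#' @param x_index index of the donor heavy atom.
#' @param h_indices indices of hydrogens bonded to the heavy atom.
#' @return named numeric vector `c(d_nx, theta_cnx, theta_nxh)`.
#' @export
measure_geometry <- function(frame, x_index, h_indices) {
  p <- site_positions(frame$sites)
  npos <- p[frame$probe[3], ]
  cpos <- p[frame$probe[2], ]
  xpos <- p[x_index, ]
  d_nx <- sqrt(sum((xpos - npos)^2))
  ang <- function(a, b) {
    cosv <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  theta_cnx <- ang(cpos - npos, xpos - npos)
  theta_nxh <- min(vapply(h_indices, function(h) {
    ang(npos - xpos, p[h, ] - xpos)
  }, numeric(1)))
  c(d_nx = d_nx, theta_cnx = theta_cnx, theta_nxh = theta_nxh)
}

#' Sample H-bond geometries from a bivariate Gaussian
#'
#' Draws `(theta_CNX, d_NX)` pairs from a correlated bivariate normal,
#' truncated by rejection to `theta` in `[0, 180]` degrees and `d > 0`.
#' The attribute `rejection_fraction` records the fraction of raw draws
#' discarded by truncation.
#'
#' @param center_theta,center_d distribution centers (deg, Angstrom).
#' @param sd_theta,sd_d standard deviations, `> 0`.
#' @param rho correlation, `|rho| < 1`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return data frame with columns `theta` and `d`.
#' @export
gen_geometry_samples <- function(center_theta, center_d, sd_theta, sd_d,
                                 rho = 0, n = 1000L, seed = 1L) {
  if (sd_theta <= 0 || sd_d <= 0) stop("standard deviations must be > 0")
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1")
  if (n < 1) stop("`n` must be >= 1")
  withr::with_seed(as.integer(seed), {
    got <- 0L
    rejected <- 0L
    theta <- numeric(n)
    d <- numeric(n)
    while (got < n) {
      m <- max(1000L, 2L * (n - got))
      z1 <- stats::rnorm(m)
      z2 <- stats::rnorm(m)
      t_raw <- center_theta + sd_theta * z1
      d_raw <- center_d + sd_d * (rho * z1 + sqrt(1 - rho^2) * z2)
      ok <- t_raw >= 0 & t_raw <= 180 & d_raw > 0
      rejected <- rejected + sum(!ok)
      take <- min(sum(ok), n - got)
      idx <- which(ok)[seq_len(take)]
      theta[got + seq_len(take)] <- t_raw[idx]
      d[got + seq_len(take)] <- d_raw[idx]
      got <- got + take
    }
  })
  out <- data.frame(theta = theta, d = d)
  attr(out, "rejection_fraction") <- rejected / (rejected + n)
  out
}

#' Describe one IR absorption band
#'
#' A pseudo-Voigt band: `gauss_fraction` of an area-normalized Gaussian
#' plus the complement of an area-normalized Lorentzian, both with the same
#' center and full width at half maximum.
#'
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), `> 0`.
#' @param area integrated area (absorbance * cm^-1), `> 0`.
#' @param gauss_fraction Gaussian mixing fraction in `[0, 1]` (1 = pure
#'   Gaussian).
#' @return list of class `band_model`.
#' @export
band_model <- function(center, fwhm, area = 1, gauss_fraction = 1) {
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  if (area <= 0) stop("`area` must be > 0")
  if (gauss_fraction < 0 || gauss_fraction > 1) {
    stop("`gauss_fraction` must lie in [0, 1]")
  }
  structure(list(center = center, fwhm = fwhm, area = area,
                 gauss_fraction = gauss_fraction),
            class = "band_model")
}

pseudo_voigt <- function(x, center, fwhm, area, gauss_fraction) {
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-0.5 * ((x - center) / sg)^2) / (sg * sqrt(2 * pi))
  l <- (fwhm / (2 * pi)) / ((x - center)^2 + (fwhm / 2)^2)
  area * (gauss_fraction * g + (1 - gauss_fraction) * l)
}

#' Generate a synthetic IR spectrum
#'
#' Sum of pseudo-Voigt bands evaluated on a wavenumber grid, plus i.i.d.
#' Gaussian absorbance noise.
#'
#' @param bands list of [band_model] objects (may be empty).
#' @param noise_sd noise standard deviation (absorbance units).
#' @param grid strictly increasing wavenumber grid (cm^-1).
#' @param seed integer seed.
#' @return data frame of class `ir_spectrum` with columns `wavenumber` and
#'   `absorbance`.
#' @export
gen_spectrum <- function(bands, noise_sd = 0, grid, seed = 1L) {
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing with >= 2 points")
  }
  y <- numeric(length(grid))
  for (b in bands) {
    stopifnot(inherits(b, "band_model"))
    y <- y + pseudo_voigt(grid, b$center, b$fwhm, b$area, b$gauss_fraction)
  }
  if (noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(grid), 0, noise_sd))
  }
  structure(data.frame(wavenumber = grid, absorbance = y),
            class = c("ir_spectrum", "data.frame"))
}
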