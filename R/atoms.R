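#' Coulomb constant in V * Angstrom / e
#'
#' Conversion factor for electrostatics in atomic-ish units: the potential of
#' a unit point charge at 1 Angstrom is 14.39964 V. Fields computed in V/A are
#' converted to MV/cm with [VA_TO_MVCM].
#'
#' @export
K_COULOMB <- 14.39964

#' Unit conversion: 1 V/Angstrom = 100 MV/cm
#' @export
VA_TO_MVCM <- 100

#' Construct a set of atom sites with electrostatic parameters
#'
#' An `atom_sites` object is the basic container for a molecular scene: one
#' row per atom, with Cartesian position and the per-atom electrostatic
#' parameters used by the field/potential engines. Parameters beyond the
#' partial charge are optional and default to zero, so a plain fixed-charge
#' description is just positions plus charges.
#'
#' @param element character vector of element symbols (labels only; never
#'   interpreted chemically).
#' @param position numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param charge numeric vector of partial charges (e).
#' @param dipole optional n x 3 matrix of permanent point dipoles (e*A).
#' @param quadrupole optional n x 6 matrix of traceless Cartesian quadrupole
#'   components in the column order `qxx, qxy, qxz, qyy, qyz, qzz` (e*A^2).
#'   The trace `qxx + qyy + qzz` must vanish to 1e-8. The convention is the
#'   "3xx - r^2" traceless form whose interaction energy with a field
#'   gradient carries a 1/3 contraction factor; the corresponding potential
#'   is `k * (R . Q . R) / (2 r^5)`.
#' @param polarizability optional vector of isotropic dipole
#'   polarizabilities (A^3), `>= 0`.
#' @param damping optional vector of dimensionless Thole damping factors
#'   (default 0.39). The pairwise factor used in induced-dipole interactions
#'   is the minimum of the two sites' values.
#' @param group integer or character vector of exclusion-group labels. Sites
#'   sharing a group never see each other's fields, and whole groups can be
#'   excluded from sums (used to remove a probe's own parameters from the
#'   field it reports).
#'
#' @return A data frame of class `atom_sites` with columns `element`, `x`,
#'   `y`, `z`, `charge`, `dx`, `dy`, `dz`, `qxx`..`qzz`, `alpha`, `damping`,
#'   `group`.
#' @export
atom_sites <- function(element, position, charge,
                       dipole = NULL, quadrupole = NULL,
                       polarizability = NULL, damping = NULL,
                       group = NULL) {
  position <- as.matrix(position)
  if (ncol(position) != 3) stop("`position` must be an n x 3 matrix")
  n <- nrow(position)
  if (length(element) != n) stop("`element` length must match positions")
  charge <- as.numeric(charge)
  if (length(charge) != n) stop("`charge` length must match positions")
  if (is.null(dipole)) dipole <- matrix(0, n, 3)
  dipole <- as.matrix(dipole)
  if (!all(dim(dipole) == c(n, 3))) stop("`dipole` must be n x 3")
  if (is.null(quadrupole)) quadrupole <- matrix(0, n, 6)
  quadrupole <- as.matrix(quadrupole)
  if (!all(dim(quadrupole) == c(n, 6))) stop("`quadrupole` must be n x 6")
  tr <- quadrupole[, 1] + quadrupole[, 4] + quadrupole[, 6]
  if (any(abs(tr) > 1e-8)) {
    stop("quadrupole trace must vanish (|qxx + qyy + qzz| < 1e-8)")
  }
  if (is.null(polarizability)) polarizability <- rep(0, n)
  if (any(polarizability < 0)) stop("polarizabilities must be >= 0")
  if (is.null(damping)) damping <- rep(0.39, n)
  damping <- rep_len(as.numeric(damping), n)
  if (is.null(group)) group <- seq_len(n)
  sites <- data.frame(
    element = as.character(element),
    x = position[, 1], y = position[, 2], z = position[, 3],
    charge = charge,
    dx = dipole[, 1], dy = dipole[, 2], dz = dipole[, 3],
    qxx = quadrupole[, 1], qxy = quadrupole[, 2], qxz = quadrupole[, 3],
    qyy = quadrupole[, 4], qyz = quadrupole[, 5], qzz = quadrupole[, 6],
    alpha = rep_len(as.numeric(polarizability), n),
    damping = damping,
    group = group,
    stringsAsFactors = FALSE
  )
  rownames(sites) <- NULL
  class(sites) <- c("atom_sites", "data.frame")
  sites
}

#' @export
print.atom_sites <- function(x, ...) {
  cat(sprintf("atom_sites: %d sites, %d exclusion groups\n",
              nrow(x), length(unique(x$group))))
  lvl <- site_parameter_level(x)
  cat(sprintf("  parameter level: %s%s\n", lvl,
              if (any(x$alpha > 0)) " (+polarizabilities)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more sites\n", nrow(x) - 6))
  invisible(x)
}

site_positions <- function(sites) {
  cbind(sites$x, sites$y, sites$z)
}

site_parameter_level <- function(sites) {
  if (any(abs(c(sites$dx, sites$dy, sites$dz, sites$qxx, sites$qxy,
                sites$qxz, sites$qyy, sites$qyz, sites$qzz)) > 0)) {
    "multipoles"
  } else {
    "charges"
  }
}

#' Construct a trajectory frame around a nitrile probe
#'
#' A frame bundles an [atom_sites] scene with the identity of the nitrile
#' probe: the indices of the ring carbon, the nitrile carbon and the nitrile
#' nitrogen. The C-N bond length is validated against the physical range for
#' a nitrile.
#'
#' @param sites an [atom_sites] object.
#' @param probe integer vector of length 3: indices of (ring C, nitrile C,
#'   nitrile N) within `sites`.
#' @param time frame time stamp in ps.
#' @return An object of class `md_frame`: a list with elements `sites`,
#'   `probe` and `time`.
#' @export
md_frame <- function(sites, probe, time = 0) {
  stopifnot(inherits(sites, "atom_sites"))
  probe <- as.integer(probe)
  if (length(probe) != 3 || anyDuplicated(probe) ||
      any(probe < 1) || any(probe > nrow(sites))) {
    stop("`probe` must be 3 distinct in-range indices (ring C, C, N)")
  }
  p <- site_positions(sites)
  dcn <- sqrt(sum((p[probe[3], ] - p[probe[2], ])^2))
  if (dcn < 1.0 || dcn > 1.35) {
    stop(sprintf("C-N distance %.3f A outside the nitrile range [1.0, 1.35]",
                 dcn))
  }
  structure(list(sites = sites, probe = probe, time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame at t = %g ps: %d sites, probe (ringC, C, N) = %s\n",
              x$time, nrow(x$sites), paste(x$probe, collapse = ", ")))
  invisible(x)
}

probe_axis <- function(frame) {
  p <- site_positions(frame$sites)
  v <- p[frame$probe[3], ] - p[frame$probe[2], ]
  v / sqrt(sum(v^2))
}

probe_groups <- function(frame) {
  unique(frame$sites$group[frame$probe])
}
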