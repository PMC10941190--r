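# Field and potential engines. All sums are direct (no cutoff, no periodic
# images): scenes here are desk-scale clusters, not periodic boxes.

included_rows <- function(sites, exclude) {
  if (is.null(exclude) || length(exclude) == 0) rep(TRUE, nrow(sites))
  else !(sites$group %in% exclude)
}

#' Electric field of a parameter set at a point
#'
#' Sums the fields of point charges and, at `level = "multipoles"`, point
#' dipoles and traceless point quadrupoles over all sites not belonging to
#' an excluded group. Units: V/Angstrom, with the Coulomb constant
#' [K_COULOMB].
#'
#' @param sites an [atom_sites] object.
#' @param point numeric length-3 evaluation point (Angstrom).
#' @param exclude vector of exclusion-group labels to omit from the sum.
#' @param level `"charges"` (monopoles only) or `"multipoles"` (charges +
#'   dipoles + quadrupoles).
#' @param extra_dipoles optional n x 3 matrix of additional point dipoles
#'   (e*A) co-located with the sites, e.g. converged induced dipoles.
#' @return numeric length-3 field vector in V/A.
#' @export
field_at_point <- function(sites, point, exclude = NULL,
                           level = c("multipoles", "charges"),
                           extra_dipoles = NULL) {
  level <- match.arg(level)
  keep <- included_rows(sites, exclude)
  if (!any(keep)) return(c(0, 0, 0))
  s <- sites[keep, , drop = FALSE]
  R <- matrix(point, nrow(s), 3, byrow = TRUE) - site_positions(s)
  r2 <- rowSums(R * R)
  if (any(r2 < 1e-12)) {
    stop(sprintf("singular evaluation point: coincides with site %d",
                 which(keep)[which.min(r2)]))
  }
  r <- sqrt(r2)
  e <- K_COULOMB * colSums(s$charge / (r2 * r) * R)
  if (level == "multipoles") {
    mu <- cbind(s$dx, s$dy, s$dz)
    if (any(mu != 0)) {
      mur <- rowSums(mu * R)
      e <- e + K_COULOMB *
        colSums((3 * mur / r2) / (r2 * r) * R - mu / (r2 * r))
    }
    if (any(abs(c(s$qxx, s$qxy, s$qxz, s$qyy, s$qyz, s$qzz)) > 0)) {
      QR <- cbind(
        s$qxx * R[, 1] + s$qxy * R[, 2] + s$qxz * R[, 3],
        s$qxy * R[, 1] + s$qyy * R[, 2] + s$qyz * R[, 3],
        s$qxz * R[, 1] + s$qyz * R[, 2] + s$qzz * R[, 3]
      )
      rqr <- rowSums(R * QR)
      r5 <- r2 * r2 * r
      e <- e + K_COULOMB *
        colSums((5 * rqr / (2 * r5 * r2)) * R - QR / r5)
    }
  }
  if (!is.null(extra_dipoles)) {
    mu <- as.matrix(extra_dipoles)[keep, , drop = FALSE]
    if (any(mu != 0)) {
      mur <- rowSums(mu * R)
      e <- e + K_COULOMB *
        colSums((3 * mur / r2) / (r2 * r) * R - mu / (r2 * r))
    }
  }
  e
}

#' Electrostatic potential of a parameter set at one or more points
#'
#' @inheritParams field_at_point
#' @param points numeric m x 3 matrix (or length-3 vector) of evaluation
#'   points.
#' @param min_dist points closer than this to any included site are returned
#'   as `NA` (singularity mask).
#' @return numeric vector of potentials in V, one per point.
#' @export
potential_at_points <- function(sites, points, exclude = NULL,
                                level = c("multipoles", "charges"),
                                min_dist = 1e-3) {
  level <- match.arg(level)
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  keep <- included_rows(sites, exclude)
  if (!any(keep)) return(rep(0, nrow(points)))
  s <- sites[keep, , drop = FALSE]
  pos <- site_positions(s)
  out <- numeric(nrow(points))
  masked <- rep(FALSE, nrow(points))
  mp <- level == "multipoles"
  for (i in seq_len(nrow(points))) {
    R <- matrix(points[i, ], nrow(s), 3, byrow = TRUE) - pos
    r2 <- rowSums(R * R)
    if (any(r2 < min_dist^2)) {
      masked[i] <- TRUE
      next
    }
    r <- sqrt(r2)
    v <- sum(s$charge / r)
    if (mp) {
      v <- v + sum((s$dx * R[, 1] + s$dy * R[, 2] + s$dz * R[, 3]) / (r2 * r))
      rqr <- s$qxx * R[, 1]^2 + s$qyy * R[, 2]^2 + s$qzz * R[, 3]^2 +
        2 * (s$qxy * R[, 1] * R[, 2] + s$qxz * R[, 1] * R[, 3] +
               s$qyz * R[, 2] * R[, 3])
      v <- v + sum(rqr / (2 * r2 * r2 * r))
    }
    out[i] <- K_COULOMB * v
  }
  out[masked] <- NA_real_
  out
}

thole_lambdas <- function(r, alpha_i, alpha_j, a) {
  # Exponential (Thole) damping of the dipole-dipole tensor; u is the
  # polarizability-scaled distance. Undamped when either alpha is zero.
  if (alpha_i <= 0 || alpha_j <= 0) return(c(l3 = 1, l5 = 1))
  u3 <- (r / (alpha_i * alpha_j)^(1 / 6))^3
  ex <- exp(-a * u3)
  c(l3 = 1 - ex, l5 = 1 - (1 + a * u3) * ex)
}

#' Self-consistent mutually induced dipoles
#'
#' Iterates `mu_i = alpha_i * E_i` to self-consistency, where `E_i` is the
#' permanent field (charges + permanent multipoles) at site `i` plus the
#' field of all other induced dipoles. Following the usual convention for
#' polarizabilities quoted in A^3, the self-consistency equation is
#' dimensionally closed in e-based units: `E` enters in e/A^2 (the field
#' in V/A divided by [K_COULOMB]) so that `alpha * E` is a dipole in e*A.
#' Induced-dipole interactions are damped with the Thole exponential
#' scheme using the pairwise minimum of the two sites' damping factors;
#' permanent fields are left undamped. Pairs of sites in the same
#' exclusion group do not interact at all.
#'
#' @inheritParams field_at_point
#' @param tol convergence threshold on the maximum per-site dipole change
#'   (e*A).
#' @param max_iter maximum number of self-consistency iterations.
#' @param frozen exclusion groups whose sites keep zero induced dipole but
#'   still polarize the others through their permanent parameters (used
#'   for a probe whose own induction is zeroed by convention).
#' @return n x 3 matrix of induced dipoles (e*A), zero rows for excluded or
#'   unpolarizable sites, with attributes `iterations` and `residual`.
#' @export
induced_dipoles <- function(sites, exclude = NULL, tol = 1e-8,
                            max_iter = 100L, frozen = NULL) {
  n <- nrow(sites)
  mu <- matrix(0, n, 3)
  keep <- included_rows(sites, exclude)
  pol <- which(keep & sites$alpha > 0 & !(sites$group %in% frozen))
  attr(mu, "iterations") <- 0L
  attr(mu, "residual") <- 0
  if (length(pol) == 0) {
    attr(mu, "iterations") <- 1L
    return(mu)
  }
  pos <- site_positions(sites)
  # permanent field at each polarizable site (same-group sites masked)
  eperm <- matrix(0, length(pol), 3)
  for (k in seq_along(pol)) {
    i <- pol[k]
    grp <- sites$group[i]
    excl <- unique(c(exclude, grp))
    eperm[k, ] <- field_at_point(sites, pos[i, ], exclude = excl,
                                 level = "multipoles") / K_COULOMB
  }
  # precompute damped dipole interaction tensors between polarizable pairs
  np <- length(pol)
  Tm <- vector("list", np * np)
  for (k in seq_len(np)) {
    for (l in seq_len(np)) {
      if (l == k) next
      i <- pol[k]; j <- pol[l]
      if (sites$group[i] == sites$group[j]) next
      Rv <- pos[i, ] - pos[j, ]
      r2 <- sum(Rv * Rv)
      r <- sqrt(r2)
      lam <- thole_lambdas(r, sites$alpha[i], sites$alpha[j],
                           min(sites$damping[i], sites$damping[j]))
      rhat <- Rv / r
      Tm[[(k - 1) * np + l]] <- (1 / r^3) *
        (3 * lam["l5"] * tcrossprod(rhat) - lam["l3"] * diag(3))
    }
  }
  mup <- sites$alpha[pol] * eperm  # direct-induction start
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    newmu <- mup
    for (k in seq_len(np)) {
      e <- eperm[k, ]
      for (l in seq_len(np)) {
        Tkl <- Tm[[(k - 1) * np + l]]
        if (!is.null(Tkl)) e <- e + as.vector(Tkl %*% mup[l, ])
      }
      newmu[k, ] <- sites$alpha[pol[k]] * e
    }
    resid <- max(abs(newmu - mup))
    mup <- newmu
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop(sprintf(
      "induced dipoles did not converge in %d iterations (residual %.3g e*A)",
      max_iter, resid))
  }
  mu[pol, ] <- mup
  attr(mu, "iterations") <- iter
  attr(mu, "residual") <- resid
  mu
}

#' Projected nitrile probe field in MV/cm
#'
#' Evaluates the total environmental electric field at the nitrile and
#' projects it onto the C->N unit vector. The probe's own exclusion
#' group(s) are always omitted, so the reported field is the environment's
#' field at the probe. The sign convention makes an H-bond donor proton
#' sitting in front of N give a negative value.
#'
#' The default evaluation point is the average of the fields at the C and N
#' atoms, the common convention for vibrational Stark probes; the bond
#' midpoint and the N atom alone are available as diagnostics.
#'
#' @param frame an [md_frame].
#' @param level `"charges"` or `"multipoles"`.
#' @param include_induction if `TRUE`, converge mutually induced dipoles in
#'   the environment and add their field at the probe. The probe's own
#'   sites never acquire induced dipoles; whether their permanent
#'   parameters polarize the environment is controlled by
#'   `probe_polarizes`.
#' @param probe_polarizes if `TRUE` (default) the probe's permanent charges
#'   and multipoles act as sources in the self-consistent induction, as
#'   they would in a polarizable force field; if `FALSE` the probe group
#'   is removed from the induction entirely.
#' @param eval_mode `"average-CN"`, `"midpoint"` or `"N-only"`.
#' @param exclude extra exclusion groups beyond the probe's own.
#' @param tol,max_iter passed to [induced_dipoles] when induction is on.
#' @return projected field F_CN in MV/cm (scalar).
#' @export
projected_probe_field <- function(frame,
                                  level = c("multipoles", "charges"),
                                  include_induction = FALSE,
                                  eval_mode = c("average-CN", "midpoint",
                                                "N-only"),
                                  exclude = NULL, tol = 1e-8,
                                  max_iter = 100L, probe_polarizes = TRUE) {
  level <- match.arg(level)
  eval_mode <- match.arg(eval_mode)
  stopifnot(inherits(frame, "md_frame"))
  excl <- unique(c(exclude, probe_groups(frame)))
  p <- site_positions(frame$sites)
  cpos <- p[frame$probe[2], ]
  npos <- p[frame$probe[3], ]
  pts <- switch(eval_mode,
    "average-CN" = rbind(cpos, npos),
    "midpoint" = rbind((cpos + npos) / 2),
    "N-only" = rbind(npos)
  )
  mu_ind <- NULL
  if (include_induction) {
    mu_ind <- if (probe_polarizes) {
      induced_dipoles(frame$sites, exclude = exclude, tol = tol,
                      max_iter = max_iter, frozen = probe_groups(frame))
    } else {
      induced_dipoles(frame$sites, exclude = excl, tol = tol,
                      max_iter = max_iter)
    }
  }
  fields <- vapply(seq_len(nrow(pts)), function(i) {
    field_at_point(frame$sites, pts[i, ], exclude = excl, level = level,
                   extra_dipoles = mu_ind)
  }, numeric(3))
  e <- rowMeans(fields)
  ax <- probe_axis(frame)
  sum(e * ax) * VA_TO_MVCM
}
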