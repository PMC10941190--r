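# Independent brute-force oracles and random-scene builders used across
# the suite. The oracles are deliberately written as scalar term-by-term
# loops, separate from the package's vectorized engines.

oracle_field_at_point <- function(sites, point, exclude = NULL,
                                  level = "multipoles") {
  e <- c(0, 0, 0)
  for (i in seq_len(nrow(sites))) {
    if (!is.null(exclude) && sites$group[i] %in% exclude) next
    R <- point - c(sites$x[i], sites$y[i], sites$z[i])
    r <- sqrt(sum(R^2))
    e <- e + 14.39964 * sites$charge[i] * R / r^3
    if (level == "multipoles") {
      mu <- c(sites$dx[i], sites$dy[i], sites$dz[i])
      rhat <- R / r
      e <- e + 14.39964 * (3 * sum(mu * rhat) * rhat - mu) / r^3
      Q <- matrix(c(sites$qxx[i], sites$qxy[i], sites$qxz[i],
                    sites$qxy[i], sites$qyy[i], sites$qyz[i],
                    sites$qxz[i], sites$qyz[i], sites$qzz[i]), 3, 3)
      QR <- as.vector(Q %*% R)
      rqr <- sum(R * QR)
      e <- e + 14.39964 * (5 * rqr * R / (2 * r^7) - QR / r^5)
    }
  }
  e
}

oracle_potential_at_point <- function(sites, point, exclude = NULL,
                                      level = "multipoles") {
  v <- 0
  for (i in seq_len(nrow(sites))) {
    if (!is.null(exclude) && sites$group[i] %in% exclude) next
    R <- point - c(sites$x[i], sites$y[i], sites$z[i])
    r <- sqrt(sum(R^2))
    v <- v + sites$charge[i] / r
    if (level == "multipoles") {
      mu <- c(sites$dx[i], sites$dy[i], sites$dz[i])
      v <- v + sum(mu * R) / r^3
      Q <- matrix(c(sites$qxx[i], sites$qxy[i], sites$qxz[i],
                    sites$qxy[i], sites$qyy[i], sites$qyz[i],
                    sites$qxz[i], sites$qyz[i], sites$qzz[i]), 3, 3)
      v <- v + sum(R * (Q %*% R)) / (2 * r^5)
    }
  }
  14.39964 * v
}

random_traceless_quad <- function(scale = 0.2) {
  m <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  m <- (m + t(m)) / 2
  m <- m - diag(3) * sum(diag(m)) / 3
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

# Random multipolar scene: n sites in a box, kept >= 1.5 A apart from a
# central probe region so evaluation points are never near-singular.
random_sites <- function(n, seed, box = 8, with_multipoles = TRUE,
                         with_alpha = FALSE) {
  withr::with_seed(seed, {
    box <- max(box, (n * 8)^(1 / 3))
    # sequential placement with a minimum-separation check, so dense
    # scenes never contain near-singular pairs
    pos <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      repeat {
        p <- stats::runif(3, -box, box)
        if (sqrt(sum(p^2)) < 1.5) next
        if (i == 1 ||
            min(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                                matrix(p, i - 1, 3, byrow = TRUE))^2))) > 1.0) {
          pos[i, ] <- p
          break
        }
      }
    }
    quad <- t(replicate(n, if (with_multipoles) random_traceless_quad()
                        else rep(0, 6)))
    atom_sites(
      element = rep("X", n),
      position = pos,
      charge = stats::runif(n, -1, 1),
      dipole = if (with_multipoles) matrix(stats::rnorm(n * 3, sd = 0.3),
                                           n, 3) else NULL,
      quadrupole = quad,
      polarizability = if (with_alpha) stats::runif(n, 0, 0.8) else NULL,
      group = seq_len(n)
    )
  })
}

# Rigid-body transform of a frame: rotates positions, dipoles and
# quadrupoles (Q' = R Q R^T) and translates positions.
transform_frame <- function(frame, rot, shift) {
  s <- frame$sites
  pos <- cbind(s$x, s$y, s$z) %*% t(rot) +
    matrix(shift, nrow(s), 3, byrow = TRUE)
  dip <- cbind(s$dx, s$dy, s$dz) %*% t(rot)
  quad <- t(vapply(seq_len(nrow(s)), function(i) {
    Q <- matrix(c(s$qxx[i], s$qxy[i], s$qxz[i],
                  s$qxy[i], s$qyy[i], s$qyz[i],
                  s$qxz[i], s$qyz[i], s$qzz[i]), 3, 3)
    Qr <- rot %*% Q %*% t(rot)
    # re-symmetrize to keep the trace exactly zero against roundoff
    Qr <- (Qr + t(Qr)) / 2
    Qr <- Qr - diag(3) * sum(diag(Qr)) / 3
    c(Qr[1, 1], Qr[1, 2], Qr[1, 3], Qr[2, 2], Qr[2, 3], Qr[3, 3])
  }, numeric(6)))
  sites <- atom_sites(s$element, pos, s$charge, dip, quad, s$alpha,
                      s$damping, s$group)
  md_frame(sites, frame$probe, frame$time)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Frames realizing a generated two-state trace: H-bonded frames get a
# close head-on donor, non-H-bonded frames a distant one.
scene_for_state <- function(state, time = 0) {
  spec <- if (state == 1L) scene_spec(3.0, 165, 10)
          else scene_spec(5.0, 150, 15)
  fr <- gen_scene(spec, time = time)
  fr
}
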