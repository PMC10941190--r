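test_that("closed-form Coulomb and on-axis dipole fields are exact", {
  s <- atom_sites("Q", matrix(c(0, 0, 0), 1), charge = 1)
  e <- field_at_point(s, c(1, 0, 0))
  expect_equal(e, c(14.39964, 0, 0), tolerance = 1e-12)

  # pure point dipole, on-axis: |E| = 2 k mu / r^3
  sd <- atom_sites("D", matrix(c(0, 0, 0), 1), charge = 0,
                   dipole = matrix(c(0, 0, 1), 1))
  ed <- field_at_point(sd, c(0, 0, 2))
  expect_equal(ed, c(0, 0, 2 * 14.39964 / 8), tolerance = 1e-10)

  expect_error(field_at_point(s, c(0, 0, 0)), "singular")
})

test_that("vectorized fields and potentials match the brute-force oracle", {
  for (seed in 1:6) {
    n <- sample(10:50, 1)
    s <- random_sites(n, seed = seed)
    pts <- withr::with_seed(seed + 100, matrix(stats::rnorm(9, sd = 0.4),
                                               3, 3))
    for (i in 1:3) {
      for (lvl in c("charges", "multipoles")) {
        e <- field_at_point(s, pts[i, ], level = lvl)
        eo <- oracle_field_at_point(s, pts[i, ], level = lvl)
        expect_lt(sqrt(sum((e - eo)^2)) / sqrt(sum(eo^2)), 1e-10)
        v <- potential_at_points(s, pts[i, ], level = lvl)
        vo <- oracle_potential_at_point(s, pts[i, ], level = lvl)
        expect_lt(abs(v - vo) / abs(vo), 1e-10)
      }
    }
  }
})

test_that("multipole level with zero higher moments reduces to charges", {
  s <- random_sites(20, seed = 3, with_multipoles = FALSE)
  p <- c(0.3, -0.2, 0.5)
  expect_equal(field_at_point(s, p, level = "multipoles"),
               field_at_point(s, p, level = "charges"), tolerance = 1e-14)
})

test_that("permanent fields superpose over disjoint site sets", {
  a <- random_sites(15, seed = 21)
  b <- random_sites(15, seed = 22)
  b$group <- paste0("b", b$group)
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  class(ab) <- c("atom_sites", "data.frame")
  p <- c(0.1, 0.2, -0.3)
  expect_equal(field_at_point(ab, p),
               field_at_point(a, p) + field_at_point(b, p),
               tolerance = 1e-12)
})

test_that("exclusion groups drop whole groups from the sums", {
  s <- atom_sites(c("A", "B"), rbind(c(2, 0, 0), c(0, 2, 0)),
                  charge = c(1, 1), group = c("g1", "g2"))
  e <- field_at_point(s, c(0, 0, 0), exclude = "g1")
  eo <- field_at_point(s[2, ], c(0, 0, 0))
  expect_equal(e, eo, tolerance = 1e-14)
  expect_equal(field_at_point(s, c(0, 0, 0), exclude = c("g1", "g2")),
               c(0, 0, 0))
})

test_that("induced dipoles solve the self-consistent equations", {
  # isolated polarizable site: mu = alpha * E (E in e/A^2 units)
  s <- atom_sites(c("Q", "P"), rbind(c(0, 0, 0), c(5, 0, 0)),
                  charge = c(1, 0), polarizability = c(0, 1),
                  group = c("a", "b"))
  mu <- induced_dipoles(s)
  eperm <- field_at_point(s, c(5, 0, 0), exclude = "b") / K_COULOMB
  expect_equal(mu[2, ], 1 * eperm, tolerance = 1e-8)

  # two mutually polarizable sites: compare with a direct 6x6 linear solve
  s2 <- atom_sites(c("Q", "P", "P"),
                   rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)),
                   charge = c(1, 0, 0), polarizability = c(0, 1, 1.2),
                   group = c("a", "b", "c"))
  mu2 <- induced_dipoles(s2, tol = 1e-12)
  al <- c(1, 1.2)
  pos <- rbind(c(3, 0, 0), c(6, 0, 0))
  ep <- rbind(field_at_point(s2, pos[1, ], exclude = "b") / K_COULOMB,
              field_at_point(s2, pos[2, ], exclude = "c") / K_COULOMB)
  rv <- pos[1, ] - pos[2, ]
  r <- sqrt(sum(rv^2))
  u3 <- (r / (al[1] * al[2])^(1 / 6))^3
  a <- 0.39
  l3 <- 1 - exp(-a * u3)
  l5 <- 1 - (1 + a * u3) * exp(-a * u3)
  Tt <- (3 * l5 * tcrossprod(rv / r) - l3 * diag(3)) / r^3
  A <- diag(6)
  A[1:3, 4:6] <- -al[1] * Tt
  A[4:6, 1:3] <- -al[2] * Tt
  rhs <- c(al[1] * ep[1, ], al[2] * ep[2, ])
  mu_direct <- solve(A, rhs)
  expect_equal(as.vector(t(mu2[2:3, ])), mu_direct, tolerance = 1e-8)

  # all alpha = 0: zero dipoles, immediate return
  s3 <- random_sites(10, seed = 5)
  mu3 <- induced_dipoles(s3)
  expect_true(all(mu3 == 0))
  expect_equal(attr(mu3, "iterations"), 1L)
})

test_that("probe-driven polarization of the environment is optional", {
  fr <- gen_scene(scene_spec(2.93, 167, 10,
                             parameter_level = "multipoles+polarizabilities"))
  perm <- projected_probe_field(fr)
  pol_on <- projected_probe_field(fr, include_induction = TRUE)
  # the nitrile's charges polarize the donor, shifting the field
  expect_gt(abs(pol_on - perm), 0.1)

  # with the probe removed from the induction a two-group scene has no
  # polarizing source left: the permanent answer is recovered
  pol_off <- projected_probe_field(fr, include_induction = TRUE,
                                   probe_polarizes = FALSE)
  expect_equal(pol_off, perm, tolerance = 1e-10)

  # frozen groups acquire no induced dipoles
  mu <- induced_dipoles(fr$sites, frozen = "probe")
  expect_true(all(mu[1:3, ] == 0))
})

test_that("induction is independent of iteration path details", {
  fr <- gen_scene(scene_spec(2.93, 167, 10,
                             parameter_level = "multipoles+polarizabilities"))
  m1 <- induced_dipoles(fr$sites, tol = 1e-8)
  m2 <- induced_dipoles(fr$sites, tol = 1e-12)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("projected probe field honors sign convention and null case", {
  # +1 e charge 1 A beyond N on the C->N axis, N-only diagnostic mode
  s <- atom_sites(c("C", "C", "N", "Q"),
                  rbind(c(0, 0, -1.43), c(0, 0, 0), c(0, 0, 1.16),
                        c(0, 0, 2.16)),
                  charge = c(0, 0.28, -0.28, 1),
                  group = c("p", "p", "p", "q"))
  fr <- md_frame(s, 1:3)
  expect_equal(projected_probe_field(fr, level = "charges",
                                     eval_mode = "N-only"),
               -1439.964, tolerance = 1e-8)

  # empty environment: the probe sees nothing
  s0 <- atom_sites(c("C", "C", "N"),
                   rbind(c(0, 0, -1.43), c(0, 0, 0), c(0, 0, 1.16)),
                   charge = c(0, 0.28, -0.28), group = c("p", "p", "p"))
  expect_equal(projected_probe_field(md_frame(s0, 1:3)), 0)

  # donor scene at charges-only level equals the brute-force oracle
  fr2 <- gen_scene(scene_spec(2.93, 167, 10))
  p <- cbind(fr2$sites$x, fr2$sites$y, fr2$sites$z)
  ax <- (p[3, ] - p[2, ]) / sqrt(sum((p[3, ] - p[2, ])^2))
  eo <- (oracle_field_at_point(fr2$sites, p[2, ], exclude = "probe",
                               level = "charges") +
           oracle_field_at_point(fr2$sites, p[3, ], exclude = "probe",
                                 level = "charges")) / 2
  expect_equal(projected_probe_field(fr2, level = "charges"),
               sum(eo * ax) * 100, tolerance = 1e-10)
})

test_that("projected field is invariant under rigid-body transforms", {
  fr <- gen_scene(scene_spec(3.1, 155, 20, parameter_level = "multipoles"))
  f0 <- projected_probe_field(fr)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      rot <- random_rotation()
      shift <- stats::rnorm(3, sd = 5)
    })
    fr2 <- transform_frame(fr, rot, shift)
    expect_lt(abs(projected_probe_field(fr2) - f0), 1e-8)
  }
})

test_that("an approaching axial charge makes the field monotonically more negative", {
  dists <- seq(10, 2, by = -0.5)
  vals <- vapply(dists, function(d) {
    s <- atom_sites(c("C", "C", "N", "Q"),
                    rbind(c(0, 0, -1.43), c(0, 0, 0), c(0, 0, 1.16),
                          c(0, 0, 1.16 + d)),
                    charge = c(0, 0.28, -0.28, 1),
                    group = c("p", "p", "p", "q"))
    projected_probe_field(md_frame(s, 1:3), level = "charges")
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 0))
})

test_that("ESP grids match the oracle and difference maps are consistent", {
  s <- random_sites(12, seed = 31)
  pl <- plane_spec(c(-3, -3, 0.4), c(1, 0, 0), c(0, 1, 0))
  g <- esp_grid(s, pl, 7, 7, 1.0)
  for (idx in list(c(1, 1), c(4, 3), c(7, 7))) {
    pt <- pl$origin + (idx[1] - 1) * 1.0 * pl$e1 + (idx[2] - 1) * 1.0 * pl$e2
    expect_equal(g$values[idx[1], idx[2]],
                 oracle_potential_at_point(s, pt), tolerance = 1e-10)
  }

  # ring of radius 2 around a single charge: constant k/2
  sq <- atom_sites("Q", matrix(0, 1, 3), charge = 1)
  ang <- seq(0, 2 * pi, length.out = 13)
  ring <- cbind(2 * cos(ang), 2 * sin(ang), 0)
  expect_equal(potential_at_points(sq, ring), rep(7.19982, 13),
               tolerance = 1e-10)

  # difference maps: self-difference zero, antisymmetry
  d0 <- esp_difference(g, g)
  expect_true(all(d0$values[!d0$mask] == 0))
  s2 <- s
  s2$charge <- s2$charge * 0.5
  g2 <- esp_grid(s2, pl, 7, 7, 1.0)
  d12 <- esp_difference(g, g2)
  d21 <- esp_difference(g2, g)
  expect_equal(d12$values, -d21$values, tolerance = 1e-12)

  # monopole vs monopole + axial dipole: on-axis difference is k mu / r^2
  sa <- atom_sites("Q", matrix(0, 1, 3), charge = 1)
  sb <- atom_sites("Q", matrix(0, 1, 3), charge = 1,
                   dipole = matrix(c(0, 0, 0.3), 1))
  pts <- rbind(c(0, 0, 2), c(0, 0, 4))
  dv <- potential_at_points(sb, pts) - potential_at_points(sa, pts)
  expect_equal(dv, 14.39964 * 0.3 / c(4, 16), tolerance = 1e-10)

  expect_error(esp_difference(g, esp_grid(s, pl, 7, 6, 1.0)), "mismatch")
})
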