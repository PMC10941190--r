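test_that("state traces are reproducible and hit the stationary occupancy", {
  p <- switching_params(5, 5, dt = 0.1, seed = 42L)
  a <- gen_state_trace(p, 1e5)
  b <- gen_state_trace(p, 1e5)
  expect_identical(a$states, b$states)

  # symmetric rates: occupancy 1/2
  expect_lt(abs(mean(a$states) - 0.5), 0.02)

  # asymmetric rates: occupancy tau_hb / (tau_hb + tau_non)
  p2 <- switching_params(6, 4, dt = 0.1, seed = 7L)
  tr <- gen_state_trace(p2, 5e5)
  expect_lt(abs(mean(tr$states) - 0.6), 0.02)

  expect_error(gen_state_trace(p, 1), ">= 2")
  expect_error(switching_params(5, 5, dt = 0), "dt")
  expect_error(switching_params(-1, 5), "> 0")
})

test_that("sampled dwell durations are exponential with the generating mean", {
  p <- switching_params(5, 3, dt = 0.05, seed = 11L)
  tr <- gen_state_trace(p, 4e5)
  dw <- attr(tr, "dwells")
  start_hb <- attr(tr, "start_hb")
  odd <- dw[seq(1, length(dw), by = 2)]
  even <- dw[seq(2, length(dw), by = 2)]
  hb <- if (start_hb) odd else even
  non <- if (start_hb) even else odd
  expect_gt(length(hb) + length(non), 1e3)
  expect_gt(stats::ks.test(hb, "pexp", rate = 1 / 5)$p.value, 0.01)
  expect_gt(stats::ks.test(non, "pexp", rate = 1 / 3)$p.value, 0.01)
})

test_that("field traces follow the state-conditional mixture", {
  p <- switching_params(6, 4, field_hb_mean = -50, field_hb_sd = 0,
                        field_non_mean = -10, field_non_sd = 0,
                        dt = 0.1, seed = 3L)
  st <- gen_state_trace(p, 2000)
  fl <- gen_field_trace(st, p)
  expect_setequal(unique(fl$fields), c(-50, -10))
  expect_true(all(fl$fields[st$states == 1] == -50))

  # mixture mean vs occupancy-weighted closed form at large n
  p2 <- switching_params(6, 4, field_hb_mean = -60, field_hb_sd = 10,
                         field_non_mean = -20, field_non_sd = 8,
                         dt = 0.1, seed = 1L)
  st2 <- gen_state_trace(p2, 1e6)
  fl2 <- gen_field_trace(st2, p2)
  occ <- mean(st2$states)
  expected <- occ * -60 + (1 - occ) * -20
  expect_lt(abs(mean(fl2$fields) - expected), 3 * 10 / sqrt(1e6) * 10)

  # single-state trace: CLT bound on the sample mean
  p3 <- switching_params(1e6, 1e-6, field_hb_mean = -40, field_hb_sd = 5,
                         dt = 0.1, seed = 9L)
  st3 <- gen_state_trace(p3, 1e4)
  stopifnot(all(st3$states == 1))
  fl3 <- gen_field_trace(st3, p3)
  expect_lt(abs(mean(fl3$fields) + 40), 3 * 5 / sqrt(1e4))
})

test_that("gen_scene round-trips its geometric specification", {
  cases <- list(c(3.00, 180, 0), c(2.93, 167, 10), c(3.5, 120, 25),
                c(4.2, 95, 45))
  for (cs in cases) {
    fr <- gen_scene(scene_spec(cs[1], cs[2], cs[3]))
    g <- measure_geometry(fr, 4, c(5, 6))
    expect_equal(unname(g["d_nx"]), cs[1], tolerance = 1e-6)
    expect_equal(unname(g["theta_cnx"]), cs[2], tolerance = 1e-6)
    expect_equal(unname(g["theta_nxh"]), cs[3], tolerance = 1e-6)
  }
  expect_error(gen_scene(scene_spec(0.1, 180, 0)), "infeasible-geometry")
})

test_that("scene parameter levels carry the requested terms", {
  f1 <- gen_scene(scene_spec(3, 160, 10, parameter_level = "charges-only"))
  expect_true(all(c(f1$sites$dx, f1$sites$qzz, f1$sites$alpha) == 0))
  f2 <- gen_scene(scene_spec(3, 160, 10, parameter_level = "multipoles"))
  expect_true(any(f2$sites$dx != 0 | f2$sites$dz != 0))
  expect_true(all(f2$sites$alpha == 0))
  f3 <- gen_scene(scene_spec(3, 160, 10,
                             parameter_level = "multipoles+polarizabilities"))
  expect_true(any(f3$sites$alpha > 0))
})

test_that("geometry samples match their generating distribution", {
  n <- 1e5
  # center far from the angular bounds: truncation is negligible and the
  # plain CLT bound applies
  s <- gen_geometry_samples(120, 3.00, 10, 0.10, rho = 0, n = n, seed = 1L)
  expect_equal(nrow(s), n)
  expect_lt(abs(stats::cor(s$theta, s$d)), 0.02)
  expect_lt(abs(mean(s$theta) - 120), 3 * 10 / sqrt(n))
  expect_lt(abs(mean(s$d) - 3.00), 3 * 0.10 / sqrt(n))
  expect_true(all(s$theta >= 0 & s$theta <= 180))
  expect_true(all(s$d > 0))
  expect_true(attr(s, "rejection_fraction") >= 0)

  # center near the 180-degree bound: rejection truncates the upper tail,
  # so the sample mean sits below the nominal center and the rejection
  # fraction is materially nonzero
  st <- gen_geometry_samples(163, 3.00, 12, 0.08, rho = 0, n = n, seed = 1L)
  expect_true(all(st$theta <= 180))
  expect_lt(mean(st$theta), 163)
  expect_gt(attr(st, "rejection_fraction"), 0.02)

  s2 <- gen_geometry_samples(100, 3, 20, 0.1, rho = 0.5, n = 1e4, seed = 2L)
  expect_gt(stats::cor(s2$theta, s2$d), 0.3)
  expect_error(gen_geometry_samples(163, 3, 10, 0.1, rho = 1.2, n = 10),
               "rho")
})

test_that("synthetic spectra are sums of pseudo-Voigt bands plus noise", {
  grid <- seq(2200, 2280, by = 0.1)
  sp <- gen_spectrum(list(band_model(2230.8, 8, 1)), 0, grid)
  expect_equal(sp$wavenumber[which.max(sp$absorbance)], 2230.8,
               tolerance = 0.11)

  sp2 <- gen_spectrum(list(band_model(2230.1, 8, 1),
                           band_model(2246.9, 8, 3)), 0, grid)
  y <- sp2$absorbance
  n <- length(y)
  n_max <- sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
  expect_equal(n_max, 2)

  sp3 <- gen_spectrum(list(), 0.01, grid, seed = 5L)
  expect_lt(abs(stats::sd(sp3$absorbance) - 0.01), 0.002)
  expect_lt(abs(mean(sp3$absorbance)), 0.002)

  expect_error(gen_spectrum(list(), 0, numeric(0)), "grid")
  expect_error(gen_spectrum(list(), 0, c(2, 1)), "increasing")

  # determinism
  expect_identical(gen_spectrum(list(band_model(2230, 8, 1)), 0.01, grid,
                                seed = 8L),
                   gen_spectrum(list(band_model(2230, 8, 1)), 0.01, grid,
                                seed = 8L))
})
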