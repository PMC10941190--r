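donors_of_scene <- function() donor_set(4L, list(c(5L, 6L)))

test_that("H-bond detection applies distance and hydrogen-angle cutoffs", {
  hits <- function(d, th_cnx, th_nxh, ...) {
    nrow(detect_hbond(gen_scene(scene_spec(d, th_cnx, th_nxh)),
                      donors_of_scene(), ...))
  }
  expect_equal(hits(3.0, 160, 10), 1)
  expect_equal(hits(4.5, 160, 10), 0)   # distance fail
  expect_equal(hits(3.0, 160, 45), 0)   # angle fail
  expect_equal(hits(3.9, 160, 10), 1)
  expect_equal(hits(3.9, 160, 10, cutoff_d = 3.5), 0)  # alternate cutoff

  # theta_CNX is recorded but is not a criterion
  r <- detect_hbond(gen_scene(scene_spec(3.0, 100, 10)), donors_of_scene())
  expect_equal(nrow(r), 1)
  expect_equal(r$theta_cnx, 100, tolerance = 1e-6)

  # donors without hydrogens are skipped with a warning
  expect_warning(
    r2 <- detect_hbond(gen_scene(scene_spec(3.0, 160, 10)),
                       donor_set(4L, list(integer(0)))),
    "no hydrogens")
  expect_equal(nrow(r2), 0)
})

test_that("classify_trace recovers generator states through scenes", {
  p <- switching_params(6, 4, dt = 1, seed = 13L)
  st <- gen_state_trace(p, 60)
  frames <- lapply(seq_along(st$states), function(i) {
    scene_for_state(st$states[i], time = st$times[i])
  })
  tr <- classify_trace(frames, donors_of_scene())
  expect_identical(tr$states, st$states)
  expect_equal(nrow(tr$records), sum(st$states))

  # unordered frames are rejected
  expect_error(classify_trace(rev(frames), donors_of_scene()),
               "time-ordered")

  # all H-bond-free frames give an all-zero trace
  far <- lapply(1:5, function(i) gen_scene(scene_spec(6, 160, 10),
                                           time = i))
  expect_true(all(classify_trace(far, donors_of_scene())$states == 0L))
})

test_that("two simultaneous donors give one state but two records", {
  fr <- gen_scene(scene_spec(3.0, 160, 10))
  # second donor: mirror the existing water across the xz plane normal
  s <- fr$sites
  extra <- s[4:6, ]
  extra$y <- extra$y + 0.0
  extra$x <- -extra$x
  extra$group <- "donor2"
  both <- rbind(as.data.frame(s), as.data.frame(extra))
  class(both) <- c("atom_sites", "data.frame")
  fr2 <- md_frame(both, 1:3)
  donors <- donor_set(c(4L, 7L), list(c(5L, 6L), c(8L, 9L)),
                      donor_class = c("solvent", "protein"))
  tr <- classify_trace(list(fr2), donors)
  expect_identical(tr$states, 1L)
  expect_equal(nrow(tr$records), 2)
})

test_that("fraction_weighted matches direct arithmetic on printed-style inputs", {
  expect_equal(fraction_weighted(51.5, 48.5, -24.8, -6.9), -16.1185)
  expect_equal(fraction_weighted(74.0, 26.0, -78.6, -33.5), -66.874)
  expect_equal(fraction_weighted(0, 100, NA, -15.4), -15.4)
  expect_equal(fraction_weighted(50, 50, -50, -10), -30)
  expect_error(fraction_weighted(120, 48.5, -24.8, -6.9), "\\[0, 100\\]")

  # invariance to simultaneous scaling once normalized by the sum
  w1 <- fraction_weighted(60, 40, -50, -10)
  w2 <- fraction_weighted(30, 20, -50, -10) * 100 / 50
  expect_equal(w1, w2)
})

test_that("population summary handles degenerate and mixture traces", {
  # all frames non-H-bonded: absent H-bonded median, weighted = median_non
  ps0 <- population_summary(rep(-15.4, 100), rep(0L, 100))
  expect_equal(ps0$frac_hb, 0)
  expect_true(is.na(ps0$median_hb))
  expect_equal(ps0$weighted_field, -15.4)

  # two-value trace, 50/50
  f <- c(rep(-50, 50), rep(-10, 50))
  s <- c(rep(1L, 50), rep(0L, 50))
  ps <- population_summary(f, s)
  expect_equal(ps$median_hb, -50)
  expect_equal(ps$median_non, -10)
  expect_equal(ps$weighted_field, -30)

  # mixture-generated: medians near generating means
  p <- switching_params(6, 4, field_hb_mean = -60, field_hb_sd = 10,
                        field_non_mean = -20, field_non_sd = 8,
                        dt = 0.1, seed = 2L)
  st <- gen_state_trace(p, 1e5)
  fl <- gen_field_trace(st, p)
  traj <- rep(1:2, each = 5e4)
  psm <- population_summary(fl, st, trajectory = traj)
  se_hb <- 1.2533 * 10 / sqrt(sum(st$states))    # se of a normal median
  se_non <- 1.2533 * 8 / sqrt(sum(st$states == 0))
  expect_lt(abs(psm$median_hb - -60), 3 * se_hb + 0.1)
  expect_lt(abs(psm$median_non - -20), 3 * se_non + 0.1)
  expect_false(is.na(psm$weighted_err))
  expect_true(psm$weighted_field > psm$median_hb &&
                psm$weighted_field < psm$median_non)

  # two-trajectory error convention: half the absolute difference
  f2 <- c(rep(-10, 10), rep(-20, 10))
  s2 <- rep(0L, 20)
  ps2 <- population_summary(f2, s2, trajectory = rep(1:2, each = 10))
  expect_equal(ps2$median_non_err, abs(-10 - -20) / 2)
})

test_that("population medians are invariant to frame permutation", {
  withr::with_seed(4L, {
    f <- stats::rnorm(500, -30, 10)
    s <- stats::rbinom(500, 1, 0.4)
    perm <- sample(500)
  })
  a <- population_summary(f, s)
  b <- population_summary(f[perm], s[perm])
  expect_equal(a$median_hb, b$median_hb)
  expect_equal(a$median_non, b$median_non)
  expect_equal(a$frac_hb, b$frac_hb)
})

test_that("tightening the distance cutoff can only reduce the H-bond fraction", {
  withr::with_seed(6L, {
    ds <- stats::runif(40, 2.8, 4.4)
  })
  frames <- lapply(seq_along(ds), function(i) {
    gen_scene(scene_spec(ds[i], 160, 10), time = i)
  })
  frac <- function(cut) {
    mean(classify_trace(frames, donors_of_scene(), cutoff_d = cut)$states)
  }
  expect_lte(frac(3.5), frac(4.0))
})

test_that("donor identity fractions follow the attribution rules", {
  rec <- function(frame, cls) {
    data.frame(frame_index = frame, donor_id = "d", donor_class = cls,
               d_nx = 3, theta_cnx = 160, theta_nxh = 10,
               stringsAsFactors = FALSE)
  }
  all_solv <- do.call(rbind, lapply(1:5, rec, cls = "solvent"))
  expect_equal(donor_identity_fractions(all_solv)[["solvent"]], 100)

  mix <- rbind(do.call(rbind, lapply(1:9, rec, cls = "solvent")),
               rec(10, "protein"))
  dif <- donor_identity_fractions(mix)
  expect_equal(dif[["solvent"]], 90)
  expect_equal(dif[["protein"]], 10)

  # frame with both classes: fractional vs protein-wins attribution
  both <- rbind(rec(1, "solvent"), rec(1, "protein"), rec(2, "solvent"))
  expect_equal(donor_identity_fractions(both)[["solvent"]], 75)
  expect_equal(
    donor_identity_fractions(both, "protein-wins")[["protein"]], 50)
})

test_that("field histograms partition the total", {
  p <- switching_params(6, 4, dt = 0.1, seed = 3L)
  st <- gen_state_trace(p, 2e4)
  fl <- gen_field_trace(st, p)
  h <- field_histogram(fl, st, bin_width = 2)
  expect_equal(h$total, h$hb + h$non, tolerance = 1e-12)
  expect_equal(sum(h$total) * 2, 1, tolerance = 1e-12)

  # histogram mean close to the mixture mean
  hmean <- sum(h$mids * h$total) / sum(h$total)
  expect_lt(abs(hmean - mean(fl$fields)), 2 / 2 + 0.2)

  # single-population trace: other component identically zero
  h1 <- field_histogram(fl$fields, rep(1L, length(fl$fields)))
  expect_true(all(h1$non == 0))
  expect_error(field_histogram(fl, st, bin_width = 0), "bin_width")
})
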