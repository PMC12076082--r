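# Density profiles, coexisting-density extraction, and critical-point
# fitting.

test_that("density profile conserves total mass exactly", {
  p <- slab_gen_params(box = c(80, 80, 600), rho_h = 280, rho_l = 15,
                       n_molecules = 30, beads_per_molecule = 12,
                       n_frames = 4, seed = 6)
  tr <- gen_slab_trajectory(p)
  pr <- density_profile(tr, bin_width = 10, discard_frac = 0)
  binned_mass <- sum(pr$rho) / condensatr:::.DA_PER_A3_IN_MG_ML *
    (80 * 80 * pr$bin_width)
  expect_equal(binned_mass, sum(tr$mass), tolerance = 1e-9)
})

test_that("uniform beads give a flat profile and a one-phase verdict", {
  set.seed(10)
  n <- 20000L
  f <- cbind(runif(n, 0, 60), runif(n, 0, 60), runif(n, 0, 600))
  tr <- slab_trajectory(list(f), mol = rep(1:200, each = 100),
                        mass = rep(110, n), box = c(60, 60, 600),
                        temperature = 300)
  pr <- density_profile(tr, bin_width = 20, discard_frac = 0)
  expect_lt(max(pr$rho) / min(pr$rho), 1.6)
  v <- coexisting_densities(pr)
  expect_true(v$one_phase)
})

test_that("beads concentrated on one plane land in a single bin", {
  n <- 500L
  f <- cbind(runif(n, 0, 50), runif(n, 0, 50), rep(0, n))
  tr <- slab_trajectory(list(f), mol = seq_len(n), mass = rep(110, n),
                        box = c(50, 50, 500), temperature = 300)
  pr <- density_profile(tr, bin_width = 10, discard_frac = 0)
  expect_equal(sum(pr$rho > 0), 1L)
})

test_that("an ideal step profile yields the plateau densities within 2%", {
  # build a synthetic profile object directly: 300 inside, 10 outside
  z <- seq(5, 1995, by = 10)
  rho <- ifelse(abs(z - 1000) < 300, 300, 10)
  pr <- structure(list(z = z, rho = rho, n_frames = 1L, bin_width = 10,
                       box = c(100, 100, 2000), temperature = 310,
                       total_mass = NA),
                  class = "density_profile")
  cp <- coexisting_densities(pr)
  expect_false(cp$one_phase)
  expect_lt(abs(cp$rho_h - 300) / 300, 0.02)
  expect_lt(abs(cp$rho_l - 10) / 10, 0.02)
})

test_that("generated slabs reproduce their generating binodal point", {
  sp <- lcd2_ctpr_spec("LCD2-CTPR3")
  tc <- 335
  pt <- gen_binodal_points(tc, 170, 3e8, -0.3, 0.95 * tc)
  p <- slab_gen_params(box = c(150, 150, 4000), rho_h = pt$rho_h,
                       rho_l = pt$rho_l, n_molecules = 140, construct = sp,
                       n_frames = 12, temperature = pt$T, seed = 31)
  tr <- gen_slab_trajectory(p)
  cp <- coexisting_densities(density_profile(tr, bin_width = 10))
  expect_false(cp$one_phase)
  expect_lt(abs(cp$rho_h - pt$rho_h) / pt$rho_h, 0.05)
  expect_lt(abs(cp$rho_l - pt$rho_l) / pt$rho_l, 0.05)
})

test_that("binodal fitting inverts the generator exactly on noiseless input", {
  cases <- list(c(346, 300, 1e7, -0.5), c(357, 250, 5e7, 0),
                c(316, 400, 2e6, -1.2))
  for (cs in cases) {
    temps <- seq(0.85, 0.99, length.out = 10) * cs[1]
    pts <- gen_binodal_points(cs[1], cs[2], cs[3], cs[4], temps)
    f <- fit_binodal(pts)
    expect_lt(abs(f$tc - cs[1]) / cs[1], 1e-3)
    expect_lt(abs(f$rho_c - cs[2]) / cs[2], 1e-3)
    expect_lt(abs(f$d - cs[3]) / cs[3], 1e-3)
    if (cs[4] == 0) {
      expect_lt(abs(f$A), 1e-6)
      expect_equal(f$rho_c, mean((pts$rho_l + pts$rho_h) / 2),
                   tolerance = 1e-9)
    } else {
      expect_lt(abs(f$A - cs[4]) / abs(cs[4]), 1e-3)
    }
  }
})

test_that("joint refinement agrees with the sequential fit on clean data", {
  temps <- seq(0.86, 0.98, length.out = 8) * 340
  pts <- gen_binodal_points(340, 280, 2e7, -0.4, temps)
  fs <- fit_binodal(pts, method = "sequential")
  fj <- fit_binodal(pts, method = "joint")
  expect_equal(fj$tc, fs$tc, tolerance = 1e-4)
  expect_equal(fj$rho_c, fs$rho_c, tolerance = 1e-4)
})

test_that("degenerate binodal input is rejected", {
  pts <- gen_binodal_points(340, 280, 2e7, 0, c(300, 320))
  expect_error(fit_binodal(pts), "at least 3")
  pts3 <- data.frame(T = c(300, 300, 300), rho_l = c(1, 2, 3),
                     rho_h = c(10, 11, 12))
  expect_error(fit_binodal(pts3), "distinct")
  bad <- data.frame(T = c(300, 310, 320), rho_l = c(10, 10, 10),
                    rho_h = c(10, 10, 10))
  expect_error(fit_binodal(bad), "two-phase")
})

test_that("the density gap shrinks monotonically to zero at Tc", {
  set.seed(77)
  for (i in 1:10) {
    tc <- runif(1, 310, 380)
    pts <- gen_binodal_points(tc, runif(1, 100, 400), 10^runif(1, 6, 9),
                              runif(1, -1, 0.2),
                              seq(0.82, 0.995, length.out = 12) * tc)
    gap <- pts$rho_h - pts$rho_l
    expect_true(all(diff(gap) < 0))
    expect_gt(min(gap), 0)
  }
})

test_that("normalised binodal rescales linearly and preserves ordering", {
  temps <- seq(0.85, 0.98, length.out = 8)
  f3 <- fit_binodal(gen_binodal_points(335, 300, 1e7, -0.5, temps * 335))
  f2 <- fit_binodal(gen_binodal_points(316, 300, 1e7, -0.5, temps * 316))
  f4 <- fit_binodal(gen_binodal_points(357, 300, 1e7, -0.5, temps * 357))
  ref <- f3$tc
  a2 <- attr(normalised_binodal(f2, ref), "apex")
  a3 <- attr(normalised_binodal(f3, ref), "apex")
  a4 <- attr(normalised_binodal(f4, ref), "apex")
  expect_equal(a3, 1, tolerance = 1e-6)   # own Tc as reference: apex at 1
  expect_lt(a2, 1)                        # fewer repeats: apex below 1
  expect_gt(a4, 1)                        # more repeats: apex above 1
  # doubling the reference halves every normalised temperature
  nb1 <- normalised_binodal(f3, ref)
  nb2 <- normalised_binodal(f3, 2 * ref)
  expect_equal(nb2$T_norm, nb1$T_norm / 2)
})

test_that("six-temperature slab pipeline recovers the planted Tc within 3%", {
  sp <- lcd2_ctpr_spec("LCD2-CTPR4")
  tc <- 357
  temps <- seq(0.85, 0.97, length.out = 6) * tc
  pts <- gen_binodal_points(tc, 170, 3e8, -0.3, temps)
  trajs <- lapply(seq_len(6), function(i) {
    gen_slab_trajectory(slab_gen_params(
      box = c(150, 150, 4000), rho_h = pts$rho_h[i], rho_l = pts$rho_l[i],
      n_molecules = 140, construct = sp, n_frames = 8,
      temperature = pts$T[i], seed = 100 + i))
  })
  cx <- slab_coexistence(trajs, bin_width = 10)
  expect_equal(nrow(cx), 6L)
  f <- fit_binodal(cx)
  expect_lt(abs(f$tc - tc) / tc, 0.03)
})
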