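# Ground-truth generators: determinism, conservation laws, and exact
# satisfaction of the coexistence laws.

test_that("generators are pure functions of their parameters", {
  p <- slab_gen_params(box = c(80, 80, 500), rho_h = 300, rho_l = 10,
                       n_molecules = 40, beads_per_molecule = 15,
                       n_frames = 3, seed = 21)
  t1 <- gen_slab_trajectory(p)
  t2 <- gen_slab_trajectory(p)
  expect_identical(t1$frames, t2$frames)

  s1 <- gen_phasescan(scan_gen_params(n_droplets = 100, seed = 9))
  s2 <- gen_phasescan(scan_gen_params(n_droplets = 100, seed = 9))
  expect_identical(s1, s2)

  i1 <- gen_condensate_image(image_gen_params(
    centres = cbind(5, 5), radii = 1.5, noise_sd = 10, seed = 2))
  i2 <- gen_condensate_image(image_gen_params(
    centres = cbind(5, 5), radii = 1.5, noise_sd = 10, seed = 2))
  expect_identical(i1$green, i2$green)

  # and they do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_phasescan(scan_gen_params(n_droplets = 10)))
  expect_identical(runif(1), before)
})

test_that("slab generator conserves molecules and mass across frames", {
  p <- slab_gen_params(box = c(80, 80, 500), rho_h = 300, rho_l = 10,
                       n_molecules = 40, beads_per_molecule = 15,
                       n_frames = 4, seed = 3)
  tr <- gen_slab_trajectory(p)
  expect_length(tr$frames, 4L)
  expect_equal(length(unique(tr$mol)), 40L)
  for (f in tr$frames) {
    expect_equal(nrow(f), 40L * 15L)
    expect_true(all(f >= 0 & f <= matrix(tr$box, nrow(f), 3, byrow = TRUE)))
  }
  expect_equal(sum(tr$mass), 40 * 15 * 110)
})

test_that("slab generator hits requested plateau densities within 5%", {
  sp <- lcd2_ctpr_spec("LCD2-CTPR4")
  p <- slab_gen_params(box = c(150, 150, 6000), rho_h = 300, rho_l = 10,
                       n_molecules = 140, construct = sp, n_frames = 20,
                       seed = 11)
  tr <- gen_slab_trajectory(p)
  pr <- density_profile(tr, bin_width = 10, discard_frac = 0.5)
  # direct bead-mass binning against the generating geometry
  geo <- condensatr:::.slab_geometry(p)
  zc <- 3000
  central <- pr$z > zc - 0.5 * geo$halfwidth & pr$z < zc + 0.5 * geo$halfwidth
  outer <- pr$z < zc - 2 * geo$halfwidth | pr$z > zc + 2 * geo$halfwidth
  expect_lt(abs(mean(pr$rho[central]) - 300) / 300, 0.05)
  expect_lt(abs(mean(pr$rho[outer]) - 10) / 10, 0.25)
})

test_that("zero dilute density puts every molecule in the slab", {
  p <- slab_gen_params(box = c(80, 80, 800), rho_h = 300, rho_l = 0,
                       n_molecules = 30, beads_per_molecule = 10,
                       n_frames = 2, bead_sd = 3, seed = 5)
  tr <- gen_slab_trajectory(p)
  geo <- condensatr:::.slab_geometry(p)
  margin <- 5 * 3  # bead cloud spread
  for (f in tr$frames) {
    expect_true(all(abs(f[, 3L] - 400) <= geo$halfwidth + margin))
  }
})

test_that("unachievable densities raise an informative error", {
  expect_error(
    gen_slab_trajectory(slab_gen_params(
      box = c(80, 80, 500), rho_h = 900, rho_l = 800,
      n_molecules = 5, beads_per_molecule = 10, seed = 1)),
    "unachievable")
})

test_that("binodal points satisfy both coexistence laws to machine precision", {
  tc <- 346; rho_c <- 300; d <- 1e7; A <- -0.5
  temps <- seq(0.85, 0.99, length.out = 10) * tc
  pts <- gen_binodal_points(tc, rho_c, d, A, temps)
  lhs4 <- (pts$rho_h - pts$rho_l)^3.06
  rhs4 <- d * (1 - pts$T / tc)
  expect_equal(lhs4, rhs4, tolerance = 1e-12)
  lhs5 <- pts$rho_h + pts$rho_l
  rhs5 <- 2 * rho_c + 2 * A * (pts$T - tc)
  expect_equal(lhs5, rhs5, tolerance = 1e-12)
  # critical closure: difference vanishes and midpoint -> rho_c near tc
  near <- gen_binodal_points(tc, rho_c, d, A, tc * (1 - 1e-12))
  expect_lt(near$rho_h - near$rho_l, 0.05)
  expect_equal((near$rho_h + near$rho_l) / 2, rho_c, tolerance = 1e-6)
  # A = 0 keeps the midpoint constant
  pts0 <- gen_binodal_points(tc, rho_c, d, 0, temps)
  expect_equal((pts0$rho_h + pts0$rho_l) / 2, rep(rho_c, 10))
  expect_error(gen_binodal_points(tc, rho_c, d, A, c(300, tc)), "below tc")
})

test_that("csat generator reproduces the exact piecewise law when noiseless", {
  g <- gen_csat_series(csat_gen_params(
    m = 2, c = 50, x_grid = c(1, 2, 5, 10, 24.9, 30), noise_sd = 0))
  below <- g$series$x < 25
  expect_equal(g$series$y[below], 2 * g$series$x[below])   # on the line
  expect_equal(g$series$y[!below], rep(50, sum(!below)))   # on the plateau
  # calibration table is exactly linear when noiseless
  expect_equal(g$calibration$band_density,
               1.7 * g$calibration$concentration)
  # grid must span the breakpoint
  expect_error(csat_gen_params(m = 1, c = 0.1, x_grid = c(1, 2, 3, 4)),
               "span")
})

test_that("image generator plants exact geometry and intensity ratio", {
  # zero disks: flat image
  flat <- gen_condensate_image(image_gen_params(
    centres = matrix(numeric(0), 0, 2), radii = numeric(0),
    intensity_bg = 100, noise_sd = 0))
  expect_true(all(flat$green == 100))
  # planted 5x ratio, no noise
  img <- gen_condensate_image(image_gen_params(
    centres = cbind(6.4, 6.4), radii = 2, intensity_in = 500,
    intensity_bg = 100, noise_sd = 0))
  expect_equal(mean(img$green[img$truth$mask]) /
                 mean(img$green[!img$truth$mask]), 5)
  # disks must fit inside the frame
  expect_error(image_gen_params(centres = cbind(0.2, 5), radii = 1),
               "inside the frame")
})
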