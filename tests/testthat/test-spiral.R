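traj32 <- make_spiral(64, 32, 9.2)
arms32 <- 0:(traj32$n_arms_full - 1)

test_that("spiral reaches the Nyquist radius at the end of the readout", {
  k_end <- Mod(traj32$arm_k[length(traj32$arm_k)])
  expect_equal(k_end, 32 / (2 * 64), tolerance = 1e-9)
  expect_equal(traj32$t_ms[1], traj32$te_ms)
  expect_equal(max(traj32$t_ms) - min(traj32$t_ms), 9.2)
})

test_that("arm i is arm 0 rotated by i * 360 / n_arms degrees", {
  a3 <- arm_coordinates(traj32, 3)
  rot <- traj32$arm_k * exp(1i * 3 * 2 * pi / traj32$n_arms_full)
  expect_equal(a3, rot, tolerance = 1e-12)
  expect_error(arm_coordinates(traj32, traj32$n_arms_full), "out of range")
  expect_error(make_spiral(64, 32, 9.2, n_arms_full = 0), "at least 1")
})

test_that("full arm set passes a brute-force Nyquist gap check", {
  traj <- make_spiral(220, 110, 9.2)
  pts <- unlist(lapply(0:(traj$n_arms_full - 1),
                       function(a) arm_coordinates(traj, a)))
  kmax <- 110 / (2 * 220)
  dk <- 1 / 220
  # within each annulus of width 1/FOV the azimuthal gap between sampled
  # points stays a small multiple of 1/FOV; with half the arms removed the
  # same check degrades roughly twofold
  max_gap <- function(points, r) {
    sel <- abs(Mod(points) - r) <= dk / 2
    ang <- sort(Arg(points[sel]))
    max(diff(c(ang, ang[1] + 2 * pi))) * r
  }
  half <- unlist(lapply(seq(0, traj$n_arms_full - 1, by = 2),
                        function(a) arm_coordinates(traj, a)))
  radii <- seq(5 * dk, kmax - dk / 2, by = 5 * dk)
  for (r in radii) {
    g_full <- max_gap(pts, r)
    expect_lt(g_full, 2 * dk)
    expect_gt(max_gap(half, r), 1.5 * g_full)
  }
})

test_that("forward sampling matches analytic point-source phases", {
  n <- 32
  pt <- matrix(0 + 0i, n, n)
  pt[20, 14] <- 1
  xy <- (seq_len(n) - 1 - n / 2) * (64 / n)
  k <- arm_coordinates(traj32, 2)
  s0 <- forward_sample(pt, traj32, 2)
  expect_equal(s0, exp(-2i * pi * (Re(k) * xy[20] + Im(k) * xy[14])),
               tolerance = 1e-12)
  # off-resonant point source accrues exp(i 2 pi f t)
  f0 <- 55
  s1 <- forward_sample(pt, traj32, 2, b0map = matrix(f0, n, n))
  expect_equal(s1, s0 * exp(2i * pi * f0 * traj32$t_ms / 1000),
               tolerance = 1e-12)
  # zero image, zero field
  expect_equal(max(Mod(forward_sample(matrix(0 + 0i, n, n), traj32, 0))), 0)
  expect_equal(forward_sample(pt, traj32, 2, b0map = matrix(0, n, n)), s0)
})

test_that("reconstruction is linear and zero-preserving", {
  n <- 32
  g1 <- gaussian_phantom(n, 64, 6)
  g2 <- gaussian_phantom(n, 64, 10) * (0.5 + 0.5i)
  k1 <- unlist(lapply(arms32, function(a) forward_sample(g1, traj32, a)))
  k2 <- unlist(lapply(arms32, function(a) forward_sample(g2, traj32, a)))
  a <- 2 - 1i; b <- 0.3 + 0.4i
  lhs <- grid_recon(a * k1 + b * k2, traj32, arms32)
  rhs <- a * grid_recon(k1, traj32, arms32) + b * grid_recon(k2, traj32, arms32)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_equal(max(Mod(grid_recon(rep(0 + 0i, length(k1)), traj32, arms32))), 0)
  expect_error(grid_recon(k1[-1], traj32, arms32), "sample count")
})

test_that("least-squares recon of a fully sampled smooth phantom is faithful", {
  g <- gaussian_phantom(32, 64, 6)
  ks <- unlist(lapply(arms32, function(a) forward_sample(g, traj32, a)))
  rec <- grid_recon(ks, traj32, arms32, method = "lsq")
  nrmse <- sqrt(mean(Mod(rec - g)^2)) / sqrt(mean(Mod(g)^2))
  expect_lt(nrmse, 0.05)
})

test_that("deblurring is exact for zero and constant off-resonance", {
  g <- gaussian_phantom(32, 64, 6)
  n <- 32
  ks <- unlist(lapply(arms32, function(a) forward_sample(g, traj32, a)))
  plain <- grid_recon(ks, traj32, arms32)
  expect_equal(mfi_deblur(ks, traj32, matrix(0, n, n), arms32), plain,
               tolerance = 1e-10)
  # constant b0: deblurring equals recon of globally demodulated data
  b0c <- matrix(70, n, n)
  ksb <- unlist(lapply(arms32, function(a) {
    forward_sample(g, traj32, a, b0map = b0c)
  }))
  dem <- ksb * exp(-2i * pi * 70 * rep(traj32$t_ms, length(arms32)) / 1000)
  expect_equal(mfi_deblur(ksb, traj32, b0c, arms32),
               grid_recon(dem, traj32, arms32), tolerance = 1e-10)
  expect_error(mfi_deblur(ksb, traj32, b0c, arms32, n_bins = 0), "n_bins")
})

test_that("deblurring reduces the error of a two-compartment field", {
  n <- 32
  g <- gaussian_phantom(n, 64, 6)
  b02 <- matrix(-80, n, n)
  b02[, (n / 2 + 1):n] <- 80
  ks <- unlist(lapply(arms32, function(a) {
    forward_sample(g, traj32, a, b0map = b02)
  }))
  rmse <- function(x) sqrt(mean(Mod(x - g)^2))
  uncorr <- rmse(grid_recon(ks, traj32, arms32, method = "lsq"))
  deblur <- rmse(mfi_deblur(ks, traj32, b02, arms32, method = "lsq"))
  expect_lt(deblur, uncorr)
})

test_that("trajectory text files round trip", {
  path <- tempfile(fileext = ".txt")
  write_trajectory(traj32, path)
  t2 <- read_trajectory(path)
  expect_equal(t2$arm_k, traj32$arm_k, tolerance = 1e-12)
  expect_equal(t2$dcf, traj32$dcf, tolerance = 1e-12)
  expect_equal(t2$n_arms_full, traj32$n_arms_full)
  expect_equal(t2$fov_mm, traj32$fov_mm)
})
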