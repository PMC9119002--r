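c0 <- 1540

test_that("zero-length propagation is the identity", {
  k <- seq(-300, 300, length.out = 101)
  H <- propagator(k, propagator_spec(0.06, 0.06, c0, "-"), 4e6)
  expect_equal(H, rep(1 + 0i, length(k)))
})

test_that("k_theta = 0 takes the plane-radial-wave limit", {
  for (br in c("-", "+")) {
    sgn <- if (br == "+") 1 else -1
    H <- propagator(0, propagator_spec(0.05, 0.08, c0, br), 3.5e6)
    expect_equal(H, exp(sgn * 2i * pi * 3.5e6 * 0.03 / c0), tolerance = 1e-12)
  }
})

test_that("propagating modes have exactly unit modulus", {
  set.seed(11)
  n <- 1e4
  f <- runif(n, 1e6, 6e6)
  r1 <- runif(n, 0.04, 0.08); r2 <- r1 + runif(n, 0, 0.05)
  # draw k below the propagating cutoff at the smaller radius
  k <- runif(n) * f * pmin(r1, r2) / (c0 * 1.001)
  dev <- vapply(seq_len(n), function(i)
    abs(Mod(propagator(k[i], propagator_spec(r1[i], r2[i], c0, "-"), f[i])) - 1),
    0)
  expect_lt(max(dev), 1e-12)
})

test_that("opposite branches are exact inverses for propagating modes", {
  k <- seq(0, 100, length.out = 64)
  f <- 3.5e6; r1 <- 0.05; r2 <- 0.09
  keep <- k == 0 | f * r1 / (c0 * k) > 1.001
  Hm <- propagator(k, propagator_spec(r1, r2, c0, "-"), f)
  Hp <- propagator(k, propagator_spec(r1, r2, c0, "+"), f)
  expect_lt(max(abs(Hm[keep] * Hp[keep] - 1)), 1e-12)
})

test_that("propagators compose across intermediate shells", {
  set.seed(3)
  k <- runif(200, -150, 150)
  f <- 4e6; r1 <- 0.05; r2 <- 0.07; r3 <- 0.1
  keep <- abs(k) < f * r1 / (c0 * 1.001)
  H12 <- propagator(k, propagator_spec(r1, r2, c0, "-"), f)
  H23 <- propagator(k, propagator_spec(r2, r3, c0, "-"), f)
  H13 <- propagator(k, propagator_spec(r1, r3, c0, "-"), f)
  expect_lt(max(abs(H12[keep] * H23[keep] - H13[keep])), 1e-10)
})

test_that("the decay policy never amplifies", {
  k <- seq(-500, 500, length.out = 257)
  for (br in c("-", "+")) {
    H <- propagator(k, propagator_spec(0.05, 0.06, c0, br, "decay"), 2e6)
    expect_true(all(Mod(H) <= 1 + 1e-12))
  }
})

test_that("propagator at the smallest nonzero bin converges to the k = 0 limit", {
  f <- 3.5e6; sp <- propagator_spec(0.05, 0.07, c0, "-")
  lim <- propagator(0, sp, f)
  errs <- vapply(c(64, 256, 1024), function(n) {
    k1 <- fft_freqs(n, 0.01)[2]   # smallest positive bin; aperture n/100 rad
    abs(propagator(k1, sp, f) - lim)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("angular transform round-trips, isolates modes, and is unitary", {
  th <- small_theta(256, 0.6)
  set.seed(5)
  S <- complex(real = rnorm(256), imaginary = rnorm(256))
  back <- angular_transform(
    angular_transform(S, th, "inverse")$values, th, "forward")$values
  expect_lt(max(abs(back - S)), 1e-12 * max(abs(S)))
  k <- fft_freqs(256, diff(th)[1])
  x <- exp(2i * pi * k[17] * th)
  X <- angular_transform(x, th, "forward")$values
  expect_equal(which.max(Mod(X)), 17L)
  expect_lt(sort(Mod(X), decreasing = TRUE)[2], 1e-12 * max(Mod(X)))
  dth <- diff(th)[1]; dk <- 1 / (256 * dth)
  xr <- complex(real = rnorm(256), imaginary = rnorm(256))
  Xr <- angular_transform(xr, th, "forward")$values
  expect_equal(sum(Mod(xr)^2) * dth, sum(Mod(Xr)^2) * dk, tolerance = 1e-10)
  expect_error(angular_transform(xr, cumsum(runif(256)), "forward"), "uniform")
})

test_that("the angular window has a flat interior and cosine edges", {
  expect_equal(make_window(32, 0), rep(1, 32))
  w1 <- make_window(33, 1)
  expect_equal(w1[c(1, 33)], c(0, 0))
  expect_equal(w1[17], 1)
  for (tf in c(0.1, 0.5, 0.9)) {
    w <- make_window(65, tf)
    expect_equal(w[33], 1)
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(make_window(64, 1.2))
  expect_error(make_window(3, 0.5))
})

test_that("an extrapolation step with r2 = r1 and no window is the identity", {
  fld <- rand_field(128, c(2e6, 3.5e6), seed = 21)
  out <- asm_step(fld, propagator_spec(fld$radius, fld$radius, c0, "-"))
  expect_lt(max(abs(out$values - fld$values)), 1e-12 * max(abs(fld$values)))
})

test_that("a single angular mode is multiplied by its propagator value", {
  th <- small_theta(128, 0.5)
  k <- fft_freqs(128, diff(th)[1])
  x <- exp(2i * pi * k[9] * th)
  fld <- polar_field(matrix(x, ncol = 1), 0.05, 3.5e6, th)
  sp <- propagator_spec(0.05, 0.062, c0, "-")
  out <- asm_step(fld, sp)
  expect_equal(out$values[, 1], propagator(k[9], sp, 3.5e6) * x,
               tolerance = 1e-10)
})

test_that("one step matches the O(N^2) direct-sum evaluation", {
  fld <- rand_field(64, c(2.5e6, 4e6), seed = 8)
  sp <- propagator_spec(0.05, 0.055, c0, "-")
  w <- make_window(64, 0.25)
  fast <- asm_step(fld, sp, w)$values
  slow <- direct_sum_step(fld, sp, w)
  expect_lt(max(abs(fast - slow)), 1e-10 * max(abs(slow)))
})

test_that("a propagated central impulse stays symmetric about theta = 0", {
  th <- small_theta(257, 0.45)
  v <- matrix(0 + 0i, 257, 1)
  v[129, 1] <- 1
  fld <- polar_field(v, 0.05, 3.5e6, th)
  # 40 wavelengths outward
  r2 <- 0.05 + 40 * c0 / 3.5e6
  out <- asm_step(fld, propagator_spec(0.05, r2, c0, "-"),
                  make_window(257, 0.25))
  m <- Mod(out$values[, 1])
  expect_lt(max(abs(m - rev(m))), 1e-8 * max(m))
})

test_that("the windowed step never increases the per-frequency theta-RMS", {
  fld <- rand_field(128, c(1e6, 3e6, 5e6), seed = 13)
  out <- asm_step(fld, propagator_spec(0.05, 0.06, c0, "-"),
                  make_window(128, 0.25))
  rms_in <- sqrt(colMeans(Mod(fld$values)^2))
  rms_out <- sqrt(colMeans(Mod(out$values)^2))
  expect_true(all(rms_out <= rms_in * (1 + 1e-12)))
})

test_that("marching in k steps equals a single long step for constant c", {
  fld <- propagating_only(rand_field(128, c(2e6, 3.5e6, 5e6), seed = 30))
  grid <- polar_grid(fld$theta_axis, seq(0.05, 0.06, length.out = 11))
  cube <- asm_march(fld, grid, c0, "-", keep = 11L)
  one <- asm_step(fld, propagator_spec(0.05, 0.06, c0, "-"))
  rel <- sqrt(sum(Mod(cube$values[, 1, ] - one$values)^2) /
              sum(Mod(one$values)^2))
  expect_lt(rel, 1e-8)
})

test_that("a two-shell march is a single step, and grids are validated", {
  fld <- rand_field(64, 3e6, seed = 31)
  grid <- polar_grid(fld$theta_axis, c(0.05, 0.052))
  cube <- asm_march(fld, grid, c0, "-")
  step <- asm_step(fld, propagator_spec(0.05, 0.052, c0, "-"))
  expect_equal(cube$values[, 2, 1], step$values[, 1])
  bad <- polar_grid(fld$theta_axis, c(0.06, 0.062))
  expect_error(asm_march(fld, bad, c0), "radius")
})

test_that("a radially varying profile uses each interval's sound speed", {
  fld <- propagating_only(rand_field(64, 3e6, seed = 32))
  grid <- polar_grid(fld$theta_axis, seq(0.05, 0.053, length.out = 4))
  cs <- c(1450, 1540, 1600)
  cube <- asm_march(fld, grid, cs, "-")
  stepwise <- fld
  for (i in 1:3)
    stepwise <- asm_step(stepwise,
                         propagator_spec(grid$r[i], grid$r[i + 1], cs[i], "-"))
  expect_equal(cube$values[, 4, 1], stepwise$values[, 1], tolerance = 1e-12)
})
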