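c0 <- 1540

mk_pair <- function(n_theta = 64, seed = 40) {
  freqs <- c(2e6, 3e6, 4e6)
  tx <- rand_field(n_theta, freqs, seed = seed)
  rx <- rand_field(n_theta, freqs, seed = seed + 1)
  grid <- polar_grid(tx$theta_axis, seq(0.05, 0.054, length.out = 5))
  list(tx = tx, rx = rx, grid = grid)
}

test_that("a zero receive field yields a zero image", {
  p <- mk_pair()
  z <- polar_field(matrix(0 + 0i, 64, 3), 0.05, p$tx$freq_axis, p$tx$theta_axis)
  img <- migrate_shot(p$tx, z, p$grid, c0)
  expect_true(all(img$values == 0))
})

test_that("self-correlation at the array shell is real and non-negative", {
  p <- mk_pair()
  img <- migrate_shot(p$tx, p$tx, p$grid, c0, window = rep(1, 64))
  shell0 <- img$values[, 1]
  expect_lt(max(abs(Im(shell0))), 1e-12 * max(abs(shell0)))
  expect_true(all(Re(shell0) >= 0))
  expect_equal(Re(shell0), rowSums(Mod(p$tx$values)^2), tolerance = 1e-12)
})

test_that("per-shot images are conjugate-linear in tx and linear in rx", {
  p <- mk_pair(seed = 50)
  a <- 0.7 - 1.3i
  base <- migrate_shot(p$tx, p$rx, p$grid, c0)
  sc_tx <- migrate_shot(polar_field(a * p$tx$values, 0.05, p$tx$freq_axis,
                                    p$tx$theta_axis), p$rx, p$grid, c0)
  expect_equal(sc_tx$values, Conj(a) * base$values, tolerance = 1e-10)
  sc_rx <- migrate_shot(p$tx, polar_field(a * p$rx$values, 0.05,
                                          p$rx$freq_axis, p$rx$theta_axis),
                        p$grid, c0)
  expect_equal(sc_rx$values, a * base$values, tolerance = 1e-10)
  # superposition in rx
  p2 <- mk_pair(seed = 60)
  both <- migrate_shot(p$tx, polar_field(p$rx$values + p2$rx$values, 0.05,
                                         p$rx$freq_axis, p$rx$theta_axis),
                       p$grid, c0)
  other <- migrate_shot(p$tx, p2$rx, p$grid, c0)
  expect_equal(both$values, base$values + other$values, tolerance = 1e-10)
})

test_that("compiled and reference migration engines agree", {
  p <- mk_pair(seed = 70)
  ic <- migrate_shot(p$tx, p$rx, p$grid, c0, f_number = 1.5, engine = "cpp")
  ir <- migrate_shot(p$tx, p$rx, p$grid, c0, f_number = 1.5, engine = "r")
  expect_equal(ic$values, ir$values, tolerance = 1e-12)
})

test_that("frequency-domain imaging equals explicit time-domain correlation", {
  # real band-limited signals on a shared time axis; Eq. of the imaging
  # condition: sum_t tx(t) rx(t) = 2 Re sum_{f>0} Conj(TX) RX (Parseval)
  n_theta <- 64; n_t <- 128; fs <- 14e6
  f_all <- (seq_len(n_t) - 1) * fs / n_t
  bi <- which(f_all > 1e6 & f_all < 6.5e6)
  set.seed(80)
  TX <- matrix(complex(real = rnorm(n_theta * length(bi)),
                       imaginary = rnorm(n_theta * length(bi))),
               n_theta, length(bi))
  RX <- matrix(complex(real = rnorm(n_theta * length(bi)),
                       imaginary = rnorm(n_theta * length(bi))),
               n_theta, length(bi))
  th <- small_theta(n_theta)
  grid <- polar_grid(th, 0.05)
  img <- migrate_shot(polar_field(TX, 0.05, f_all[bi], th),
                      polar_field(RX, 0.05, f_all[bi], th),
                      grid, c0, window = rep(1, n_theta))
  # explicit route: inverse transform to time, sample-wise product, time sum
  tx_t <- polarasm:::band_spectra_to_traces(t(TX), bi, n_t, fs)
  rx_t <- polarasm:::band_spectra_to_traces(t(RX), bi, n_t, fs)
  td <- colSums(tx_t * rx_t)
  fd <- 2 * Re(img$values[, 1]) / n_t
  expect_equal(fd, td, tolerance = 1e-8)
})

test_that("band weights cover the pulse support and taper degenerates to flat", {
  f <- seq(0.2e6, 7e6, length.out = 200)
  pulse <- gaussian_pulse_spectrum(3.5e6, 0.5, f)
  w <- band_weights(f, pulse, "flat")
  expect_true(all(w %in% c(0, 1)))
  expect_true(all(w[Mod(pulse$spectrum) >= 1e-2] == 1))
  expect_equal(band_weights(f, pulse, "taper", 0), w)
  wt <- band_weights(f, pulse, "taper", 0.4)
  expect_true(all(wt >= 0 & wt <= 1))
  expect_true(all(wt <= w + 1e-12))
  fbad <- seq(20e6, 30e6, length.out = 10)
  expect_error(band_weights(fbad, pulse), "support")
})

test_that("f-number weights map the acceptance angle to a k cutoff", {
  k <- seq(-600, 600, length.out = 401)
  expect_equal(fnumber_weights(k, 0.06, 3.5e6, c0, 0), rep(1, 401))
  # vanishing acceptance angle keeps only the k = 0 bin
  w_inf <- fnumber_weights(k, 0.06, 3.5e6, c0, 1e9)
  expect_equal(sum(w_inf > 1e-6), 1L)
  expect_equal(w_inf[k == 0], 1)
  kc <- (3.5e6 * 0.06 / c0) * sin(atan(0.25))
  w2 <- fnumber_weights(k, 0.06, 3.5e6, c0, 2)
  expect_true(all(w2[abs(k) > kc] == 0))
  expect_true(all(w2[abs(k) <= 0.9 * kc] == 1))
  expect_error(fnumber_weights(k, 0.06, 3.5e6, c0, -1))
})

test_that("compounding is a coherent complex sum", {
  p <- mk_pair(seed = 90)
  img <- migrate_shot(p$tx, p$rx, p$grid, c0)
  expect_equal(compound(list(img))$values, img$values)
  neg <- img; neg$values <- -img$values
  expect_true(all(compound(list(img, neg))$values == 0))
  two <- compound(list(img, img))
  expect_equal(two$values, 2 * img$values)
  expect_equal(20 * log10(max(Mod(two$values)) / max(Mod(img$values))),
               6.02, tolerance = 1e-3)
  other <- mk_pair(32)
  g2 <- polar_grid(small_theta(32), seq(0.05, 0.054, length.out = 5))
  img2 <- migrate_shot(rand_field(32, p$tx$freq_axis, seed = 91),
                       rand_field(32, p$tx$freq_axis, seed = 92), g2, c0)
  expect_error(compound(list(img, img2)), "grid")
})

test_that("snapshot mode stores the marching shell fields", {
  p <- mk_pair(seed = 95)
  img <- migrate_shot(p$tx, p$rx, p$grid, c0, window = rep(1, 64),
                      snapshots = c(1L, 3L))
  snaps <- attr(img, "snapshots")
  expect_named(snaps, c("1", "3"))
  expect_equal(snaps[["1"]]$tx, p$tx$values)
  stepped <- asm_step(asm_step(p$tx,
                               propagator_spec(p$grid$r[1], p$grid$r[2], c0, "-")),
                      propagator_spec(p$grid$r[2], p$grid$r[3], c0, "-"))
  expect_equal(snaps[["3"]]$tx, stepped$values, tolerance = 1e-12)
})

test_that("narrowing the band stretches the axial extent of a point image", {
  acq <- tiny_point_acquisition(scat_theta = 0, scat_depth = 25e-3)
  img_wide <- migrate(acq$channel, acq$grid, band = c(1.8e6, 5.6e6))
  img_narrow <- migrate(acq$channel, acq$grid, band = c(3.0e6, 4.0e6))
  ax_extent <- function(img) {
    env <- Mod(img$values)
    pk <- arrayInd(which.max(env), dim(env))
    prof <- env[pk[1], ]
    sum(prof >= max(prof) / 2) * img$grid$dr
  }
  expect_gt(ax_extent(img_narrow), ax_extent(img_wide))
})

test_that("a focused-transmit point at the focus images at the focus", {
  acq <- tiny_point_acquisition(scat_theta = 0.05, scat_depth = 25e-3,
                                focus_theta = 0.05, focus_depth = 25e-3)
  img <- migrate(acq$channel, acq$grid, f_number = 1.5)
  env <- Mod(img$values)
  pk <- arrayInd(which.max(env), dim(env))
  expect_lt(abs(img$grid$theta[pk[1]] - acq$truth$theta), 1.5 * img$grid$dtheta)
  expect_lt(abs(img$grid$r[pk[2]] - acq$truth$r), 1.5 * img$grid$dr)
})
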