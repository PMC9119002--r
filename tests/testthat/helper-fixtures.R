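# shared fixtures and independent brute-force oracles

small_theta <- function(n = 64, half = 0.4) seq(-half, half, length.out = n)

rand_field <- function(n_theta, freqs, radius = 0.05, seed = 1,
                       theta = small_theta(n_theta)) {
  set.seed(seed)
  v <- matrix(complex(real = rnorm(n_theta * length(freqs)),
                      imaginary = rnorm(n_theta * length(freqs))),
              n_theta, length(freqs))
  polar_field(v, radius, freqs, theta)
}

# restrict a field to modes propagating at its own radius (margin > 1)
propagating_only <- function(field, c0 = 1540, margin = 1.05) {
  n <- length(field$theta_axis)
  dth <- diff(field$theta_axis)[1]
  k <- fft_freqs(n, dth)
  V <- stats::mvfft(field$values)
  mask <- outer(abs(k), field$freq_axis, function(ak, f)
    ak == 0 | f * field$radius / (c0 * pmax(ak, 1e-300)) > margin)
  V[!mask] <- 0
  polar_field(Conj(stats::mvfft(Conj(V))) / n, field$radius,
              field$freq_axis, field$theta_axis)
}

# O(N^2) direct-sum evaluation of one extrapolation step: explicit discrete
# forward transform, propagator multiply, explicit inverse, window
direct_sum_step <- function(field, spec, window) {
  th <- field$theta_axis
  n <- length(th)
  dth <- diff(th)[1]
  k <- fft_freqs(n, dth)
  dk <- 1 / (n * dth)
  out <- matrix(0 + 0i, n, length(field$freq_axis))
  for (j in seq_along(field$freq_axis)) {
    H <- propagator(k, spec, field$freq_axis[j])
    Fk <- vapply(k, function(kk)
      sum(field$values[, j] * exp(-2i * pi * kk * th)) * dth, 0 + 0i)
    out[, j] <- vapply(th, function(tt)
      sum(H * Fk * exp(2i * pi * k * tt)) * dk, 0 + 0i)
  }
  out * window
}

# tiny single-scatterer acquisition on the 128-element probe; used by the
# localization tests for both beamformers
tiny_point_acquisition <- function(scat_theta = 0.05, scat_depth = 25e-3,
                                   subaperture = 20L, focus_depth = 25e-3,
                                   focus_theta = 0) {
  probe <- probe_preset("c128")
  r0 <- probe$radius_r0
  th_el <- element_angles(probe)
  ctr <- which.min(abs(th_el - focus_theta))
  act <- seq.int(max(1, ctr - subaperture %/% 2 + 1),
                 min(probe$n_elements, ctr + subaperture %/% 2))
  ev <- transmit_event(probe, focus_theta, r0 + focus_depth, 1540, act)
  pulse <- gaussian_pulse_spectrum(3.5e6, 0.5, seq(0, 7e6, length.out = 64))
  ph <- make_phantom(list(r0 = r0, theta = c(-0.3, 0.3), depth = c(5e-3, 35e-3)),
                     points = data.frame(theta = scat_theta, depth = scat_depth,
                                         amplitude = 1))
  ch <- simulate_channel_data(probe, list(ev), pulse, ph, c = 1540,
                              sampling_rate = 14e6, n_sub = 2L)
  grid <- default_grid(probe, max_depth = 35e-3, n_theta = 192L, dr = 0.44e-3,
                       margin = -0.25)
  list(probe = probe, event = ev, pulse = pulse, phantom = ph,
       channel = ch, grid = grid,
       truth = list(theta = scat_theta, r = r0 + scat_depth))
}
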