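#' Beamformed image on a polar grid
#'
#' Complex image values indexed (theta, r). `metadata` records the
#' reconstruction parameters (band, f-number, window taper, sound speed,
#' per-shot flag, ...) for provenance.
#'
#' @param values complex matrix, `n_theta x n_r`.
#' @param grid a [polar_grid].
#' @param metadata named list of reconstruction parameters.
#' @param per_shot logical: is this a single-transmit image?
#' @return an object of class `polar_image`.
#' @export
polar_image <- function(values, grid, metadata = list(), per_shot = FALSE) {
  values <- as.matrix(values)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  stopifnot(inherits(grid, "polar_grid"),
            nrow(values) == grid$n_theta, ncol(values) == grid$n_r,
            all(is.finite(Re(values))), all(is.finite(Im(values))))
  structure(list(values = values, grid = grid, metadata = metadata,
                 per_shot = per_shot),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("Polar image: %d theta x %d r%s\n", x$grid$n_theta, x$grid$n_r,
              if (x$per_shot) " (single transmit)" else ""))
  env <- Mod(x$values)
  cat(sprintf("  envelope peak %.3g, depth span [%.1f, %.1f] mm\n",
              max(env), 1e3 * (min(x$grid$r) - x$grid$r0),
              1e3 * (max(x$grid$r) - x$grid$r0)))
  invisible(x)
}

#' Envelope of a beamformed image
#'
#' @param image a [polar_image].
#' @return numeric matrix `|I(theta, r)|`.
#' @export
envelope <- function(image) {
  stopifnot(inherits(image, "polar_image"))
  Mod(image$values)
}

#' Log-compressed envelope for display
#'
#' @param image a [polar_image].
#' @param dynamic_range display range in dB below the envelope peak.
#' @return matrix of dB values in `[-dynamic_range, 0]`.
#' @export
log_compress <- function(image, dynamic_range = 60) {
  env <- envelope(image)
  db <- 20 * log10(env / max(env))
  pmax(db, -dynamic_range)
}

#' Plot a polar image
#'
#' Scan-converts the log-compressed envelope and displays it with the depth
#' axis downward.
#'
#' @param x a [polar_image].
#' @param dynamic_range dB.
#' @param pixel_size metres; default twice the lateral sample at mid-depth.
#' @param ... passed to [graphics::image].
#' @export
plot.polar_image <- function(x, dynamic_range = 60, pixel_size = NULL, ...) {
  g <- x$grid
  if (is.null(pixel_size)) pixel_size <- g$dtheta * mean(g$r)
  xr <- max(g$r) * sin(max(abs(range(g$theta))))
  sc <- scan_convert(x, x_range = c(-xr, xr),
                     z_range = range(g$r * cos(max(abs(g$theta))), g$r),
                     pixel_size = pixel_size, what = "db",
                     dynamic_range = dynamic_range)
  graphics::image(sc$x * 1e3, sc$z * 1e3, sc$values,
                  col = grDevices::gray.colors(256, 0, 1), ylim = rev(range(sc$z * 1e3)),
                  xlab = "x [mm]", ylab = "z [mm]", useRaster = TRUE, ...)
  invisible(x)
}

#' Frequency band weights for image formation
#'
#' `mode = "flat"`: weight 1 on the pulse's support (down to -40 dB of the
#' spectral peak), 0 outside. `mode = "taper"`: cosine roll-off over
#' `taper_fraction` of that band (a Tukey profile over the support);
#' `taper_fraction = 0` reduces to flat. Narrowing or tapering the band
#' trades axial resolution for cost and ringing suppression.
#'
#' @param freq_axis frequency bins, Hz.
#' @param pulse a [gaussian_pulse_spectrum].
#' @param mode `"flat"` or `"taper"`.
#' @param taper_fraction in `[0, 1]`.
#' @return numeric weights in `[0, 1]` over `freq_axis`.
#' @export
band_weights <- function(freq_axis, pulse, mode = c("flat", "taper"),
                         taper_fraction = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(pulse, "pulse"))
  mag <- Mod(gaussian_pulse_spectrum(pulse$center_frequency,
                                     pulse$fractional_bandwidth,
                                     freq_axis)$spectrum)
  sup <- mag >= 10^(-40 / 20)
  if (!any(sup)) stop("pulse has no support on this frequency axis")
  w <- as.numeric(sup)
  if (mode == "taper" && taper_fraction > 0) {
    idx <- range(which(sup))
    n <- idx[2] - idx[1] + 1L
    if (n >= 4) w[idx[1]:idx[2]] <- make_window(n, taper_fraction)
  }
  w
}

#' k-space f-number apodization
#'
#' Depth-dependent receive-aperture control applied in the angular-spectrum
#' domain: components with `|k_theta| <= (f*r/c) * sin(atan(1/(2*f_number)))`
#' pass, with a cosine taper over the outer 10% of the passband. The
#' acceptance-angle mapping treats `1/(2*f_number)` as the tangent of the
#' half-aperture angle, the usual aperture-growth rule. `f_number = 0` is an
#' all-pass sentinel.
#'
#' @param k_theta angular spatial frequencies, cycles/radian.
#' @param r shell radius, metres.
#' @param f frequency, Hz (scalar or vector).
#' @param c sound speed, m/s.
#' @param f_number receive f-number (> 0), or 0 to disable.
#' @return weights in `[0, 1]`: vector for scalar `f`, else a
#'   `length(k_theta) x length(f)` matrix.
#' @export
fnumber_weights <- function(k_theta, r, f, c = 1540, f_number = 0) {
  if (f_number < 0) stop("f_number must be non-negative")
  if (f_number == 0) {
    w <- matrix(1, length(k_theta), length(f))
    return(if (length(f) == 1L) drop(w) else w)
  }
  kc <- (f * r / c) * sin(atan(1 / (2 * f_number)))   # per frequency
  q <- outer(abs(k_theta), ifelse(kc > 0, kc, Inf), "/")
  w <- matrix(0, length(k_theta), length(f))
  w[q <= 0.9] <- 1
  tp <- q > 0.9 & q <= 1
  w[tp] <- 0.5 * (1 + cos(pi * (q[tp] - 0.9) / 0.1))
  w[k_theta == 0, ] <- 1
  if (length(f) == 1L) drop(w) else w
}

#' Shot-profile migration of one transmit event
#'
#' Marches the transmit field outward with the `-` branch propagator and the
#' receive field outward with the `+` branch, and at every shell accumulates
#' the frequency-domain imaging condition
#' `I_i(theta, r) = sum_f w_band(f) * Conj(p_tx(theta, r, f)) * p_rx(theta, r, f)`.
#' Optional k-space f-number weights are applied to the receive angular
#' spectrum before its inverse transform at each shell. Only the current
#' shell of each field is kept in memory unless `snapshots` is requested.
#'
#' @param tx0 transmit [polar_field] at `grid$r[1]` (see
#'   [init_transmit_field]).
#' @param rx0 receive [polar_field] on the same theta/frequency axes.
#' @param grid a [polar_grid] starting at the array radius.
#' @param sound_speed scalar, per-interval vector, or function of radius.
#' @param window angular window (default Tukey, taper 0.25).
#' @param band weights over the frequency axis (default flat over all bins).
#' @param f_number k-space receive f-number; 0 disables.
#' @param engine `"cpp"` (compiled core) or `"r"` (reference implementation
#'   built from [asm_step]).
#' @param snapshots optional integer shell indices: store the transmit and
#'   receive shell fields there (debug/demonstration mode; memory grows with
#'   the number of snapshots).
#' @return a per-shot [polar_image]; with `snapshots`, the image carries a
#'   `snapshots` attribute holding the stored shells.
#' @export
migrate_shot <- function(tx0, rx0, grid, sound_speed = 1540, window = NULL,
                         band = NULL, f_number = 0,
                         engine = c("cpp", "r"), snapshots = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(tx0, "polar_field"), inherits(rx0, "polar_field"),
            inherits(grid, "polar_grid"))
  if (length(tx0$freq_axis) != length(rx0$freq_axis) ||
      max(abs(tx0$freq_axis - rx0$freq_axis)) > 1e-6)
    stop("transmit and receive fields must share one frequency axis")
  if (max(abs(tx0$theta_axis - rx0$theta_axis)) > 1e-12)
    stop("transmit and receive fields must share one theta axis")
  if (max(abs(grid$theta - tx0$theta_axis)) > 1e-12)
    stop("grid theta axis must match the fields")
  if (abs(grid$r[1] - tx0$radius) > 1e-9 * tx0$radius)
    stop("grid must start at the fields' radius")
  n <- grid$n_theta
  if (is.null(window)) window <- make_window(n, 0.25)
  if (is.null(band)) band <- rep(1, length(tx0$freq_axis))
  if (length(band) != length(tx0$freq_axis)) stop("band weight length mismatch")
  if (!any(band > 0)) stop("empty frequency band")
  cs <- .interval_speeds(grid$r, sound_speed)
  k <- fft_freqs(n, grid$dtheta)
  meta <- list(f_number = f_number, sound_speed = cs,
               band = band, window_taper = window, per_shot = TRUE)
  if (engine == "cpp" && is.null(snapshots)) {
    img <- migrate_shot_cpp(tx0$values, rx0$values, k, tx0$freq_axis,
                            grid$r, cs, window, band, f_number)
    return(polar_image(img, grid, meta, per_shot = TRUE))
  }
  # reference implementation (and snapshot mode)
  img <- matrix(0 + 0i, n, grid$n_r)
  tx <- tx0; rx <- rx0
  snaps <- list()
  for (i in seq_len(grid$n_r)) {
    rx_img <- rx$values
    if (f_number > 0) {
      fw <- fnumber_weights(k, grid$r[i], tx0$freq_axis, cs[min(i, length(cs))],
                            f_number)
      if (!is.matrix(fw)) fw <- matrix(fw, ncol = 1L)
      rx_img <- Conj(mvfft(Conj(mvfft(rx$values) * fw))) / n
    }
    img[, i] <- (Conj(tx$values) * rx_img) %*% band
    if (!is.null(snapshots) && i %in% snapshots)
      snaps[[as.character(i)]] <- list(r = grid$r[i], tx = tx$values,
                                       rx = rx$values)
    if (i < grid$n_r) {
      tx <- asm_step(tx, propagator_spec(grid$r[i], grid$r[i + 1], cs[i], "-"),
                     window)
      rx <- asm_step(rx, propagator_spec(grid$r[i], grid$r[i + 1], cs[i], "+"),
                     window)
    }
  }
  out <- polar_image(img, grid, meta, per_shot = TRUE)
  if (!is.null(snapshots)) attr(out, "snapshots") <- snaps
  out
}

#' Coherently compound per-shot images
#'
#' Complex sum `I = sum_i I_i` over transmit events; the envelope is taken
#' only after summation.
#'
#' @param images list of [polar_image]s on identical grids.
#' @return a compounded [polar_image].
#' @export
compound <- function(images) {
  stopifnot(length(images) >= 1, all(vapply(images, inherits, TRUE, "polar_image")))
  g <- images[[1]]$grid
  for (im in images[-1])
    if (im$grid$n_theta != g$n_theta || im$grid$n_r != g$n_r ||
        max(abs(im$grid$theta - g$theta)) > 1e-12 ||
        max(abs(im$grid$r - g$r)) > 1e-12)
      stop("all images must share one grid")
  vals <- Reduce(`+`, lapply(images, `[[`, "values"))
  meta <- images[[1]]$metadata
  meta$per_shot <- FALSE
  meta$n_compounded <- length(images)
  polar_image(vals, g, meta, per_shot = FALSE)
}

#' Shot-profile migration of a full acquisition
#'
#' Convenience wrapper: for every transmit event in `channel`, initializes
#' the transmit (Eq.-of-motion delays + pulse spectrum) and receive (band
#' spectra of the traces) shell fields, migrates the shot, and coherently
#' compounds.
#'
#' @param channel a [channel_data].
#' @param grid a [polar_grid] starting at the probe radius.
#' @param band `c(f_lo, f_hi)` Hz; default the pulse's -40 dB support
#'   clipped to the sampled spectrum.
#' @param band_mode,band_taper passed to [band_weights].
#' @param f_number k-space receive f-number.
#' @param window_taper Tukey taper fraction for the angular window.
#' @param sound_speed scalar, per-interval vector, or function of radius.
#' @param events subset of transmit events to use (default all).
#' @return a compounded [polar_image].
#' @export
migrate <- function(channel, grid, band = NULL,
                    band_mode = "flat", band_taper = 0.2,
                    f_number = 0, window_taper = 0.25,
                    sound_speed = channel$sound_speed,
                    events = seq_along(channel$events)) {
  stopifnot(inherits(channel, "channel_data"))
  fs <- channel$sampling_rate
  p <- channel$pulse
  if (is.null(band)) {
    hw <- sqrt(40 / 20 * log(10) * 2) * p$sigma_f   # -40 dB half width
    band <- c(max(p$center_frequency - hw, fs / dim(channel$traces)[3]),
              min(p$center_frequency + hw, fs / 2 * 0.999))
  }
  window <- make_window(grid$n_theta, window_taper)
  shots <- vector("list", length(events))
  for (j in seq_along(events)) {
    i <- events[j]
    rx0 <- init_receive_field(channel, i, channel$probe, grid$theta, band)
    pulse_b <- gaussian_pulse_spectrum(p$center_frequency,
                                       p$fractional_bandwidth, rx0$freq_axis)
    tx0 <- init_transmit_field(channel$probe, channel$events[[i]], pulse_b,
                               grid$theta)
    bw <- band_weights(rx0$freq_axis, p, band_mode, band_taper)
    shots[[j]] <- migrate_shot(tx0, rx0, grid, sound_speed, window, bw,
                               f_number)
  }
  out <- compound(shots)
  out$metadata$band_hz <- band
  out$metadata$beamformer <- "shot-profile migration (polar ASM)"
  out
}
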