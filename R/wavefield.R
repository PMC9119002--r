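#' Geometric focal delays for a curvilinear aperture
#'
#' Per-element firing delays that focus the active subaperture at
#' `(focus_theta, focus_r)`: `tau_e = (max_e d_e - d_e) / c` with `d_e` the
#' Euclidean element-to-focus distance, so the wavefronts coincide at the
#' focus at time `max_e d_e / c` after the earliest element fires. Inactive
#' elements get delay 0 (they are silenced by the apodization).
#'
#' @param probe a [curvilinear_probe].
#' @param focus_theta beam axis angle, radians.
#' @param focus_r focal radius (from the centre of curvature), metres; must
#'   exceed the probe radius.
#' @param c sound speed, m/s.
#' @param active_elements integer indices of the active subaperture.
#' @return numeric vector of delays (seconds), length `n_elements`.
#' @export
focal_delays <- function(probe, focus_theta, focus_r, c = 1540,
                         active_elements = seq_len(probe$n_elements)) {
  stopifnot(inherits(probe, "curvilinear_probe"))
  if (focus_r <= probe$radius_r0) stop("focus lies behind the array")
  pos <- element_positions(probe)
  fx <- focus_r * sin(focus_theta); fz <- focus_r * cos(focus_theta)
  d <- sqrt((pos$x - fx)^2 + (pos$z - fz)^2)
  tau <- numeric(probe$n_elements)
  tau[active_elements] <- (max(d[active_elements]) - d[active_elements]) / c
  tau
}

#' A focused transmit event
#'
#' Bundles the per-element delays and apodization of one focused
#' transmission, plus the focal geometry needed by the virtual-source
#' baseline (`t_focus`: time at which the delayed wavefronts coincide at the
#' focus, measured from the firing of the earliest element).
#'
#' @inheritParams focal_delays
#' @param apodization weights in `[0, 1]` over the active elements (recycled);
#'   default uniform.
#' @return an object of class `transmit_event` with fields `delays`,
#'   `apodization` (both length `n_elements`), `focus_theta`, `focus_r`,
#'   `t_focus`, `active_elements`.
#' @export
transmit_event <- function(probe, focus_theta, focus_r, c = 1540,
                           active_elements = seq_len(probe$n_elements),
                           apodization = 1) {
  delays <- focal_delays(probe, focus_theta, focus_r, c, active_elements)
  apod <- numeric(probe$n_elements)
  apod[active_elements] <- rep_len(apodization, length(active_elements))
  if (any(apod < 0 | apod > 1)) stop("apodization weights must lie in [0, 1]")
  pos <- element_positions(probe)
  fx <- focus_r * sin(focus_theta); fz <- focus_r * cos(focus_theta)
  d <- sqrt((pos$x - fx)^2 + (pos$z - fz)^2)
  structure(list(delays = delays, apodization = apod,
                 focus_theta = focus_theta, focus_r = focus_r,
                 t_focus = max(d[active_elements]) / c,
                 active_elements = as.integer(active_elements)),
            class = "transmit_event")
}

#' Walking-aperture focused-transmit sequence
#'
#' Beam axes uniformly spaced over `span` (radians, symmetric about 0), one
#' focused transmit per beam, each using a subaperture of `subaperture`
#' elements centred on the nearest element to the beam axis and clipped to
#' the array edges.
#'
#' @param probe a [curvilinear_probe].
#' @param n_beams number of transmit events.
#' @param span total angular span of beam axes, radians (beams at
#'   `seq(-span/2, span/2, length.out = n_beams)`).
#' @param focal_depth focal depth beyond the array surface, metres (focal
#'   radius is `radius_r0 + focal_depth`).
#' @param subaperture nominal subaperture element count.
#' @param c sound speed, m/s.
#' @return list of [transmit_event]s.
#' @export
walking_sequence <- function(probe, n_beams, span, focal_depth,
                             subaperture, c = 1540) {
  stopifnot(n_beams >= 1, span >= 0, focal_depth > 0,
            subaperture >= 1, subaperture <= probe$n_elements)
  axes <- if (n_beams == 1L) 0 else seq(-span / 2, span / 2,
                                        length.out = n_beams)
  th_el <- element_angles(probe)
  lapply(axes, function(a) {
    ctr <- which.min(abs(th_el - a))
    half <- (subaperture - 1) / 2
    lo <- max(1L, ctr - floor(half)); hi <- min(probe$n_elements, ctr + ceiling(half))
    transmit_event(probe, a, probe$radius_r0 + focal_depth, c,
                   active_elements = seq.int(lo, hi))
  })
}

# map each theta sample to the element whose arc footprint covers it;
# returns NA outside all footprints. Errors if the grid undersamples the
# element pitch.
.element_of_theta <- function(probe, theta_axis) {
  ang_pitch <- probe$pitch / probe$radius_r0
  n <- length(theta_axis)
  dth <- if (n > 1) (theta_axis[n] - theta_axis[1]) / (n - 1) else ang_pitch
  if (dth > ang_pitch * (1 + 1e-9))
    stop("theta grid is coarser than the element spacing")
  idx <- round(theta_axis / ang_pitch + (probe$n_elements - 1) / 2) + 1
  off <- theta_axis - (idx - 1 - (probe$n_elements - 1) / 2) * ang_pitch
  idx[abs(off) > ang_pitch / 2 * (1 + 1e-9)] <- NA_integer_
  idx[idx < 1 | idx > probe$n_elements] <- NA_integer_
  as.integer(idx)
}

#' Initial transmit wavefield on the array shell
#'
#' Builds `p_tx(theta, r0, f) = A(theta) * P(f) * exp(-2i*pi*f*tau(theta))`:
#' every theta sample inside an element's arc footprint takes that element's
#' apodization and delay, samples outside the active aperture are zero. The
#' theta grid must sample at or above the element angular density.
#'
#' @param probe a [curvilinear_probe].
#' @param event a [transmit_event].
#' @param pulse a [gaussian_pulse_spectrum] (its `freq_axis` becomes the
#'   field's frequency axis).
#' @param theta_axis uniform angular grid covering the active aperture,
#'   radians.
#' @return a [polar_field] at the probe radius.
#' @export
init_transmit_field <- function(probe, event, pulse, theta_axis) {
  stopifnot(inherits(event, "transmit_event"), inherits(pulse, "pulse"))
  el <- .element_of_theta(probe, theta_axis)
  A <- ifelse(is.na(el), 0, event$apodization[ifelse(is.na(el), 1L, el)])
  tau <- ifelse(is.na(el), 0, event$delays[ifelse(is.na(el), 1L, el)])
  f <- pulse$freq_axis
  vals <- (A * exp(-2i * pi * outer(tau, f))) *
    matrix(pulse$spectrum, length(theta_axis), length(f), byrow = TRUE)
  vals[A == 0, ] <- 0 + 0i
  polar_field(vals, probe$radius_r0, f, theta_axis)
}

#' Receive channel data
#'
#' Time-domain receive traces for a set of transmit events: a real array
#' indexed (transmit event, element, time sample) with its sampling rate and
#' the absolute time `t0` of the first sample (time zero is the firing of
#' the earliest element of each event).
#'
#' @param traces real array, `n_tx x n_rx x n_t`.
#' @param sampling_rate Hz.
#' @param t0 absolute time of the first sample, seconds.
#' @param probe the [curvilinear_probe] that recorded the data.
#' @param pulse the transmit [gaussian_pulse_spectrum].
#' @param events list of [transmit_event]s (one per transmit).
#' @param sound_speed medium sound speed used in simulation, m/s (metadata).
#' @return an object of class `channel_data`.
#' @export
channel_data <- function(traces, sampling_rate, t0, probe, pulse, events,
                         sound_speed = 1540) {
  stopifnot(length(dim(traces)) == 3L, all(is.finite(traces)),
            sampling_rate > 0, inherits(probe, "curvilinear_probe"),
            inherits(pulse, "pulse"), length(events) == dim(traces)[1],
            dim(traces)[2] == probe$n_elements)
  upper <- pulse$center_frequency * (1 + pulse$fractional_bandwidth)
  if (sampling_rate <= 2 * upper)
    warning("sampling rate below twice the pulse upper band edge")
  structure(list(traces = traces, sampling_rate = sampling_rate, t0 = t0,
                 probe = probe, pulse = pulse, events = events,
                 sound_speed = sound_speed),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf(
    "Channel data: %d transmits x %d elements x %d samples @ %.2f MHz (t0 = %.2f us)\n",
    d[1], d[2], d[3], 1e-6 * x$sampling_rate, 1e6 * x$t0))
  invisible(x)
}

#' Initial receive wavefield on the array shell
#'
#' One-sided band spectra of one event's receive traces (analysis convention
#' `exp(-2i*pi*f*t)`, phase-compensated for the recording start time `t0`),
#' placed at the element footprints on the theta grid and zero elsewhere.
#' Only bins inside `band` are retained.
#'
#' @param channel a [channel_data].
#' @param event_index which transmit event.
#' @param probe a [curvilinear_probe] (defaults to the recording probe).
#' @param theta_axis uniform angular grid, radians.
#' @param band `c(f_lo, f_hi)` in Hz; must lie inside `(0, fs/2)`.
#' @return a [polar_field] at the probe radius; its `freq_axis` holds the
#'   retained bin frequencies.
#' @export
init_receive_field <- function(channel, event_index, probe = channel$probe,
                               theta_axis, band) {
  stopifnot(inherits(channel, "channel_data"),
            event_index >= 1, event_index <= dim(channel$traces)[1])
  fs <- channel$sampling_rate
  n_t <- dim(channel$traces)[3]
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie strictly inside (0, sampling_rate/2)")
  f_all <- (seq_len(n_t) - 1) * fs / n_t
  band_idx <- which(f_all >= band[1] & f_all <= band[2])
  if (!length(band_idx)) stop("band contains no frequency bins")
  tr <- t(channel$traces[event_index, , ])          # n_t x n_rx
  spec <- traces_to_band_spectra(tr, fs, channel$t0, band_idx) # n_f x n_rx
  el <- .element_of_theta(probe, theta_axis)
  vals <- matrix(0 + 0i, length(theta_axis), length(band_idx))
  ok <- which(!is.na(el))
  vals[ok, ] <- t(spec[, el[ok], drop = FALSE])
  polar_field(vals, probe$radius_r0, f_all[band_idx], theta_axis)
}
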