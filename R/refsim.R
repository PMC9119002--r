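#' Synthetic scatterer phantom
#'
#' Builds a phantom for the reference simulator: bright point targets,
#' diffuse sub-resolution scatterers (uniform over a sector, i.i.d. standard
#' normal amplitudes, at a stated density per resolution cell), and
#' anechoic lesion discs whose interior diffuse scatterers are removed.
#' Deterministic under a fixed seed.
#'
#' @param field_of_view list with `r0` (array radius, metres), `theta`
#'   (`c(min, max)` radians) and `depth` (`c(min, max)` metres beyond the
#'   array surface) bounding the diffuse region.
#' @param points optional data frame with columns `theta`, `depth`,
#'   `amplitude`: bright point targets.
#' @param lesions optional data frame with columns `theta`, `depth`,
#'   `radius`: anechoic discs (metres).
#' @param diffuse_density diffuse scatterers per resolution cell (10 gives
#'   fully developed speckle).
#' @param resolution_cell `c(axial, lateral)` cell extents in metres;
#'   default the pulse length and one-wavelength-times-f/2 lateral extent of
#'   a 3.5 MHz, 50% bandwidth system.
#' @param seed integer seed for the diffuse draw (the caller's RNG state is
#'   left untouched).
#' @return an object of class `phantom` with Cartesian scatterer positions
#'   `x`, `z`, amplitudes `amplitude`, and the construction `spec`.
#' @export
make_phantom <- function(field_of_view, points = NULL, lesions = NULL,
                         diffuse_density = 0,
                         resolution_cell = c(0.44e-3, 0.88e-3),
                         seed = 1L) {
  stopifnot(is.list(field_of_view),
            all(c("r0", "theta", "depth") %in% names(field_of_view)))
  r0 <- field_of_view$r0
  th <- field_of_view$theta; dp <- field_of_view$depth
  stopifnot(r0 > 0, diff(th) > 0, all(dp >= 0), diff(dp) > 0)
  if (diffuse_density < 0) stop("diffuse_density must be non-negative")
  if (!is.null(lesions) && diffuse_density == 0 && nrow(lesions) > 0)
    stop("anechoic lesions require a positive diffuse density")
  x <- z <- amp <- numeric(0)
  r1 <- r0 + dp[1]; r2 <- r0 + dp[2]
  if (diffuse_density > 0) {
    area <- diff(th) * (r2^2 - r1^2) / 2
    cell <- prod(resolution_cell)
    n <- max(1L, round(diffuse_density * area / cell))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    thd <- runif(n, th[1], th[2])
    rd <- sqrt(runif(n) * (r2^2 - r1^2) + r1^2)   # uniform over sector area
    ad <- rnorm(n)
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    x <- rd * sin(thd); z <- rd * cos(thd); amp <- ad
    if (!is.null(lesions) && nrow(lesions) > 0) {
      keep <- rep(TRUE, n)
      for (j in seq_len(nrow(lesions))) {
        lr <- r0 + lesions$depth[j]
        lx <- lr * sin(lesions$theta[j]); lz <- lr * cos(lesions$theta[j])
        keep <- keep & ((x - lx)^2 + (z - lz)^2 > lesions$radius[j]^2)
      }
      x <- x[keep]; z <- z[keep]; amp <- amp[keep]
    }
  }
  if (!is.null(points) && nrow(points) > 0) {
    pr <- r0 + points$depth
    x <- c(x, pr * sin(points$theta))
    z <- c(z, pr * cos(points$theta))
    amp <- c(amp, points$amplitude)
  }
  structure(list(x = x, z = z, amplitude = amp,
                 spec = list(field_of_view = field_of_view, points = points,
                             lesions = lesions,
                             diffuse_density = diffuse_density,
                             resolution_cell = resolution_cell, seed = seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom: %d scatterers", length(x$x)))
  if (!is.null(x$spec$points)) cat(sprintf(" (%d point targets)", nrow(x$spec$points)))
  if (!is.null(x$spec$lesions)) cat(sprintf(", %d anechoic lesions", nrow(x$spec$lesions)))
  cat("\n")
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  graphics::plot(x$x * 1e3, x$z * 1e3, pch = ".", ylim = rev(range(x$z * 1e3)),
                 xlab = "x [mm]", ylab = "z [mm]", ...)
  invisible(x)
}

# element sub-source positions: n_sub point sources across each element's
# arc footprint (width = pitch) at radius r0; returns n_el x n_sub matrices
.element_subsources <- function(probe, n_sub) {
  th <- element_angles(probe)
  wa <- probe$pitch / probe$radius_r0
  off <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5) * wa
  ths <- outer(th, off, "+")
  list(x = probe$radius_r0 * sin(ths), z = probe$radius_r0 * cos(ths))
}

#' Time-domain transmit field of a focused event
#'
#' Direct-summation reference: each element is subdivided into `n_sub`
#' point sources across its arc footprint and the delayed, apodized pulse is
#' summed at every field point,
#' `p(x, t) = sum_e A_e s(t - tau_e - d_e/c) / d_e^q`.
#' `spreading = "spherical"` uses `q = 1` (3-D point sources);
#' `spreading = "cylindrical"` uses `q = 1/2` with the far-field 2-D
#' line-source waveform (half time-derivative, -45 degree phase), the
#' consistent reference for the 2-D angular-spectrum solver.
#'
#' @param probe a [curvilinear_probe].
#' @param event a [transmit_event].
#' @param pulse a [gaussian_pulse_spectrum].
#' @param field_points list with `x`, `z` coordinate vectors, metres.
#' @param c sound speed, m/s.
#' @param time_axis sample times, seconds (must cover the arrivals).
#' @param spreading `"spherical"` or `"cylindrical"`.
#' @param derivative if `TRUE`, the radiated pressure is the time derivative
#'   of the source waveform: the piston-source (velocity-prescribed) model,
#'   which is also what a pressure distribution prescribed on the source
#'   surface radiates. `FALSE` gives plain monopole point sources.
#' @param obliquity `"none"` (omnidirectional sub-sources) or `"cosine"`
#'   (each sub-source weighted by the cosine of the angle between the ray to
#'   the field point and the element normal, the baffled-source directivity
#'   that a surface-prescribed field radiates).
#' @param n_sub sub-sources per element (>= 1; 4 is ample at half-wavelength
#'   pitch).
#' @return matrix of pressures, `length(field_points$x)` x
#'   `length(time_axis)`.
#' @export
simulate_transmit_field <- function(probe, event, pulse, field_points, c = 1540,
                                    time_axis,
                                    spreading = c("spherical", "cylindrical"),
                                    derivative = FALSE,
                                    obliquity = c("none", "cosine"),
                                    n_sub = 4L) {
  spreading <- match.arg(spreading)
  obliquity <- match.arg(obliquity)
  stopifnot(inherits(event, "transmit_event"), inherits(pulse, "pulse"),
            n_sub >= 1)
  tab <- pulse_table(pulse$center_frequency, pulse$fractional_bandwidth,
                     kind = if (spreading == "spherical") "point" else "line",
                     derivative = derivative)
  q <- if (spreading == "spherical") 1 else 0.5
  np <- length(field_points$x); nt <- length(time_axis)
  sub <- .element_subsources(probe, n_sub)
  out <- matrix(0, np, nt)
  act <- event$active_elements
  for (e in act) {
    if (event$apodization[e] == 0) next
    for (s in seq_len(n_sub)) {
      ddx <- field_points$x - sub$x[e, s]
      ddz <- field_points$z - sub$z[e, s]
      d <- sqrt(ddx^2 + ddz^2)
      if (any(d < 1e-9)) stop("field point coincides with a source point")
      obl <- if (obliquity == "cosine") {
        nrm <- sqrt(sub$x[e, s]^2 + sub$z[e, s]^2)
        pmax((ddx * sub$x[e, s] + ddz * sub$z[e, s]) / (d * nrm), 0)
      } else 1
      # arrival-time matrix lookup into the waveform table
      targ <- outer(-(event$delays[e] + d / c), time_axis, "+")
      idx <- (targ - tab$t[1]) / tab$dt
      i0 <- floor(idx)
      frac <- idx - i0
      inb <- i0 >= 0 & i0 < length(tab$t) - 1
      vals <- numeric(length(idx))
      ii <- i0[inb] + 1L
      vals[inb] <- tab$s[ii] * (1 - frac[inb]) + tab$s[ii + 1L] * frac[inb]
      out <- out + (event$apodization[e] / n_sub) *
        matrix(vals, np, nt) * (obl / d^q)
    }
  }
  out
}

#' Simulate receive channel data (Born single scattering)
#'
#' Two-way time-domain reference: for each transmit event and receive
#' element, sums over scatterers
#' `amplitude * s(t - t_tx - t_rx) / (d_tx * d_rx)`, where the transmit leg
#' includes every active element's delayed, apodized, sub-divided
#' contribution and both legs use spherical spreading. Optionally adds white
#' Gaussian noise at a stated level below the peak trace amplitude.
#'
#' @param probe a [curvilinear_probe].
#' @param events list of [transmit_event]s.
#' @param pulse a [gaussian_pulse_spectrum].
#' @param phantom a [make_phantom] object.
#' @param c sound speed, m/s.
#' @param sampling_rate Hz (> 4x the centre frequency recommended).
#' @param duration record length, seconds; default covers the deepest
#'   scatterer's round trip plus the pulse.
#' @param noise_db if non-NULL, additive white Gaussian noise at this many
#'   dB below the peak trace amplitude.
#' @param n_sub sub-sources per element, used on both legs (equal counts
#'   keep transmit/receive reciprocity exact).
#' @param method `"fast"` factorizes the double element sum through a
#'   per-scatterer transmit waveform on a fine local time grid (one linear
#'   interpolation per leg); `"exact"` evaluates every
#'   transmit/receive sub-source pair directly, which is exactly symmetric
#'   under element exchange but scales with the pair count.
#' @param noise_seed seed for the noise draw.
#' @return a [channel_data].
#' @export
simulate_channel_data <- function(probe, events, pulse, phantom, c = 1540,
                                  sampling_rate = 4 * pulse$center_frequency,
                                  duration = NULL, noise_db = NULL,
                                  n_sub = 2L, method = c("fast", "exact"),
                                  noise_seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(probe, "curvilinear_probe"), length(events) >= 1,
            inherits(pulse, "pulse"), inherits(phantom, "phantom"))
  pos <- element_positions(probe)
  if (length(phantom$x)) {
    dmin <- outer(phantom$x, pos$x, "-")^2 + outer(phantom$z, pos$z, "-")^2
    if (min(dmin) < (probe$pitch * 1e-3)^2)
      stop("scatterer coincides with an element position")
  }
  tab <- pulse_table(pulse$center_frequency, pulse$fractional_bandwidth,
                     kind = "point")
  dall <- if (length(phantom$x))
    sqrt(outer(phantom$x, pos$x, "-")^2 + outer(phantom$z, pos$z, "-")^2)
  else 0.025
  if (is.null(duration))
    duration <- 2 * max(dall) / c +
      max(vapply(events, function(e) max(e$delays), 0)) + 2 * max(abs(tab$t))
  # start the record just before the earliest possible echo
  t0 <- max(0, floor((2 * min(dall) / c - 2 * max(abs(tab$t))) *
                       sampling_rate) / sampling_rate)
  n_t <- ceiling((duration - t0) * sampling_rate)
  sub <- .element_subsources(probe, n_sub)
  traces <- array(0, dim = c(length(events), probe$n_elements, n_t))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    act <- ev$active_elements[ev$apodization[ev$active_elements] > 0]
    if (length(phantom$x)) {
      traces[i, , ] <- if (method == "fast") t(simulate_event_cpp(
        phantom$x, phantom$z, phantom$amplitude,
        sub$x[act, , drop = FALSE], sub$z[act, , drop = FALSE],
        ev$delays[act], ev$apodization[act],
        sub$x, sub$z, c, sampling_rate, t0, as.integer(n_t),
        tab$s, tab$dt, tab$t[1], 2L))
      else t(simulate_event_exact_cpp(
        phantom$x, phantom$z, phantom$amplitude,
        sub$x[act, , drop = FALSE], sub$z[act, , drop = FALSE],
        ev$delays[act], ev$apodization[act],
        sub$x, sub$z, c, sampling_rate, t0, as.integer(n_t),
        tab$s, tab$dt, tab$t[1]))
    }
  }
  if (!is.null(noise_db)) {
    sd <- max(abs(traces)) * 10^(-noise_db / 20)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise_seed)
    traces <- traces + array(rnorm(length(traces), sd = sd), dim = dim(traces))
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
  channel_data(traces, sampling_rate, t0 = t0, probe = probe, pulse = pulse,
               events = events, sound_speed = c)
}
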