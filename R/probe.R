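#' Curvilinear (convex) array description
#'
#' A curvilinear probe is an arc of `n_elements` point-like element centres
#' at radius `radius_r0` from the centre of curvature, separated by an arc
#' length `pitch`. The total angular aperture
#' `(n_elements - 1) * pitch / radius_r0` must stay below `pi`.
#'
#' @param n_elements number of elements (>= 1).
#' @param radius_r0 radius of curvature of the element arc, metres.
#' @param pitch arc length between adjacent element centres, metres.
#' @param center_frequency nominal centre frequency in Hz, used only to pick
#'   defaults (radial step, pulse) downstream.
#' @return an object of class `curvilinear_probe`.
#' @examples
#' curvilinear_probe(128, 49.57e-3, 0.508e-3, 3.5e6)
#' @export
curvilinear_probe <- function(n_elements, radius_r0, pitch,
                              center_frequency = 3.5e6) {
  stopifnot(length(n_elements) == 1L, n_elements >= 1,
            n_elements == round(n_elements),
            length(radius_r0) == 1L, radius_r0 > 0,
            length(pitch) == 1L, pitch > 0,
            center_frequency > 0)
  span <- (n_elements - 1) * pitch / radius_r0
  if (span >= pi)
    stop("total angular aperture (n_elements - 1) * pitch / radius_r0 must be < pi")
  structure(list(n_elements = as.integer(n_elements),
                 radius_r0 = radius_r0, pitch = pitch,
                 center_frequency = center_frequency),
            class = "curvilinear_probe")
}

#' @export
print.curvilinear_probe <- function(x, ...) {
  cat(sprintf("Curvilinear probe: %d elements, r0 = %.2f mm, pitch = %.4f mm\n",
              x$n_elements, 1e3 * x$radius_r0, 1e3 * x$pitch))
  cat(sprintf("  angular pitch %.4f mrad, total span %.4f rad, f0 = %.2f MHz\n",
              1e3 * x$pitch / x$radius_r0,
              (x$n_elements - 1) * x$pitch / x$radius_r0,
              1e-6 * x$center_frequency))
  invisible(x)
}

#' Built-in probe presets
#'
#' Two probes used throughout the package's validation and comparison
#' studies: a generic 128-element curvilinear probe (49.57 mm radius,
#' 0.508 mm pitch, 3.5 MHz) and the Siemens 5C1 geometry (180 elements,
#' 46.03 mm radius, 0.3212 mm pitch).
#'
#' @param name `"c128"` or `"5c1"`.
#' @return a [curvilinear_probe].
#' @export
probe_preset <- function(name = c("c128", "5c1")) {
  name <- match.arg(name)
  switch(name,
         c128 = curvilinear_probe(128L, 49.57e-3, 0.508e-3, 3.5e6),
         `5c1` = curvilinear_probe(180L, 46.03e-3, 0.3212e-3, 3.5e6))
}

#' Element centre angles
#'
#' Angles of the element centres, symmetric about `theta = 0` (the array
#' centre), with exact spacing `pitch / radius_r0`.
#'
#' @param probe a [curvilinear_probe].
#' @return numeric vector of length `n_elements`, radians.
#' @export
element_angles <- function(probe) {
  stopifnot(inherits(probe, "curvilinear_probe"))
  n <- probe$n_elements
  (seq_len(n) - 1 - (n - 1) / 2) * (probe$pitch / probe$radius_r0)
}

#' Element centre positions in Cartesian coordinates
#'
#' @param probe a [curvilinear_probe].
#' @return a list with numeric vectors `x`, `z` (metres) and `theta`
#'   (radians).
#' @export
element_positions <- function(probe) {
  th <- element_angles(probe)
  list(x = probe$radius_r0 * sin(th), z = probe$radius_r0 * cos(th),
       theta = th)
}

#' Polar <-> Cartesian mappings
#'
#' The imaging convention `x = r sin(theta)`, `z = r cos(theta)`: `theta = 0`
#' is the depth axis through the array centre, positive `theta` toward
#' positive `x`. Radius is preserved exactly (`x^2 + z^2 = r^2`).
#'
#' @param theta angle(s), radians.
#' @param r radius(es), metres; must be positive.
#' @return `polar_to_cartesian`: list with `x`, `z`; `cartesian_to_polar`:
#'   list with `theta`, `r`.
#' @export
polar_to_cartesian <- function(theta, r) {
  if (any(r <= 0)) stop("r must be positive")
  list(x = r * sin(theta), z = r * cos(theta))
}

#' @rdname polar_to_cartesian
#' @param x,z Cartesian coordinates, metres.
#' @export
cartesian_to_polar <- function(x, z) {
  r <- sqrt(x^2 + z^2)
  if (any(r <= 0)) stop("point at the origin has no polar angle")
  list(theta = atan2(x, z), r = r)
}

#' Polar reconstruction grid
#'
#' Uniform angular samples (required by the discrete angular Fourier
#' transform) and uniform radial samples starting at the probe radius `r0`.
#' The implied log-radius `rho = log(r)` is available via `$rho`.
#'
#' @param theta_samples monotone increasing, uniformly spaced angles
#'   (radians).
#' @param r_samples monotone increasing, uniformly spaced radii (metres);
#'   `r_samples[1]` is taken as the probe radius `r0`.
#' @return an object of class `polar_grid` with fields `theta`, `r`, `rho`,
#'   `dtheta`, `dr`, `n_theta`, `n_r`, `r0`.
#' @export
polar_grid <- function(theta_samples, r_samples) {
  stopifnot(length(theta_samples) >= 2L, length(r_samples) >= 1L,
            all(r_samples > 0))
  dth <- diff(theta_samples)
  if (any(dth <= 0) || diff(range(dth)) > 1e-9 * mean(dth))
    stop("theta_samples must be uniformly increasing")
  if (length(r_samples) > 1L) {
    dr <- diff(r_samples)
    if (any(dr <= 0) || diff(range(dr)) > 1e-9 * mean(dr))
      stop("r_samples must be uniformly increasing")
    dr <- mean(dr)
  } else dr <- NA_real_
  structure(list(theta = theta_samples, r = r_samples, rho = log(r_samples),
                 dtheta = mean(dth), dr = dr,
                 n_theta = length(theta_samples), n_r = length(r_samples),
                 r0 = r_samples[1]),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf(
    "Polar grid: %d theta x %d r; theta in [%.4f, %.4f] rad (d = %.3f mrad)\n",
    x$n_theta, x$n_r, min(x$theta), max(x$theta), 1e3 * x$dtheta))
  cat(sprintf("  r in [%.2f, %.2f] mm (dr = %.4f mm)\n",
              1e3 * min(x$r), 1e3 * max(x$r), 1e3 * x$dr))
  invisible(x)
}

#' Default polar grid for a probe
#'
#' Builds a grid spanning the probe aperture plus a margin (for window
#' tapers and diffraction spill), with `n_theta` angular samples and radial
#' steps `dr` from `r0` to `r0 + max_depth`.
#'
#' @param probe a [curvilinear_probe].
#' @param max_depth imaging depth beyond the array surface, metres.
#' @param n_theta angular sample count.
#' @param dr radial step, metres; default half a wavelength at the probe's
#'   centre frequency in `c` = 1540 m/s.
#' @param margin extra angle beyond the aperture edge on each side, radians.
#' @param c sound speed used for the default `dr`, m/s.
#' @return a [polar_grid].
#' @export
default_grid <- function(probe, max_depth, n_theta = 256L,
                         dr = NULL, margin = 0.12, c = 1540) {
  if (is.null(dr)) dr <- c / probe$center_frequency / 2
  half <- (probe$n_elements - 1) * probe$pitch / probe$radius_r0 / 2 + margin
  theta <- seq(-half, half, length.out = n_theta)
  r <- seq(probe$radius_r0, probe$radius_r0 + max_depth, by = dr)
  polar_grid(theta, r)
}
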