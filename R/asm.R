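#' Complex wavefield on one radial shell
#'
#' A `polar_field` holds the temporal-frequency spectra of the pressure field
#' on a single shell at its `radius`: a complex matrix indexed (theta sample,
#' frequency bin). The angular axis must be uniform so the discrete angular
#' Fourier transform applies.
#'
#' @param values complex matrix, `length(theta_axis)` x `length(freq_axis)`.
#' @param radius shell radius, metres.
#' @param freq_axis frequency bins, Hz.
#' @param theta_axis uniform angular samples, radians.
#' @return an object of class `polar_field`.
#' @export
polar_field <- function(values, radius, freq_axis, theta_axis) {
  values <- as.matrix(values)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  stopifnot(nrow(values) == length(theta_axis),
            ncol(values) == length(freq_axis),
            length(radius) == 1L, radius > 0,
            all(is.finite(Re(values))), all(is.finite(Im(values))))
  .check_uniform(theta_axis, "theta_axis")
  structure(list(values = values, radius = radius,
                 freq_axis = freq_axis, theta_axis = theta_axis),
            class = "polar_field")
}

#' @export
print.polar_field <- function(x, ...) {
  cat(sprintf(
    "Polar field at r = %.2f mm: %d theta samples x %d frequency bins\n",
    1e3 * x$radius, length(x$theta_axis), length(x$freq_axis)))
  cat(sprintf("  f in [%.2f, %.2f] MHz, RMS %.3g\n",
              1e-6 * min(x$freq_axis), 1e-6 * max(x$freq_axis),
              sqrt(mean(Mod(x$values)^2))))
  invisible(x)
}

.check_uniform <- function(x, name) {
  if (length(x) < 2L) return(invisible(TRUE))
  d <- diff(x)
  if (any(d <= 0) || diff(range(d)) > 1e-9 * abs(mean(d)))
    stop(sprintf("%s must be uniformly increasing", name))
  invisible(TRUE)
}

#' Discrete-transform frequency bins
#'
#' Bin frequencies for an `n`-point discrete Fourier transform of samples
#' spaced `d` apart, in the standard wrap-around layout (0, positive,
#' negative). Units are cycles per unit of `d`.
#'
#' @param n sample count.
#' @param d sample spacing.
#' @return numeric vector of length `n`.
#' @export
fft_freqs <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

#' Propagation settings between two shells
#'
#' @param r1,r2 source and destination shell radii, metres.
#' @param sound_speed scalar sound speed for the interval, m/s.
#' @param branch `"+"` or `"-"`: sign of the propagator exponent. With the
#'   package's `exp(-2i pi f t)` analysis convention, branch `"-"` advances a
#'   transmitted (outgoing) field outward in `r` and branch `"+"` marches
#'   receive data outward while unwinding their travel time.
#' @param evanescent `"zero"` (default) or `"decay"`: handling of components
#'   with `f*r/(c*|k_theta|) <= 1`. `"zero"` accumulates phase only over the
#'   propagating portion of the path and hard-zeros modes that are evanescent
#'   at the destination radius; `"decay"` analytically continues the phase
#'   integral with the branch for which `|H| <= 1`.
#' @return an object of class `propagator_spec`.
#' @export
propagator_spec <- function(r1, r2, sound_speed = 1540,
                            branch = c("-", "+"),
                            evanescent = c("zero", "decay")) {
  branch <- match.arg(branch)
  evanescent <- match.arg(evanescent)
  stopifnot(r1 > 0, r2 > 0, sound_speed > 0)
  structure(list(r1 = r1, r2 = r2, sound_speed = sound_speed,
                 branch = branch, evanescent = evanescent),
            class = "propagator_spec")
}

# phase integral Phi(u) = sqrt(u^2-1) - atan(sqrt(u^2-1)) for u > 1, else 0;
# companion decay integral psi(u) = atanh(sqrt(1-u^2)) - sqrt(1-u^2) for u < 1
.phi_prop <- function(u) {
  out <- numeric(length(u))
  p <- which(u > 1)
  if (length(p)) {
    s <- sqrt(u[p]^2 - 1)
    out[p] <- s - atan(s)
  }
  out
}

.psi_evan <- function(u) {
  out <- numeric(length(u))
  e <- which(u < 1 & u > 0)
  if (length(e)) {
    s <- sqrt(1 - u[e]^2)
    out[e] <- atanh(s) - s
  }
  out[u <= 0] <- Inf
  out
}

# propagator matrix over (k_theta, f); k in cycles/radian, f in Hz
.prop_matrix <- function(k_theta, f, r1, r2, sound_speed, branch = "-",
                         evanescent = "zero") {
  sgn <- if (branch == "+") 1 else -1
  nk <- length(k_theta); nf <- length(f)
  H <- matrix(0 + 0i, nk, nf)
  ak <- abs(k_theta)
  kz <- which(ak == 0)
  knz <- which(ak > 0)
  if (length(kz))
    H[kz, ] <- matrix(exp(sgn * 2i * pi * f * (r2 - r1) / sound_speed),
                      length(kz), nf, byrow = TRUE)
  if (length(knz)) {
    akn <- ak[knz]
    u1 <- outer(1 / akn, f * r1 / sound_speed)   # f*r1/(c*|k|)
    u2 <- outer(1 / akn, f * r2 / sound_speed)
    phase <- akn * (matrix(.phi_prop(u2), length(knz), nf) -
                    matrix(.phi_prop(u1), length(knz), nf))
    Hnz <- exp(sgn * 2i * pi * phase)
    if (evanescent == "zero") {
      if (r1 != r2) {   # a zero-length step is the identity
        udest <- if (r2 > r1) u2 else u1
        Hnz[udest <= 1] <- 0 + 0i
      }
    } else {
      decay <- akn * abs(matrix(.psi_evan(u2), length(knz), nf) -
                         matrix(.psi_evan(u1), length(knz), nf))
      decay[!is.finite(decay)] <- Inf
      Hnz <- Hnz * exp(-2 * pi * decay)
    }
    H[knz, ] <- Hnz
  }
  H
}

#' Closed-form radial propagator
#'
#' Transfer function `H(k_theta, f)` advancing the angular spectrum of a
#' wavefield from the shell `r1` to the shell `r2`:
#' `H = exp(s * 2i*pi*|k_theta| * (Phi(r2) - Phi(r1)))` with
#' `Phi(r) = sqrt(u^2 - 1) - atan(sqrt(u^2 - 1))`, `u = f*r/(c*|k_theta|)`,
#' and `s = +1` or `-1` by `spec$branch`. In the fully propagating regime
#' (`u > 1` at both radii) the modulus is exactly 1; the `k_theta = 0` bin is
#' evaluated by its closed-form limit `exp(s * 2i*pi*f*(r2 - r1)/c)`.
#' Evanescent components are handled per `spec$evanescent`.
#'
#' @param k_theta angular spatial frequencies, cycles/radian.
#' @param spec a [propagator_spec].
#' @param f frequency, Hz (scalar or vector; `f >= 0`).
#' @return complex vector (scalar `f`) or `length(k_theta)` x `length(f)`
#'   matrix.
#' @export
propagator <- function(k_theta, spec, f) {
  stopifnot(inherits(spec, "propagator_spec"), all(f >= 0),
            all(is.finite(k_theta)), all(is.finite(f)))
  H <- .prop_matrix(k_theta, f, spec$r1, spec$r2, spec$sound_speed,
                    spec$branch, spec$evanescent)
  if (length(f) == 1L) drop(H) else H
}

#' Angular Fourier transform of a shell field
#'
#' Forward maps `theta -> k_theta` with the kernel
#' `exp(-2i*pi*k_theta*theta)`; inverse uses the conjugate kernel. The
#' discrete forms are scaled by the sample spacings (`dtheta` forward,
#' `dk_theta` inverse) so the round trip is the identity and Parseval's
#' relation holds: `sum |f|^2 dtheta = sum |F|^2 dk`. `k_theta` bins follow
#' [fft_freqs] layout, in cycles/radian.
#'
#' @param values complex vector or matrix (theta along rows).
#' @param theta uniform angular axis, radians.
#' @param direction `"forward"` or `"inverse"`. For `"inverse"`, `values`
#'   are spectra on the `fft_freqs(length(theta), dtheta)` bins.
#' @return list with `values` and `k_theta` (forward) or `theta` (inverse).
#' @export
angular_transform <- function(values, theta, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  .check_uniform(theta, "theta")
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  n <- length(theta)
  stopifnot(nrow(v) == n)
  dth <- (theta[n] - theta[1]) / (n - 1)
  k <- fft_freqs(n, dth)
  if (direction == "forward") {
    out <- mvfft(v) * dth * exp(-2i * pi * k * theta[1])
    list(values = if (is.matrix(values)) out else drop(out), k_theta = k)
  } else {
    dk <- 1 / (n * dth)
    out <- Conj(mvfft(Conj(v * exp(2i * pi * k * theta[1])))) * dk
    list(values = if (is.matrix(values)) out else drop(out), theta = theta)
  }
}

#' Tukey (cosine-tapered) angular window
#'
#' Weight 1 over the interior of the angular aperture, rolling smoothly to 0
#' at both edges over `taper_fraction / 2` of the aperture on each side.
#' Applied at every extrapolation step to suppress wrap-around of the
#' circular angular convolution.
#'
#' @param n_theta number of angular samples (>= 4).
#' @param taper_fraction total tapered fraction in `[0, 1]`; 0 gives all
#'   ones, 1 a full Hann profile.
#' @return numeric vector of weights in `[0, 1]`.
#' @export
make_window <- function(n_theta, taper_fraction = 0.25) {
  stopifnot(n_theta >= 4, taper_fraction >= 0, taper_fraction <= 1)
  if (taper_fraction == 0) return(rep(1, n_theta))
  x <- (seq_len(n_theta) - 1) / (n_theta - 1)
  w <- rep(1, n_theta)
  half <- taper_fraction / 2
  lo <- x < half
  hi <- x > 1 - half
  w[lo] <- 0.5 * (1 + cos(pi * (x[lo] / half - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((x[hi] - 1) / half + 1)))
  w
}

#' One angular-spectrum extrapolation step
#'
#' Transforms the shell field to its angular spectrum, multiplies by the
#' closed-form propagator for the interval `spec$r1 -> spec$r2`, inverse
#' transforms, and applies the angular window: `W * Finv(H * F(p))`.
#'
#' @param field a [polar_field] at radius `spec$r1`.
#' @param spec a [propagator_spec]; `spec$r1` must equal `field$radius`.
#' @param window weights over theta in `[0, 1]`; default all ones.
#' @return a [polar_field] at radius `spec$r2`.
#' @export
asm_step <- function(field, spec, window = NULL) {
  stopifnot(inherits(field, "polar_field"), inherits(spec, "propagator_spec"))
  if (abs(spec$r1 - field$radius) > 1e-9 * field$radius)
    stop("field radius does not match spec$r1")
  n <- length(field$theta_axis)
  if (is.null(window)) window <- rep(1, n)
  if (length(window) != n) stop("window length must match the theta axis")
  if (any(window < 0 | window > 1)) stop("window weights must lie in [0, 1]")
  dth <- (field$theta_axis[n] - field$theta_axis[1]) / (n - 1)
  k <- fft_freqs(n, dth)
  H <- .prop_matrix(k, field$freq_axis, spec$r1, spec$r2, spec$sound_speed,
                    spec$branch, spec$evanescent)
  # the theta-origin phase ramps of the forward and inverse transforms cancel
  spec_k <- mvfft(field$values)
  out <- Conj(mvfft(Conj(spec_k * H))) / n
  polar_field(out * window, spec$r2, field$freq_axis, field$theta_axis)
}

#' March a shell field across a radial grid
#'
#' Repeated [asm_step] over the intervals of `grid$r`, using each interval's
#' sound speed (piecewise-constant radially varying profile). Returns the
#' requested shells as a (theta, shell, frequency) cube.
#'
#' @param initial a [polar_field] at `grid$r[1]`.
#' @param grid a [polar_grid]; its theta axis must match the field's.
#' @param sound_speed scalar, vector of per-interval speeds (length
#'   `n_r - 1`), or a function of the interval mid-radius, m/s.
#' @param branch propagator branch, `"-"` (advance an outgoing transmit
#'   field) or `"+"` (march receive data outward).
#' @param window angular window from [make_window], applied every step.
#' @param keep indices into `grid$r` of shells to retain (default all).
#' @param evanescent evanescent-component policy, see [propagator_spec].
#' @return list of class `field_cube`: `values` (n_theta x length(keep) x
#'   n_f complex array), `theta`, `r` (kept radii), `freq_axis`.
#' @export
asm_march <- function(initial, grid, sound_speed = 1540,
                      branch = c("-", "+"), window = NULL,
                      keep = seq_along(grid$r),
                      evanescent = c("zero", "decay")) {
  branch <- match.arg(branch)
  evanescent <- match.arg(evanescent)
  stopifnot(inherits(initial, "polar_field"), inherits(grid, "polar_grid"))
  if (grid$n_r < 1L) stop("empty radial grid")
  if (abs(grid$r[1] - initial$radius) > 1e-9 * initial$radius)
    stop("grid$r[1] must equal the initial field's radius")
  if (length(grid$theta) != length(initial$theta_axis) ||
      max(abs(grid$theta - initial$theta_axis)) > 1e-12)
    stop("grid theta axis must match the field's theta axis")
  cs <- .interval_speeds(grid$r, sound_speed)
  keep <- sort(unique(as.integer(keep)))
  stopifnot(all(keep >= 1L), all(keep <= grid$n_r))
  nf <- length(initial$freq_axis)
  out <- array(0 + 0i, dim = c(grid$n_theta, length(keep), nf))
  fld <- initial
  ki <- 1L
  if (length(keep) && keep[1] == 1L) {
    out[, 1L, ] <- fld$values
    ki <- 2L
  }
  if (grid$n_r > 1L) for (i in seq_len(grid$n_r - 1L)) {
    sp <- propagator_spec(grid$r[i], grid$r[i + 1L], cs[i], branch, evanescent)
    fld <- asm_step(fld, sp, window)
    if (ki <= length(keep) && keep[ki] == i + 1L) {
      out[, ki, ] <- fld$values
      ki <- ki + 1L
    }
  }
  structure(list(values = out, theta = grid$theta, r = grid$r[keep],
                 freq_axis = initial$freq_axis),
            class = "field_cube")
}

.interval_speeds <- function(r, sound_speed) {
  n_int <- max(length(r) - 1L, 0L)
  if (is.function(sound_speed)) {
    cs <- sound_speed((r[-1] + r[-length(r)]) / 2)
  } else if (length(sound_speed) == 1L) {
    cs <- rep(sound_speed, n_int)
  } else if (length(sound_speed) == n_int) {
    cs <- sound_speed
  } else stop("sound_speed must be scalar, per-interval vector, or function")
  if (any(cs <= 0)) stop("sound speed must be positive")
  cs
}
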