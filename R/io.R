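CHANNEL_FORMAT <- "polarasm-channel"
IMAGE_FORMAT <- "polarasm-image"
CONTAINER_VERSION <- 1L

#' Write / read a channel-data container
#'
#' Serializes a [channel_data] object to a single-file container holding
#' the trace array (`channel_data`, transmit x element x time), the
#' sampling rate and `t0`, the per-event delay and apodization tables, the
#' probe geometry and pulse description, and a format/version stamp. The
#' round trip is lossless; readers validate the schema and report the first
#' missing field by name.
#'
#' @param channel a [channel_data].
#' @param path file path.
#' @return `write_channel_container`: the path, invisibly;
#'   `read_channel_container`: a [channel_data].
#' @export
write_channel_container <- function(channel, path) {
  stopifnot(inherits(channel, "channel_data"))
  n_tx <- length(channel$events)
  delays <- t(vapply(channel$events, `[[`, numeric(channel$probe$n_elements),
                     "delays"))
  apod <- t(vapply(channel$events, `[[`,
                   numeric(channel$probe$n_elements), "apodization"))
  obj <- list(
    format = CHANNEL_FORMAT, version = CONTAINER_VERSION,
    channel_data = channel$traces,
    sampling_rate = channel$sampling_rate,
    t0 = channel$t0,
    delays = delays, apodization = apod,
    probe = list(n_elements = channel$probe$n_elements,
                 radius = channel$probe$radius_r0,
                 pitch = channel$probe$pitch,
                 center_frequency = channel$probe$center_frequency),
    pulse = list(center_frequency = channel$pulse$center_frequency,
                 fractional_bandwidth = channel$pulse$fractional_bandwidth),
    events = lapply(channel$events, function(e)
      list(focus_theta = e$focus_theta, focus_r = e$focus_r,
           t_focus = e$t_focus, active_elements = e$active_elements)),
    sound_speed = channel$sound_speed,
    package_version = as.character(utils::packageVersion("polarasm")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_channel_container
#' @export
read_channel_container <- function(path) {
  obj <- readRDS(path)
  req <- c("format", "version", "channel_data", "sampling_rate", "t0",
           "delays", "apodization", "probe", "pulse", "events")
  for (f in req) if (is.null(obj[[f]]))
    stop(sprintf("channel container is missing required dataset '%s'", f))
  if (!identical(obj$format, CHANNEL_FORMAT))
    stop("not a polarasm channel container")
  if (obj$version > CONTAINER_VERSION)
    stop(sprintf("container version %d is newer than supported version %d",
                 obj$version, CONTAINER_VERSION))
  probe <- curvilinear_probe(obj$probe$n_elements, obj$probe$radius,
                             obj$probe$pitch, obj$probe$center_frequency)
  nf_axis <- obj$pulse$center_frequency   # pulse tabulated lazily downstream
  pulse <- gaussian_pulse_spectrum(obj$pulse$center_frequency,
                                   obj$pulse$fractional_bandwidth,
                                   seq(0, 2 * nf_axis, length.out = 64))
  events <- lapply(seq_along(obj$events), function(i) {
    e <- obj$events[[i]]
    structure(list(delays = obj$delays[i, ], apodization = obj$apodization[i, ],
                   focus_theta = e$focus_theta, focus_r = e$focus_r,
                   t_focus = e$t_focus,
                   active_elements = as.integer(e$active_elements)),
              class = "transmit_event")
  })
  channel_data(obj$channel_data, obj$sampling_rate, obj$t0, probe, pulse,
               events, sound_speed = obj$sound_speed)
}

#' Write / read an image container
#'
#' Stores a [polar_image] (complex values, theta/r axes, and all
#' reconstruction metadata) with a format/version stamp.
#'
#' @param image a [polar_image].
#' @param path file path.
#' @return `write_image_container`: the path, invisibly;
#'   `read_image_container`: a [polar_image].
#' @export
write_image_container <- function(image, path) {
  stopifnot(inherits(image, "polar_image"))
  saveRDS(list(format = IMAGE_FORMAT, version = CONTAINER_VERSION,
               values = image$values, theta = image$grid$theta,
               r = image$grid$r, metadata = image$metadata,
               per_shot = image$per_shot,
               package_version = as.character(utils::packageVersion("polarasm"))),
          path)
  invisible(path)
}

#' @rdname write_image_container
#' @export
read_image_container <- function(path) {
  obj <- readRDS(path)
  req <- c("format", "version", "values", "theta", "r", "metadata")
  for (f in req) if (is.null(obj[[f]]))
    stop(sprintf("image container is missing required dataset '%s'", f))
  if (!identical(obj$format, IMAGE_FORMAT))
    stop("not a polarasm image container")
  polar_image(obj$values, polar_grid(obj$theta, obj$r), obj$metadata,
              isTRUE(obj$per_shot))
}

#' Scan conversion to a Cartesian raster
#'
#' Bilinear interpolation of a polar image from `(theta, r)` to `(x, z)`
#' pixels. Pixels outside the sector get the sentinel value.
#'
#' @param image a [polar_image].
#' @param x_range,z_range `c(min, max)` metres.
#' @param pixel_size metres.
#' @param what `"envelope"` (default), `"db"` (log-compressed envelope) or
#'   `"complex"`.
#' @param dynamic_range dB, for `what = "db"`.
#' @param sentinel value for pixels outside the sector (default `NA`).
#' @return list with pixel-centre axes `x`, `z` and `values`
#'   (`length(x)` x `length(z)`).
#' @export
scan_convert <- function(image, x_range, z_range, pixel_size,
                         what = c("envelope", "db", "complex"),
                         dynamic_range = 60, sentinel = NA_real_) {
  what <- match.arg(what)
  stopifnot(inherits(image, "polar_image"), pixel_size > 0)
  g <- image$grid
  v <- switch(what,
              envelope = Mod(image$values),
              db = log_compress(image, dynamic_range),
              complex = image$values)
  xs <- seq(x_range[1], x_range[2], by = pixel_size)
  zs <- seq(z_range[1], z_range[2], by = pixel_size)
  px <- rep(xs, times = length(zs))
  pz <- rep(zs, each = length(xs))
  pth <- atan2(px, pz)
  pr <- sqrt(px^2 + pz^2)
  ti <- (pth - g$theta[1]) / g$dtheta
  ri <- (pr - g$r[1]) / g$dr
  inside <- ti >= 0 & ti <= g$n_theta - 1 & ri >= 0 & ri <= g$n_r - 1
  if (!any(inside)) stop("cartesian region does not overlap the sector")
  out <- rep(if (what == "complex") complex(real = sentinel) else sentinel,
             length(px))
  t0i <- pmin(floor(ti[inside]), g$n_theta - 2); tf <- ti[inside] - t0i
  r0i <- pmin(floor(ri[inside]), g$n_r - 2); rf <- ri[inside] - r0i
  v11 <- v[cbind(t0i + 1, r0i + 1)]
  v21 <- v[cbind(t0i + 2, r0i + 1)]
  v12 <- v[cbind(t0i + 1, r0i + 2)]
  v22 <- v[cbind(t0i + 2, r0i + 2)]
  out[inside] <- (1 - tf) * (1 - rf) * v11 + tf * (1 - rf) * v21 +
    (1 - tf) * rf * v12 + tf * rf * v22
  list(x = xs, z = zs, values = matrix(out, length(xs), length(zs)))
}

#' Read a reconstruction / simulation configuration
#'
#' Plain YAML configuration with explicit units in key names. Recognized
#' blocks: `probe` (either `preset: c128|5c1` or `n_elements`, `radius_mm`,
#' `pitch_mm`, `center_frequency_mhz`), `pulse`
#' (`center_frequency_mhz`, `fractional_bandwidth`), `sequence` (`n_beams`,
#' `span_deg`, `focal_depth_mm`, `subaperture`), `medium` (`c_m_s`, or a
#' `c_profile` table of `r_mm`/`c_m_s`), `grid` (`n_theta`, `dr_mm`,
#' `max_depth_mm`, `margin_rad`), `recon` (`f_number`, `band_mode`,
#' `band_taper`, `window_taper`), `seed`.
#'
#' @param path YAML file.
#' @param overrides named list overriding file values (CLI flags).
#' @return a named list of resolved, SI-unit configuration values.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  out <- list()
  pb <- cfg$probe
  out$probe <- if (!is.null(pb$preset)) probe_preset(pb$preset) else
    curvilinear_probe(pb$n_elements, pb$radius_mm * 1e-3, pb$pitch_mm * 1e-3,
                      (pb$center_frequency_mhz %||% 3.5) * 1e6)
  if (!is.null(cfg$pulse))
    out$pulse_spec <- list(center_frequency = cfg$pulse$center_frequency_mhz * 1e6,
                           fractional_bandwidth = cfg$pulse$fractional_bandwidth)
  if (!is.null(cfg$sequence))
    out$sequence <- list(n_beams = cfg$sequence$n_beams,
                         span = cfg$sequence$span_deg * pi / 180,
                         focal_depth = cfg$sequence$focal_depth_mm * 1e-3,
                         subaperture = cfg$sequence$subaperture)
  md <- cfg$medium
  out$sound_speed <- if (is.null(md)) 1540 else if (!is.null(md$c_profile)) {
    tab <- md$c_profile
    function(r) stats::approx(tab$r_mm * 1e-3, tab$c_m_s, r, rule = 2)$y
  } else md$c_m_s %||% 1540
  if (!is.null(cfg$grid))
    out$grid_spec <- list(n_theta = cfg$grid$n_theta,
                          dr = cfg$grid$dr_mm * 1e-3,
                          max_depth = cfg$grid$max_depth_mm * 1e-3,
                          margin = cfg$grid$margin_rad %||% 0.12)
  out$recon <- cfg$recon
  out$seed <- cfg$seed %||% 1L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
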