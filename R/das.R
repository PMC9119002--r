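#' Virtual-source synthetic-aperture delay-and-sum beamformer
#'
#' The comparison baseline: each focused transmit is modelled as a virtual
#' point source at its focus. For a pixel `p` and event with focus `v` on
#' beam axis `a`, the transmit time is `t_focus +/- |p - v| / c` (`+` beyond
#' the focus, `-` before it, the two-sided hyperbolic model), the receive
#' time is `|p - e| / c` per element, and each element's analytic-signal
#' trace is sampled at the round-trip time with linear interpolation.
#' Elements are admitted by an f-number aperture-growth rule (angle between
#' the pixel-element ray and the element normal at most
#' `atan(1/(2 f_number))`, cosine-tapered over the outer 10%), summed, and
#' the per-event images are coherently compounded. Events contribute only
#' inside a validity cone about their beam axis as seen from the virtual
#' source, with a cosine edge taper.
#'
#' @param channel a [channel_data] whose events carry their foci.
#' @param grid a [polar_grid] of image pixels.
#' @param sound_speed scalar, m/s.
#' @param f_number receive f-number (> 0) or 0 for the full aperture.
#' @param cone half-angle of the virtual-source validity cone, radians.
#' @param cone_taper fraction of the cone over which contributions roll off.
#' @param focus_blend radius (metres) of the focal region accepted in
#'   addition to the cone: the two-sided cone alone excludes the immediate
#'   neighbourhood of the focus (every direction is far off-axis there), so
#'   pixels within this distance of the virtual source are blended in with
#'   a cosine weight.
#' @param events subset of transmit events (default all).
#' @return a compounded [polar_image]; pixels never covered by any event's
#'   cone or recorded time window are zero.
#' @export
das_virtual_source <- function(channel, grid, sound_speed = channel$sound_speed,
                               f_number = 2, cone = 15 * pi / 180,
                               cone_taper = 0.2, focus_blend = 4e-3,
                               events = seq_along(channel$events)) {
  stopifnot(inherits(channel, "channel_data"), inherits(grid, "polar_grid"),
            f_number >= 0, cone > 0)
  probe <- channel$probe
  pos <- element_positions(probe)
  px <- as.vector(outer(sin(grid$theta), grid$r))
  pz <- as.vector(outer(cos(grid$theta), grid$r))
  fs <- channel$sampling_rate
  n_t <- dim(channel$traces)[3]
  acc <- complex(length(px))
  covered <- 0L
  for (i in events) {
    ev <- channel$events[[i]]
    vx <- ev$focus_r * sin(ev$focus_theta)
    vz <- ev$focus_r * cos(ev$focus_theta)
    ax <- sin(ev$focus_theta); az <- cos(ev$focus_theta)   # beam axis
    dxv <- px - vx; dzv <- pz - vz
    dv <- sqrt(dxv^2 + dzv^2)
    along <- dxv * ax + dzv * az
    # angle between the pixel-to-source line and the beam axis (two-sided)
    ang <- acos(pmin(1, abs(along) / pmax(dv, 1e-12)))
    wv <- numeric(length(px))
    inside <- dv > 1e-9 & ang <= cone
    edge <- ang > cone * (1 - cone_taper) & inside
    wv[inside] <- 1
    wv[edge] <- 0.5 * (1 + cos(pi * (ang[edge] / cone - (1 - cone_taper)) /
                                 cone_taper))
    if (focus_blend > 0) {
      near <- dv < focus_blend
      wv[near] <- pmax(wv[near], 0.5 * (1 + cos(pi * dv[near] / focus_blend)))
    }
    sel <- which(wv > 0)
    if (!length(sel)) next
    covered <- covered + length(sel)
    t_tx <- ev$t_focus + sign(along[sel]) * dv[sel] / sound_speed
    tr <- analytic_signal(t(channel$traces[i, , ]))       # n_t x n_rx
    contrib <- das_shot_cpp(tr, fs, channel$t0,
                            pos$x, pos$z, sin(pos$theta), cos(pos$theta),
                            px[sel], pz[sel], t_tx, sound_speed, f_number)
    acc[sel] <- acc[sel] + wv[sel] * contrib
  }
  if (covered == 0L) warning("no pixel fell inside any event's validity cone")
  polar_image(matrix(acc, grid$n_theta, grid$n_r),
              grid,
              metadata = list(beamformer = "virtual-source synthetic-aperture DAS",
                              f_number = f_number, cone_rad = cone,
                              cone_taper = cone_taper,
                              sound_speed = sound_speed),
              per_shot = FALSE)
}
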