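#' Normalized root-mean-square error between fields
#'
#' `100 * RMS(a * test - reference) / RMS(reference)` over the full compared
#' block, where `a` is the global least-squares amplitude scale aligning the
#' test field to the reference (scale only, no shift): the two simulators
#' differ by an arbitrary gain, so the comparison is of waveform shape.
#'
#' @param test,reference numeric arrays of identical shape on identical
#'   sample axes.
#' @return NRMSE in percent.
#' @export
nrmse <- function(test, reference) {
  stopifnot(length(test) == length(reference))
  ref2 <- sum(reference^2)
  if (ref2 == 0) stop("reference field is identically zero")
  t2 <- sum(test^2)
  a <- if (t2 > 0) sum(test * reference) / t2 else 0
  100 * sqrt(sum((a * test - reference)^2) / ref2)
}

#' Lateral -6 dB width of a point-target image
#'
#' Locates the envelope maximum within `search_radius` of the nominal point
#' location, refines the angular peak by parabolic interpolation, and
#' measures the full width at half the peak envelope (-6 dB) along the
#' lateral profile (the constant-`r` arc through the peak), converting the
#' angular width to arc length. Threshold crossings are linearly
#' interpolated. Measured on the pre-compression envelope; invariant to
#' global gain.
#'
#' @param image a [polar_image].
#' @param point_location list/vector with `theta`, `r` of the true target.
#' @param search_radius metres.
#' @return width in metres.
#' @export
lateral_fwhm <- function(image, point_location, search_radius = 2e-3) {
  stopifnot(inherits(image, "polar_image"))
  g <- image$grid
  env <- Mod(image$values)
  pt <- as.list(point_location)
  p <- polar_to_cartesian(pt$theta, pt$r)
  gx <- outer(sin(g$theta), g$r)
  gz <- outer(cos(g$theta), g$r)
  near <- (gx - p$x)^2 + (gz - p$z)^2 <= search_radius^2
  if (!any(near)) stop("no grid samples within search_radius of the point")
  masked <- env
  masked[!near] <- -Inf
  pk <- arrayInd(which.max(masked), dim(env))
  it <- pk[1]; ir <- pk[2]
  if (it <= 1L || it >= g$n_theta) stop("peak lies on the image boundary")
  prof <- env[, ir]
  # parabolic sub-sample refinement of the peak (position and height)
  y1 <- prof[it - 1]; y2 <- prof[it]; y3 <- prof[it + 1]
  denom <- y1 - 2 * y2 + y3
  dlt <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
  dlt <- max(min(dlt, 0.5), -0.5)
  peak <- y2 - 0.25 * (y1 - y3) * dlt
  half <- peak / 2
  # left crossing
  li <- it
  while (li > 1 && prof[li] >= half) li <- li - 1
  if (prof[li] >= half) stop("-6 dB width not bracketed on the left")
  fl <- li + (half - prof[li]) / (prof[li + 1] - prof[li])
  ri <- it
  while (ri < g$n_theta && prof[ri] >= half) ri <- ri + 1
  if (prof[ri] >= half) stop("-6 dB width not bracketed on the right")
  fr <- ri - (half - prof[ri]) / (prof[ri - 1] - prof[ri])
  (fr - fl) * g$dtheta * g$r[ir]
}

#' Region specifications on an image grid
#'
#' `region_disc` selects grid samples within `radius` of a centre given in
#' polar coordinates; `region_sector` selects a theta/r rectangle.
#'
#' @param theta,r centre (disc) or `c(min, max)` bounds (sector), radians /
#'   metres.
#' @param radius disc radius, metres.
#' @return an object of class `region_spec`.
#' @export
region_disc <- function(theta, r, radius) {
  structure(list(type = "disc", theta = theta, r = r, radius = radius),
            class = "region_spec")
}

#' @rdname region_disc
#' @export
region_sector <- function(theta, r) {
  structure(list(type = "sector", theta = theta, r = r),
            class = "region_spec")
}

region_mask <- function(region, grid) {
  stopifnot(inherits(region, "region_spec"), inherits(grid, "polar_grid"))
  if (region$type == "disc") {
    ctr <- polar_to_cartesian(region$theta, region$r)
    gx <- outer(sin(grid$theta), grid$r)
    gz <- outer(cos(grid$theta), grid$r)
    (gx - ctr$x)^2 + (gz - ctr$z)^2 <= region$radius^2
  } else {
    outer(grid$theta >= region$theta[1] & grid$theta <= region$theta[2],
          grid$r >= region$r[1] & grid$r <= region$r[2], "&")
  }
}

#' Anechoic lesion contrast
#'
#' `-20 * log10(mean envelope in lesion / mean envelope in background)`:
#' higher is better for an anechoic lesion. Invariant to global gain.
#'
#' @param image a [polar_image].
#' @param lesion,background [region_disc]/[region_sector] specifications;
#'   they must be non-empty and disjoint on the image grid.
#' @return contrast in dB.
#' @export
contrast_db <- function(image, lesion, background) {
  stopifnot(inherits(image, "polar_image"))
  ml <- region_mask(lesion, image$grid)
  mb <- region_mask(background, image$grid)
  if (!any(ml) || !any(mb)) stop("empty region on the image grid")
  if (any(ml & mb)) stop("lesion and background regions overlap")
  env <- Mod(image$values)
  bg <- mean(env[mb])
  if (bg == 0) stop("background envelope is identically zero")
  -20 * log10(mean(env[ml]) / bg)
}
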