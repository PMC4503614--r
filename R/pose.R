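#' Camera tilt from the laser-line measurements
#'
#' The vertical offset of the laser lines' vanishing point encodes the
#' downward tilt \eqn{\lambda} of the optical axis relative to the seabed:
#' \deqn{\tan\lambda = \left[\frac{m_0}{M} - \frac12 +
#'   \frac{n'}{n_1+n_2}\frac{m}{M}\right] \, 2\tan(\alpha_V/2)}
#' with \eqn{\cos\lambda = (1+\tan^2\lambda)^{-1/2}}. A positive tilt (camera
#' pitched down) moves the vanishing point above the image centre.
#'
#' Over a sloping seabed the recovered angle is the *apparent* tilt, the
#' angle between the optical axis and the seabed surface; see
#' [seabed_slope()].
#'
#' @param meas An [image_measurements()] object.
#' @param cam A [camera_intrinsics()] object.
#' @return A list with `cos_tilt`, `tan_tilt`, `tilt` (radians) and
#'   `tilt_deg`.
#' @seealso [pan_from_measurements()], [estimate_pose()]
#' @export
tilt_from_measurements <- function(meas, cam) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  bracket <- meas$m0 / cam$height - 0.5 +
    meas$n_prime / (meas$n1 + meas$n2) * meas$m / cam$height
  tan_tilt <- bracket * 2 * cam$tan_v2
  cos_tilt <- 1 / sqrt(1 + tan_tilt^2)
  list(cos_tilt = cos_tilt, tan_tilt = tan_tilt,
       tilt = atan(tan_tilt), tilt_deg = atan(tan_tilt) * 180 / pi)
}

#' Camera pan from the laser-line measurements
#'
#' The horizontal offset of the vanishing vertical encodes the pan
#' \eqn{\gamma} (signed rotation about the vertical; positive = camera
#' rotated to the right, which moves the vanishing point *left* of centre
#' because the laser direction is fixed to the vehicle frame, not to the
#' camera):
#' \deqn{\tan\gamma = \left[\frac12 - \frac{n_0}{N} -
#'   \frac{n_1}{n_1+n_2}\frac{n'}{N}\right] \, 2\tan(\alpha_H/2)\cos\lambda}
#'
#' @inheritParams tilt_from_measurements
#' @param cos_tilt The tilt cosine from [tilt_from_measurements()]; computed
#'   internally when omitted.
#' @return A list with `cos_pan`, `tan_pan`, `pan` (radians) and `pan_deg`.
#' @export
pan_from_measurements <- function(meas, cam, cos_tilt = NULL) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  if (is.null(cos_tilt)) cos_tilt <- tilt_from_measurements(meas, cam)$cos_tilt
  bracket <- 0.5 - meas$n0 / cam$width -
    meas$n1 / (meas$n1 + meas$n2) * meas$n_prime / cam$width
  tan_pan <- bracket * 2 * cam$tan_h2 * cos_tilt
  cos_pan <- 1 / sqrt(1 + tan_pan^2)
  list(cos_pan = cos_pan, tan_pan = tan_pan,
       pan = atan(tan_pan), pan_deg = atan(tan_pan) * 180 / pi)
}

#' Full camera pose (tilt, pan, vanishing point) from one image
#'
#' Combines [tilt_from_measurements()] and [pan_from_measurements()] and
#' locates the vanishing point of the projected laser lines.
#'
#' @inheritParams tilt_from_measurements
#' @return An object of class `laser_pose`: `cos_tilt`, `cos_pan`, `tilt`,
#'   `pan` (radians), `tilt_deg`, `pan_deg`, `vp_u`, `vp_v` (offsets of the
#'   vanishing point from the image centre; u positive rightward, v positive
#'   upward) and `vp_raster` (u, v raster coordinates, possibly outside the
#'   image).
#' @examples
#' cam <- camera_intrinsics(50.43, 29.67, 1280, 800)
#' meas <- image_measurements(312, 232, 465, 52, 29, 367, 143)
#' estimate_pose(meas, cam)
#' @export
estimate_pose <- function(meas, cam) {
  t <- tilt_from_measurements(meas, cam)
  p <- pan_from_measurements(meas, cam, t$cos_tilt)
  pose <- structure(
    list(cos_tilt = t$cos_tilt, cos_pan = p$cos_pan,
         tan_tilt = t$tan_tilt, tan_pan = p$tan_pan,
         tilt = t$tilt, pan = p$pan,
         tilt_deg = t$tilt_deg, pan_deg = p$pan_deg),
    class = "laser_pose")
  vp <- vanishing_point(pose, cam)
  pose$vp_u <- vp[["vp_u"]]
  pose$vp_v <- vp[["vp_v"]]
  pose$vp_raster <- c(u = cam$width / 2 + vp[["vp_u"]],
                      v = cam$height / 2 - vp[["vp_v"]])
  pose
}

#' Manually specified camera pose
#'
#' Builds a `laser_pose` from known angles, e.g. to drive the grid overlay
#' from an externally calibrated attitude.
#'
#' @param tilt_deg Downward tilt of the optical axis, degrees, in (-90, 90).
#' @param pan_deg Signed pan, degrees, in (-90, 90).
#' @param cam A [camera_intrinsics()] object (for the vanishing point).
#' @return A `laser_pose` object.
#' @export
laser_pose <- function(tilt_deg, pan_deg, cam) {
  .assert_class(cam, "camera_intrinsics", "cam")
  stopifnot(abs(tilt_deg) < 90, abs(pan_deg) < 90)
  tilt <- tilt_deg * pi / 180
  pan <- pan_deg * pi / 180
  pose <- structure(
    list(cos_tilt = cos(tilt), cos_pan = cos(pan),
         tan_tilt = tan(tilt), tan_pan = tan(pan),
         tilt = tilt, pan = pan, tilt_deg = tilt_deg, pan_deg = pan_deg),
    class = "laser_pose")
  vp <- vanishing_point(pose, cam)
  pose$vp_u <- vp[["vp_u"]]
  pose$vp_v <- vp[["vp_v"]]
  pose$vp_raster <- c(u = cam$width / 2 + vp[["vp_u"]],
                      v = cam$height / 2 - vp[["vp_v"]])
  pose
}

#' @export
print.laser_pose <- function(x, ...) {
  cat(sprintf("<laser_pose> tilt = %.3f deg, pan = %.3f deg\n",
              x$tilt_deg, x$pan_deg))
  if (!is.null(x$vp_raster))
    cat(sprintf("  vanishing point at raster (%.1f, %.1f)\n",
                x$vp_raster[["u"]], x$vp_raster[["v"]]))
  invisible(x)
}

#' Vanishing point of the laser lines for a given pose
#'
#' Image coordinates of the point where the projections of the two parallel
#' laser lines converge, relative to the image centre:
#' vertical offset (positive up) \eqn{= \frac{M}{2}\tan\lambda/\tan(\alpha_V/2)},
#' horizontal offset (positive right)
#' \eqn{= -\frac{N}{2}\tan\gamma/(\tan(\alpha_H/2)\cos\lambda)}.
#' A horizontal, laser-aligned camera puts the vanishing point at the centre.
#'
#' @param pose A `laser_pose` object (from [estimate_pose()] or
#'   [laser_pose()]).
#' @param cam A [camera_intrinsics()] object.
#' @return Named numeric vector `vp_u`, `vp_v` (pixel offsets from centre;
#'   u rightward, v upward).
#' @export
vanishing_point <- function(pose, cam) {
  .assert_class(pose, "laser_pose", "pose")
  .assert_class(cam, "camera_intrinsics", "cam")
  c(vp_u = -pose$tan_pan / pose$cos_tilt * cam$width / (2 * cam$tan_h2),
    vp_v = pose$tan_tilt * cam$height / (2 * cam$tan_v2))
}
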