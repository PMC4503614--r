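#' Ground length of the laser-delimited trapezoid
#'
#' Length over the seafloor between the two reference rows:
#' \deqn{L = \left(\frac{n'}{n''}-1\right)\frac{N}{n'}
#'   \frac{l}{2\tan(\alpha_H/2)\cos\lambda\cos\gamma}}
#'
#' Under a nonzero pan this closed form returns, exactly, the separation of
#' the two reference ground lines measured along the camera's horizontal
#' forward axis (their perpendicular distance); the side of the ground
#' parallelogram measured along the laser lines is larger by a factor
#' \eqn{1/\cos\gamma}. The two coincide to first order in \eqn{\gamma}, and
#' at survey-typical pans (a few degrees) the difference is far below the
#' measurement uncertainty. Set `pan_exact = TRUE` to apply the extra
#' \eqn{1/\cos\gamma} and obtain the along-laser length, which is the exact
#' inverse of the pinhole forward model.
#'
#' @param meas An [image_measurements()] object.
#' @param cam A [camera_intrinsics()] object.
#' @param rig A [laser_rig()] object.
#' @param pose A `laser_pose`; computed from `meas` when omitted.
#' @param pan_exact Apply the second-order pan factor (default `FALSE`,
#'   the plain closed form).
#' @return Ground length L in cm.
#' @examples
#' cam <- camera_intrinsics(50.43, 29.67, 1280, 800)
#' rig <- laser_rig(67)
#' meas <- image_measurements(312, 232, 465, 52, 29, 367, 143)
#' ground_length(meas, cam, rig)
#' @export
ground_length <- function(meas, cam, rig, pose = NULL, pan_exact = FALSE) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  if (is.null(pose)) pose <- estimate_pose(meas, cam)
  if (abs(meas$n_prime - meas$n_dprime) < 0.5)
    stop("rows too close: |n' - n''| < 0.5 px, length not resolvable",
         call. = FALSE)
  L <- (meas$n_prime / meas$n_dprime - 1) * (cam$width / meas$n_prime) *
    rig$l / (2 * cam$tan_h2 * pose$cos_tilt * pose$cos_pan)
  if (pan_exact) L <- L / pose$cos_pan
  L
}

#' Ground area of the laser-delimited trapezoid
#'
#' The image trapezoid bounded by the two laser lines and the two reference
#' rows corresponds to a ground rectangle (no pan) or parallelogram (with
#' pan) whose area is \eqn{S = L \times l}.
#'
#' @inheritParams ground_length
#' @return Ground area S in cm^2.
#' @export
ground_area <- function(meas, cam, rig, pose = NULL, pan_exact = FALSE) {
  ground_length(meas, cam, rig, pose, pan_exact) * rig$l
}

#' Perspective cotangents of the projected laser lines
#'
#' Cotangents of the angles the two projected laser lines make in the
#' physically scaled image plane, measured from the vertical through the
#' vanishing point:
#' \deqn{\cot\theta_i = \frac{n_i}{N}\frac{M}{m}
#'   \frac{\tan(\alpha_H/2)}{\tan(\alpha_V/2)}}
#' The aspect factor converts the pixel slope \eqn{n_i/m} to the physical
#' image plane, where angles are true. These encode the camera height.
#'
#' @inheritParams ground_length
#' @return Named numeric vector `cot_theta1`, `cot_theta2`.
#' @export
perspective_cotangents <- function(meas, cam) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  if (meas$m <= 0) stop("`m` must be positive", call. = FALSE)
  k <- (cam$height / meas$m) * cam$tan_h2 / cam$tan_v2 / cam$width
  c(cot_theta1 = meas$n1 * k, cot_theta2 = meas$n2 * k)
}

#' Camera height above the seabed
#'
#' Vertical distance from the camera to the ground plane:
#' \deqn{h = \frac{\cos\lambda\,\cos\gamma\, l}{\cot\theta_1 + \cot\theta_2}}
#'
#' Under a nonzero pan the plain closed form carries an exact factor
#' \eqn{\cos^2\gamma} relative to the true height of the pinhole model
#' (negligible at survey-typical pans); `pan_exact = TRUE` replaces
#' \eqn{\cos\gamma} by \eqn{1/\cos\gamma}, which inverts the forward model
#' exactly.
#'
#' @inheritParams ground_length
#' @return Camera height h in cm.
#' @examples
#' cam <- camera_intrinsics(50.43, 29.67, 1280, 800)
#' rig <- laser_rig(67)
#' meas <- image_measurements(312, 232, 465, 52, 29, 367, 143)
#' camera_height(meas, cam, rig)
#' @export
camera_height <- function(meas, cam, rig, pose = NULL, pan_exact = FALSE) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  if (is.null(pose)) pose <- estimate_pose(meas, cam)
  ct <- perspective_cotangents(meas, cam)
  s <- ct[["cot_theta1"]] + ct[["cot_theta2"]]
  if (s <= 0)
    stop("laser lines parallel in image; height undefined", call. = FALSE)
  pan_fac <- if (pan_exact) 1 / pose$cos_pan else pose$cos_pan
  pose$cos_tilt * pan_fac * rig$l / s
}

#' Ground length for a horizontal, laser-aligned camera
#'
#' Special case of [ground_length()] with zero tilt and pan:
#' \deqn{L = \left(\frac{n'}{n''}-1\right)\frac{N}{n'}
#'   \frac{l}{2\tan(\alpha_H/2)}}
#'
#' @param n_prime,n_dprime Laser-line separations (pixels) at the near and
#'   far reference row; `n_prime > n_dprime > 0`.
#' @param cam A [camera_intrinsics()] object.
#' @param rig A [laser_rig()] object.
#' @return Ground length L in cm.
#' @export
ground_length_simple <- function(n_prime, n_dprime, cam, rig) {
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  if (n_dprime <= 0 || n_prime < n_dprime)
    stop("far row must be narrower than near row (n_prime >= n_dprime > 0)",
         call. = FALSE)
  (n_prime / n_dprime - 1) * (cam$width / n_prime) *
    rig$l / (2 * cam$tan_h2)
}

#' Ground area for a horizontal, laser-aligned camera
#'
#' @inheritParams ground_length_simple
#' @return Ground area S = L * l in cm^2.
#' @export
ground_area_simple <- function(n_prime, n_dprime, cam, rig) {
  ground_length_simple(n_prime, n_dprime, cam, rig) * rig$l
}

#' Camera height for a horizontal, laser-aligned camera
#'
#' With a horizontal camera the height follows from the vertical image-plane
#' offset of the near row and the laser separation at that row:
#' \eqn{h = (-z_{A'} / l')\, l}. Both pixel lengths must be on the *same*
#' image-plane scale; pass `cam` to convert a vertical pixel offset to the
#' horizontal pixel scale (multiplies by
#' \eqn{N\tan(\alpha_V/2) / (M\tan(\alpha_H/2))}).
#'
#' @param z_a_px Signed vertical pixel offset of the near row relative to the
#'   image centre, positive up (so a row below centre is negative).
#' @param l_prime_px Laser-line separation at that row, horizontal pixels
#'   (> 0).
#' @param rig A [laser_rig()] object.
#' @param cam Optional [camera_intrinsics()]; when given, `z_a_px` is taken
#'   as raw vertical pixels and converted to the horizontal scale.
#' @return Camera height h in cm.
#' @export
camera_height_simple <- function(z_a_px, l_prime_px, rig, cam = NULL) {
  .assert_class(rig, "laser_rig", "rig")
  if (l_prime_px <= 0) stop("`l_prime_px` must be positive", call. = FALSE)
  if (!is.null(cam)) {
    .assert_class(cam, "camera_intrinsics", "cam")
    z_a_px <- z_a_px * (cam$width * cam$tan_v2) / (cam$height * cam$tan_h2)
  }
  (-z_a_px / l_prime_px) * rig$l
}

#' Seabed slope from apparent and true camera tilt
#'
#' Over a sloping seabed the tilt recovered from the imagery is the apparent
#' tilt, the sum of the camera's true downward tilt and the ground slope
#' (when the laser lines run along the slope). Hence
#' \eqn{\alpha = \lambda - \lambda_0}.
#'
#' @param apparent_tilt_deg Apparent tilt from [estimate_pose()], degrees.
#' @param true_tilt_deg True camera tilt from an external attitude sensor,
#'   degrees.
#' @return Seabed slope in degrees (positive = ground rising away from the
#'   camera).
#' @export
seabed_slope <- function(apparent_tilt_deg, true_tilt_deg) {
  stopifnot(is.numeric(apparent_tilt_deg), is.numeric(true_tilt_deg))
  apparent_tilt_deg - true_tilt_deg
}
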