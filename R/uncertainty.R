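#' Maximal relative uncertainty of the tilt cosine
#'
#' First-order maximal (absolute-sum) propagation of one-pixel measurement
#' errors into \eqn{\cos\lambda}:
#' \deqn{\frac{\Delta\cos\lambda}{\cos\lambda} =
#'   \left|\frac{m_0}{M}-\frac12+\frac{n'}{n_1+n_2}\frac{m}{M}\right|
#'   \left[2\tan(\alpha_V/2)\cos\lambda\right]^2
#'   \left[\frac{1+n'/(n_1+n_2)}{M} +
#'         \frac{1+2n'/(n_1+n_2)}{n_1+n_2}\right]}
#' (each resolution term scaled by the assumed pixel error).
#'
#' @param meas An [image_measurements()] object.
#' @param cam A [camera_intrinsics()] object.
#' @param errors A [measurement_errors()] object.
#' @return Dimensionless relative uncertainty (>= 0).
#' @export
rel_unc_cos_tilt <- function(meas, cam, errors = measurement_errors()) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(errors, "measurement_errors", "errors")
  r <- meas$n_prime / (meas$n1 + meas$n2)
  bracket <- meas$m0 / cam$height - 0.5 + r * meas$m / cam$height
  t <- tilt_from_measurements(meas, cam)
  abs(bracket) * (2 * cam$tan_v2 * t$cos_tilt)^2 *
    errors$pixel_error *
    ((1 + r) / cam$height + (1 + 2 * r) / (meas$n1 + meas$n2))
}

#' Maximal relative uncertainty of the pan cosine
#'
#' Absolute-sum propagation into \eqn{\cos\gamma}, including the nested
#' contribution of the tilt-cosine uncertainty:
#' \deqn{\frac{\Delta\cos\gamma}{\cos\gamma} =
#'   \left[2\tan(\alpha_H/2)\cos\lambda\cos\gamma\right]^2 |B_\gamma|
#'   \left\{\left[1+\left(1+\frac{2n_1}{n_1+n_2}\right)
#'   \frac{n'}{n_1+n_2}\right]\frac1N +
#'   |B_\gamma|\,\frac{\Delta\cos\lambda}{\cos\lambda}\right\}}
#' where \eqn{B_\gamma = 1/2 - n_0/N - n_1 n'/((n_1+n_2)N)}.
#'
#' @inheritParams rel_unc_cos_tilt
#' @param cos_tilt,cos_pan Optional precomputed pose cosines.
#' @param ruc_tilt Optional precomputed [rel_unc_cos_tilt()] value.
#' @return Dimensionless relative uncertainty (>= 0).
#' @export
rel_unc_cos_pan <- function(meas, cam, errors = measurement_errors(),
                            cos_tilt = NULL, cos_pan = NULL,
                            ruc_tilt = NULL) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(errors, "measurement_errors", "errors")
  if (is.null(cos_tilt) || is.null(cos_pan)) {
    pose <- estimate_pose(meas, cam)
    cos_tilt <- pose$cos_tilt
    cos_pan <- pose$cos_pan
  }
  if (is.null(ruc_tilt)) ruc_tilt <- rel_unc_cos_tilt(meas, cam, errors)
  f1 <- meas$n1 / (meas$n1 + meas$n2)
  bracket <- abs(0.5 - meas$n0 / cam$width -
                   f1 * meas$n_prime / cam$width)
  inner <- (1 + (1 + 2 * f1) * meas$n_prime / (meas$n1 + meas$n2)) *
    errors$pixel_error / cam$width + bracket * ruc_tilt
  (2 * cam$tan_h2 * cos_tilt * cos_pan)^2 * bracket * inner
}

#' Maximal relative uncertainty of the ground length
#'
#' \deqn{\frac{\Delta L}{L} =
#'   \left(\frac{n''}{n'}+\frac{n'}{n''}\right)\frac{1}{n'-n''} +
#'   \frac{\Delta\cos\gamma}{\cos\gamma} +
#'   \frac{\Delta\cos\lambda}{\cos\lambda} + \frac{\Delta l}{l}}
#' This is the exact absolute-sum first-order propagation of the length
#' closed form with one-pixel row-separation errors.
#'
#' @inheritParams rel_unc_cos_tilt
#' @param rig A [laser_rig()] object (supplies `l` and its uncertainty).
#' @param ruc_pan,ruc_tilt Optional precomputed cosine relative
#'   uncertainties.
#' @return Dimensionless relative uncertainty; multiply by L for
#'   \eqn{\Delta L}.
#' @export
rel_unc_length <- function(meas, cam, rig, errors = measurement_errors(),
                           ruc_pan = NULL, ruc_tilt = NULL) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(rig, "laser_rig", "rig")
  if (is.null(ruc_tilt)) ruc_tilt <- rel_unc_cos_tilt(meas, cam, errors)
  if (is.null(ruc_pan))
    ruc_pan <- rel_unc_cos_pan(meas, cam, errors, ruc_tilt = ruc_tilt)
  np <- meas$n_prime
  nd <- meas$n_dprime
  (nd / np + np / nd) * errors$pixel_error / (np - nd) +
    ruc_pan + ruc_tilt + .delta_l(errors, rig) / rig$l
}

#' Maximal relative uncertainty of the ground area
#'
#' Identical to [rel_unc_length()] except the laser-separation term enters
#' twice (the area is L times l):
#' \eqn{\Delta S/S = \Delta L/L + \Delta l/l} exactly.
#'
#' @inheritParams rel_unc_length
#' @return Dimensionless relative uncertainty; multiply by S for
#'   \eqn{\Delta S}.
#' @export
rel_unc_area <- function(meas, cam, rig, errors = measurement_errors(),
                         ruc_pan = NULL, ruc_tilt = NULL) {
  rel_unc_length(meas, cam, rig, errors, ruc_pan, ruc_tilt) +
    .delta_l(errors, rig) / rig$l
}

#' Maximal relative uncertainty of the camera height
#'
#' \deqn{\frac{\Delta h}{h} = \frac1m + \frac{2}{n_1+n_2} +
#'   \frac{\Delta\cos\gamma}{\cos\gamma} +
#'   \frac{\Delta\cos\lambda}{\cos\lambda} + \frac{\Delta l}{l}}
#' The first two terms are the exact absolute-sum propagation of one-pixel
#' errors in the line-slope measurements (`m`, `n1`, `n2`); note the height
#' depends on the line slopes only, not on the row separations.
#'
#' @inheritParams rel_unc_length
#' @return Dimensionless relative uncertainty; multiply by h for
#'   \eqn{\Delta h}.
#' @export
rel_unc_height <- function(meas, cam, rig, errors = measurement_errors(),
                           ruc_pan = NULL, ruc_tilt = NULL) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(rig, "laser_rig", "rig")
  if (is.null(ruc_tilt)) ruc_tilt <- rel_unc_cos_tilt(meas, cam, errors)
  if (is.null(ruc_pan))
    ruc_pan <- rel_unc_cos_pan(meas, cam, errors, ruc_tilt = ruc_tilt)
  errors$pixel_error / meas$m +
    2 * errors$pixel_error / (meas$n1 + meas$n2) +
    ruc_pan + ruc_tilt + .delta_l(errors, rig) / rig$l
}
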