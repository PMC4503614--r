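#' Full single-image estimate with uncertainties
#'
#' Runs the complete pipeline on one measurement set: camera pose from the
#' vanishing point, ground length and area of the laser-delimited trapezoid,
#' camera height, optional seabed slope, and maximal first-order
#' uncertainties for all of them. One image in, one estimate out.
#'
#' @param meas An [image_measurements()] object.
#' @param cam A [camera_intrinsics()] object.
#' @param rig A [laser_rig()] object.
#' @param errors A [measurement_errors()] object.
#' @param true_tilt_deg Optional externally measured camera tilt (degrees);
#'   when given, the seabed slope `apparent - true` is reported.
#' @param pan_exact Use the exact-pan variants of the length and height
#'   estimators (see [ground_length()]); default `FALSE`.
#' @return An object of class `laser_estimate` with components `pose`,
#'   `length_L`, `area_S`, `height_h`, `cot_theta1`, `cot_theta2`,
#'   `delta_L`, `delta_S`, `delta_h`, relative uncertainties, optional
#'   `slope_deg`, and an echo of all inputs.
#' @examples
#' cam <- camera_intrinsics(50.43, 29.67, 1280, 800)
#' rig <- laser_rig(67, delta_l = 0.5)
#' meas <- image_measurements(312, 232, 465, 52, 29, 367, 143)
#' laser_estimate(meas, cam, rig)
#' @export
laser_estimate <- function(meas, cam, rig, errors = measurement_errors(),
                           true_tilt_deg = NULL, pan_exact = FALSE) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  .assert_class(errors, "measurement_errors", "errors")
  pose <- estimate_pose(meas, cam)
  L <- ground_length(meas, cam, rig, pose, pan_exact)
  S <- L * rig$l
  h <- camera_height(meas, cam, rig, pose, pan_exact)
  ct <- perspective_cotangents(meas, cam)
  ruc_tilt <- rel_unc_cos_tilt(meas, cam, errors)
  ruc_pan <- rel_unc_cos_pan(meas, cam, errors,
                             cos_tilt = pose$cos_tilt,
                             cos_pan = pose$cos_pan, ruc_tilt = ruc_tilt)
  rL <- rel_unc_length(meas, cam, rig, errors, ruc_pan, ruc_tilt)
  rS <- rel_unc_area(meas, cam, rig, errors, ruc_pan, ruc_tilt)
  rh <- rel_unc_height(meas, cam, rig, errors, ruc_pan, ruc_tilt)
  out <- structure(
    list(pose = pose,
         length_L = L, area_S = S, height_h = h,
         cot_theta1 = ct[["cot_theta1"]], cot_theta2 = ct[["cot_theta2"]],
         rel_unc_cos_tilt = ruc_tilt, rel_unc_cos_pan = ruc_pan,
         rel_unc_L = rL, rel_unc_S = rS, rel_unc_h = rh,
         delta_L = rL * L, delta_S = rS * S, delta_h = rh * h,
         slope_deg = if (!is.null(true_tilt_deg))
           seabed_slope(pose$tilt_deg, true_tilt_deg) else NULL,
         true_tilt_deg = true_tilt_deg,
         pan_exact = pan_exact,
         inputs = list(measurements = meas, camera = cam, rig = rig,
                       errors = errors)),
    class = "laser_estimate")
  out
}

#' @export
print.laser_estimate <- function(x, ...) {
  cat("<laser_estimate>\n")
  cat(sprintf("  tilt  lambda = %6.2f deg   pan gamma = %6.2f deg\n",
              x$pose$tilt_deg, x$pose$pan_deg))
  cat(sprintf("  length L = %.1f +/- %.1f cm\n", x$length_L, x$delta_L))
  cat(sprintf("  area   S = %.0f +/- %.0f cm^2\n", x$area_S, x$delta_S))
  cat(sprintf("  height h = %.1f +/- %.1f cm\n", x$height_h, x$delta_h))
  if (!is.null(x$slope_deg))
    cat(sprintf("  seabed slope = %.2f deg (true tilt %.2f deg)\n",
                x$slope_deg, x$true_tilt_deg))
  invisible(x)
}

#' Flatten a laser estimate to a one-row data frame
#'
#' @param x A `laser_estimate`.
#' @param ... Unused.
#' @return A one-row `data.frame` with all scalar outputs and input echoes.
#' @export
as.data.frame.laser_estimate <- function(x, ...) {
  m <- x$inputs$measurements
  cam <- x$inputs$camera
  rig <- x$inputs$rig
  data.frame(
    length_L_cm = x$length_L, delta_L_cm = x$delta_L,
    area_S_cm2 = x$area_S, delta_S_cm2 = x$delta_S,
    height_h_cm = x$height_h, delta_h_cm = x$delta_h,
    tilt_deg = x$pose$tilt_deg, pan_deg = x$pose$pan_deg,
    cos_tilt = x$pose$cos_tilt, cos_pan = x$pose$cos_pan,
    vp_u = x$pose$vp_u, vp_v = x$pose$vp_v,
    cot_theta1 = x$cot_theta1, cot_theta2 = x$cot_theta2,
    rel_unc_cos_tilt = x$rel_unc_cos_tilt,
    rel_unc_cos_pan = x$rel_unc_cos_pan,
    slope_deg = if (is.null(x$slope_deg)) NA_real_ else x$slope_deg,
    true_tilt_deg = if (is.null(x$true_tilt_deg)) NA_real_
                    else x$true_tilt_deg,
    pan_exact = x$pan_exact,
    n_prime = m$n_prime, n_dprime = m$n_dprime, n0 = m$n0,
    n1 = m$n1, n2 = m$n2, m0 = m$m0, m = m$m,
    alpha_h_deg = cam$alpha_h, alpha_v_deg = cam$alpha_v,
    image_width_px = cam$width, image_height_px = cam$height,
    laser_separation_cm = rig$l, laser_separation_sigma_cm = rig$delta_l,
    pixel_error_px = x$inputs$errors$pixel_error)
}

#' Write an estimate report to JSON or CSV
#'
#' Reports echo every input value and the package version so published area
#' estimates are reproducible.
#'
#' @param est A `laser_estimate`.
#' @param path Output file path.
#' @param format `"json"` (structured) or `"csv"` (flat, one row); guessed
#'   from the file extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_report <- function(est, path, format = NULL) {
  .assert_class(est, "laser_estimate", "est")
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(est), path, row.names = FALSE)
  } else {
    m <- est$inputs$measurements
    cam <- est$inputs$camera
    rig <- est$inputs$rig
    rep <- list(
      tool = "laserquad",
      version = as.character(utils::packageVersion("laserquad")),
      estimates = list(
        length_L_cm = est$length_L, delta_L_cm = est$delta_L,
        area_S_cm2 = est$area_S, delta_S_cm2 = est$delta_S,
        height_h_cm = est$height_h, delta_h_cm = est$delta_h),
      pose = list(
        tilt_deg = est$pose$tilt_deg, pan_deg = est$pose$pan_deg,
        cos_tilt = est$pose$cos_tilt, cos_pan = est$pose$cos_pan,
        vp_u = est$pose$vp_u, vp_v = est$pose$vp_v,
        cot_theta1 = est$cot_theta1, cot_theta2 = est$cot_theta2,
        rel_unc_cos_tilt = est$rel_unc_cos_tilt,
        rel_unc_cos_pan = est$rel_unc_cos_pan),
      slope_deg = est$slope_deg,
      true_tilt_deg = est$true_tilt_deg,
      pan_exact = est$pan_exact,
      inputs = list(
        measurements = list(n_prime = m$n_prime, n_dprime = m$n_dprime,
                            n0 = m$n0, n1 = m$n1, n2 = m$n2,
                            m0 = m$m0, m = m$m),
        camera = list(alpha_h_deg = cam$alpha_h, alpha_v_deg = cam$alpha_v,
                      image_width_px = cam$width,
                      image_height_px = cam$height),
        rig = list(laser_separation_cm = rig$l,
                   laser_separation_sigma_cm = rig$delta_l),
        pixel_error_px = est$inputs$errors$pixel_error))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}
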