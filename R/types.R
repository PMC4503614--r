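#' Camera intrinsics for an uncropped, distortion-free still image
#'
#' Bundles the two angles of view and the pixel grid of the camera. These are
#' the only camera parameters the method needs: all equations use ratios of
#' pixel counts, so the physical sensor width cancels and never has to be
#' known.
#'
#' @param alpha_h Horizontal angle of view, degrees, in (0, 180).
#' @param alpha_v Vertical angle of view, degrees, in (0, 180).
#' @param width Image width in pixels (>= 2).
#' @param height Image height in pixels (>= 2).
#'
#' @return An object of class `camera_intrinsics` with fields `alpha_h`,
#'   `alpha_v` (degrees), `width`, `height` (pixels) and the precomputed
#'   half-angle tangents `tan_h2`, `tan_v2`.
#' @examples
#' camera_intrinsics(50.43, 29.67, 1280, 800)
#' @export
camera_intrinsics <- function(alpha_h, alpha_v, width, height) {
  stopifnot(is.numeric(alpha_h), length(alpha_h) == 1L, is.finite(alpha_h),
            is.numeric(alpha_v), length(alpha_v) == 1L, is.finite(alpha_v),
            is.numeric(width), length(width) == 1L,
            is.numeric(height), length(height) == 1L)
  if (alpha_h <= 0 || alpha_h >= 180)
    stop("`alpha_h` must be in (0, 180) degrees", call. = FALSE)
  if (alpha_v <= 0 || alpha_v >= 180)
    stop("`alpha_v` must be in (0, 180) degrees", call. = FALSE)
  if (width < 2 || height < 2)
    stop("image dimensions must be at least 2 pixels", call. = FALSE)
  structure(
    list(alpha_h = alpha_h, alpha_v = alpha_v,
         width = as.numeric(width), height = as.numeric(height),
         tan_h2 = tan(alpha_h * pi / 360), tan_v2 = tan(alpha_v * pi / 360)),
    class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %g x %g px, angles of view %g x %g deg\n",
              x$width, x$height, x$alpha_h, x$alpha_v))
  invisible(x)
}

#' Two-parallel-laser rig geometry
#'
#' Describes the pair of sheet lasers rigidly mounted to the vehicle frame:
#' the ground separation `l` of the two projected lines, its calibration
#' uncertainty, and optionally the individual offsets of the optical-axis
#' ground track from each line (only the forward model needs those; the
#' estimators use `l` alone).
#'
#' @param l Separation of the two laser lines on the ground, cm (> 0).
#' @param delta_l Uncertainty of `l`, cm (>= 0). Defaults to 0.5 cm, a typical
#'   calibration tolerance for frame-mounted line lasers.
#' @param l1,l2 Optional offsets (cm) of the left and right line from the
#'   ground track of the optical axis; must satisfy `l1 + l2 == l`. Default is
#'   a centred rig (`l/2` each).
#'
#' @return An object of class `laser_rig`.
#' @examples
#' laser_rig(67)
#' @export
laser_rig <- function(l, delta_l = 0.5, l1 = NULL, l2 = NULL) {
  stopifnot(is.numeric(l), length(l) == 1L, is.finite(l),
            is.numeric(delta_l), length(delta_l) == 1L, is.finite(delta_l))
  if (l <= 0) stop("laser separation `l` must be positive", call. = FALSE)
  if (delta_l < 0) stop("`delta_l` must be non-negative", call. = FALSE)
  if (is.null(l1) != is.null(l2))
    stop("give both `l1` and `l2`, or neither", call. = FALSE)
  if (is.null(l1)) {
    l1 <- l / 2
    l2 <- l / 2
  } else if (abs(l1 + l2 - l) > 1e-9 * l) {
    stop("`l1 + l2` must equal `l`", call. = FALSE)
  }
  structure(list(l = l, delta_l = delta_l, l1 = l1, l2 = l2),
            class = "laser_rig")
}

#' @export
print.laser_rig <- function(x, ...) {
  cat(sprintf("<laser_rig> l = %g +/- %g cm (l1 = %g, l2 = %g)\n",
              x$l, x$delta_l, x$l1, x$l2))
  invisible(x)
}

#' Pixel measurements of the projected laser lines in one still image
#'
#' The seven pixel quantities read off a single image that the estimators
#' consume. Two horizontal reference rows cut the two laser lines; the image
#' trapezoid they bound corresponds to a ground rectangle (no pan) or
#' parallelogram (with pan).
#'
#' Conventions (raster origin top-left, u rightward, v downward, real-valued
#' coordinates):
#' * `n_prime`, `n_dprime`: horizontal separation of the two lines at the
#'   near (lower) and far (upper) reference row.
#' * `n0`: horizontal distance from the left image edge to the left line at
#'   the near row.
#' * `m0`: vertical distance from the *bottom* image edge to the near row
#'   (the near row sits at raster `v = height - m0`). This convention makes
#'   the tilt estimator an exact inverse of the pinhole projection at any row
#'   position.
#' * `n1`, `n2`: horizontal distances from the vertical through the vanishing
#'   point to the left and right line, at a row `m` pixels below the
#'   vanishing point. Only the ratios `n1/m`, `n2/m` (the line slopes) enter
#'   the estimators, so any row below the vanishing point may be used; the
#'   uncertainty formulas, however, inherit the chosen row.
#'
#' `n1` or `n2` may be (slightly) negative when a strong pan pushes the
#' vanishing vertical outside the pair of lines; their sum must be positive.
#'
#' @param n_prime,n_dprime,n0,n1,n2,m0,m Pixel quantities as above.
#' @return An object of class `image_measurements`.
#' @examples
#' image_measurements(n_prime = 312, n_dprime = 232, n0 = 465,
#'                    n1 = 52, n2 = 29, m0 = 367, m = 143)
#' @export
image_measurements <- function(n_prime, n_dprime, n0, n1, n2, m0, m) {
  vals <- c(n_prime = n_prime, n_dprime = n_dprime, n0 = n0,
            n1 = n1, n2 = n2, m0 = m0, m = m)
  if (!all(is.finite(vals)))
    stop("all measurements must be finite numbers", call. = FALSE)
  if (n_dprime <= 0)
    stop("`n_dprime` must be positive", call. = FALSE)
  if (n_prime <= n_dprime)
    stop("far row must be narrower than near row (n_prime > n_dprime)",
         call. = FALSE)
  if (m <= 0) stop("`m` must be positive", call. = FALSE)
  if (n1 + n2 <= 0)
    stop("vanishing point undefined: n1 + n2 must be positive", call. = FALSE)
  if (n0 < 0 || m0 < 0)
    stop("`n0` and `m0` must be non-negative", call. = FALSE)
  structure(as.list(vals), class = "image_measurements")
}

#' @export
print.image_measurements <- function(x, ...) {
  cat("<image_measurements> (pixels)\n")
  cat(sprintf("  n' = %g  n'' = %g  n0 = %g  m0 = %g\n",
              x$n_prime, x$n_dprime, x$n0, x$m0))
  cat(sprintf("  n1 = %g  n2 = %g  m = %g\n", x$n1, x$n2, x$m))
  invisible(x)
}

#' @export
as.data.frame.image_measurements <- function(x, ...) {
  data.frame(n_prime = x$n_prime, n_dprime = x$n_dprime, n0 = x$n0,
             n1 = x$n1, n2 = x$n2, m0 = x$m0, m = x$m)
}

#' Measurement error model for uncertainty propagation
#'
#' The propagation formulas assume a maximal error per pixel measurement
#' (reading a line position in an image analysis tool is good to about one
#' pixel) and the calibration uncertainty of the laser separation.
#'
#' @param pixel_error Maximal error of each pixel quantity, pixels (default 1).
#' @param delta_l Uncertainty of the laser separation, cm; if `NULL`, taken
#'   from the rig at propagation time.
#' @return An object of class `measurement_errors`.
#' @export
measurement_errors <- function(pixel_error = 1, delta_l = NULL) {
  stopifnot(is.numeric(pixel_error), length(pixel_error) == 1L,
            is.finite(pixel_error), pixel_error >= 0)
  if (!is.null(delta_l))
    stopifnot(is.numeric(delta_l), length(delta_l) == 1L, delta_l >= 0)
  structure(list(pixel_error = pixel_error, delta_l = delta_l),
            class = "measurement_errors")
}

.delta_l <- function(errors, rig) {
  if (!is.null(errors$delta_l)) errors$delta_l else rig$delta_l
}

.assert_class <- function(x, cls, arg) {
  if (!inherits(x, cls))
    stop(sprintf("`%s` must be a <%s> object", arg, cls), call. = FALSE)
  invisible(x)
}
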