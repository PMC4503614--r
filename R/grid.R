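#' Equal-ground-area grid overlay
#'
#' Constructs image line segments that correspond to an equal-area grid on
#' the seafloor, using the two laser lines as the natural scale (an
#' adaptation of the Canadian-grid idea with the vanishing point taking the
#' role of the optical centre).
#'
#' Lateral grid lines are virtual laser lines: they pass through the
#' vanishing point, at ground offsets `k * lateral_spacing` from the left
#' laser line; their image slope is interpolated (and extrapolated)
#' linearly in the perspective cotangent between the two laser lines, which
#' is exact for the pinhole model. Transversal grid rows are horizontal
#' image rows placed so that successive ground separations, obtained by
#' inverting the length closed form, all equal `axial_spacing`; the
#' reciprocal distance of a row from the vanishing point is affine in
#' ground distance, so rows follow in closed form from the near reference
#' row.
#'
#' @param meas An [image_measurements()] object (supplies the laser-line
#'   geometry and the near reference row).
#' @param cam A [camera_intrinsics()] object.
#' @param rig A [laser_rig()] object.
#' @param pose Optional precomputed `laser_pose`.
#' @param lateral_spacing Ground spacing of the lateral lines, cm (> 0).
#' @param axial_spacing Ground spacing of the transversal rows, cm (> 0).
#' @param lateral_range Integer multiples of `lateral_spacing` (offsets
#'   from the left laser line) to draw; default `0:ceiling(l/spacing)`
#'   spans the laser pair.
#' @param axial_range Integer multiples of `axial_spacing` away from the
#'   near reference row (positive = away from the camera).
#' @param pan_exact Use the exact-pan length convention when spacing the
#'   rows (see [ground_length()]).
#' @return A list with `laterals` and `axials` (data frames of segment
#'   endpoints `u1, v1, u2, v2` plus the ground offset/distance of each
#'   line) and `vp_raster`.
#' @export
ground_grid_overlay <- function(meas, cam, rig, pose = NULL,
                                lateral_spacing, axial_spacing,
                                lateral_range = NULL, axial_range = 0:5,
                                pan_exact = FALSE) {
  .assert_class(meas, "image_measurements", "meas")
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  stopifnot(lateral_spacing > 0, axial_spacing > 0)
  if (is.null(pose)) pose <- estimate_pose(meas, cam)
  u_vp <- pose$vp_raster[["u"]]
  v_vp <- pose$vp_raster[["v"]]
  v_near <- cam$height - meas$m0         # near reference row
  if (v_near <= v_vp)
    stop("degenerate pose: near row at or above the vanishing point",
         call. = FALSE)
  if (is.null(lateral_range)) lateral_range <- 0:ceiling(rig$l / lateral_spacing)

  # image slope (du/dv below the vanishing point) is affine in ground offset
  s_left <- -meas$n1 / meas$m
  s_right <- meas$n2 / meas$m
  slope_at <- function(d_cm) s_left + (s_right - s_left) * d_cm / rig$l
  v_bot <- cam$height - 1
  laterals <- do.call(rbind, lapply(lateral_range, function(k) {
    s <- slope_at(k * lateral_spacing)
    data.frame(k = k, ground_offset_cm = k * lateral_spacing,
               u1 = u_vp, v1 = v_vp,
               u2 = u_vp + s * (v_bot - v_vp), v2 = v_bot)
  }))

  # reciprocal row distance from the vanishing point is affine in ground y
  K <- rig$l / (2 * cam$tan_h2 * pose$cos_tilt * pose$cos_pan)
  if (pan_exact) K <- K / pose$cos_pan
  c_px <- meas$n_prime / (v_near - v_vp)   # line-pair width per pixel below vp
  A <- cam$width * K / c_px
  inv0 <- 1 / (v_near - v_vp)
  axials <- do.call(rbind, lapply(axial_range, function(k) {
    inv <- inv0 + k * axial_spacing / A
    if (inv <= 0) return(NULL)             # beyond the horizon
    v <- v_vp + 1 / inv
    ul <- u_vp + slope_at(min(lateral_range) * lateral_spacing) * (v - v_vp)
    ur <- u_vp + slope_at(max(lateral_range) * lateral_spacing) * (v - v_vp)
    data.frame(k = k, ground_distance_cm = k * axial_spacing,
               u1 = ul, v1 = v, u2 = ur, v2 = v)
  }))
  list(laterals = laterals, axials = axials,
       vp_raster = c(u = u_vp, v = v_vp))
}
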