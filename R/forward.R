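#' Ground-truth scene for the pinhole forward model
#'
#' Exact perspective model of the camera + two-laser rig over a (possibly
#' inclined) seabed, used as the simulation oracle and synthetic-fixture
#' generator. World frame: origin at the camera, x to the right along the
#' rig, y the horizontal projection of the laser direction, z up. The laser
#' sheets are the vertical planes `x = -l1` (left) and `x = +l2` (right);
#' the ground plane is `z = -h + y tan(slope)`, so positive slope rises away
#' from the camera and the laser lines run along the slope.
#'
#' The camera is panned by gamma about the vertical (positive = to the
#' right), then tilted down by lambda about its own horizontal axis; roll is
#' zero throughout. The image-plane distance never appears: pixel scales are
#' `N / (2 tan(alpha_H/2))` horizontally and `M / (2 tan(alpha_V/2))`
#' vertically per unit tangent.
#'
#' @param cam A [camera_intrinsics()] object.
#' @param rig A [laser_rig()] object (supplies `l1`, `l2`).
#' @param h Camera height above the ground at the camera position, cm (> 0).
#' @param tilt_deg Downward camera tilt lambda, degrees, in [0, 90).
#' @param pan_deg Signed pan gamma, degrees, in (-90, 90).
#' @param ground_slope_deg Seabed slope alpha, degrees (default 0).
#' @return An object of class `forward_scene`.
#' @examples
#' cam <- camera_intrinsics(50.43, 29.67, 1280, 800)
#' scn <- forward_scene(cam, laser_rig(67), h = 113,
#'                      tilt_deg = 18.9, pan_deg = -1.0)
#' @export
forward_scene <- function(cam, rig, h, tilt_deg, pan_deg,
                          ground_slope_deg = 0) {
  .assert_class(cam, "camera_intrinsics", "cam")
  .assert_class(rig, "laser_rig", "rig")
  stopifnot(is.numeric(h), length(h) == 1L, h > 0,
            tilt_deg >= 0, tilt_deg < 90, abs(pan_deg) < 90,
            abs(ground_slope_deg) < 90)
  lam <- tilt_deg * pi / 180
  gam <- pan_deg * pi / 180
  # rows: camera right, forward, up axes in world coordinates
  B <- rbind(
    r = c(cos(gam), -sin(gam), 0),
    f = c(sin(gam) * cos(lam), cos(gam) * cos(lam), -sin(lam)),
    u = c(sin(gam) * sin(lam), cos(gam) * sin(lam), cos(lam)))
  structure(list(cam = cam, rig = rig, h = h,
                 tilt_deg = tilt_deg, pan_deg = pan_deg,
                 ground_slope_deg = ground_slope_deg,
                 tan_slope = tan(ground_slope_deg * pi / 180),
                 basis = B),
            class = "forward_scene")
}

#' @export
print.forward_scene <- function(x, ...) {
  cat(sprintf(
    "<forward_scene> h = %g cm, tilt = %g deg, pan = %g deg, slope = %g deg\n",
    x$h, x$tilt_deg, x$pan_deg, x$ground_slope_deg))
  invisible(x)
}

# ground elevation under (x, y)
.ground_z <- function(scene, y) -scene$h + y * scene$tan_slope

#' Project ground points into the image
#'
#' Exact pinhole projection of points on the seabed plane into raster pixel
#' coordinates. Vectorised over `x` and `y`.
#'
#' @param scene A [forward_scene()] object.
#' @param x Lateral ground coordinate(s), cm (positive right).
#' @param y Axial horizontal ground coordinate(s), cm (must be positive, in
#'   front of the rig; points behind the camera are rejected).
#' @return A data frame with raster columns `u`, `v`.
#' @export
project_point <- function(scene, x, y) {
  .assert_class(scene, "forward_scene", "scene")
  stopifnot(length(x) == length(y) || length(x) == 1L || length(y) == 1L)
  P <- rbind(x, y, .ground_z(scene, y))
  p <- scene$basis %*% P
  if (any(p["f", ] <= 0))
    stop("point behind the camera (non-positive depth)", call. = FALSE)
  cam <- scene$cam
  data.frame(
    u = cam$width / 2 + p["r", ] / p["f", ] * cam$width / (2 * cam$tan_h2),
    v = cam$height / 2 - p["u", ] / p["f", ] * cam$height / (2 * cam$tan_v2))
}

#' Back-project a pixel onto the seabed plane
#'
#' Inverse of [project_point()]: intersects the viewing ray of a raster
#' pixel with the ground plane.
#'
#' @param scene A [forward_scene()] object.
#' @param u,v Raster pixel coordinates (vectorised).
#' @return A data frame with ground columns `x`, `y` (cm).
#' @export
ground_point_from_pixel <- function(scene, u, v) {
  .assert_class(scene, "forward_scene", "scene")
  cam <- scene$cam
  tx <- (u - cam$width / 2) * 2 * cam$tan_h2 / cam$width
  tz <- (cam$height / 2 - v) * 2 * cam$tan_v2 / cam$height
  d <- t(scene$basis) %*% rbind(tx, 1, tz)   # world ray directions
  denom <- d[3, ] - scene$tan_slope * d[2, ]
  if (any(denom >= 0))
    stop("ray does not meet the seabed (at or above the horizon)",
         call. = FALSE)
  s <- -scene$h / denom
  data.frame(x = s * d[1, ], y = s * d[2, ])
}

# raster u of the laser sheet x = x0 at raster row(s) v (exact, closed form)
.laser_u_at_row <- function(scene, x0, v) {
  cam <- scene$cam
  cv <- (cam$height / 2 - v) * 2 * cam$tan_v2 / cam$height
  B <- scene$basis
  # image-row plane normal u - cv * f, componentwise so v may be a vector
  w1 <- B["u", 1] - cv * B["f", 1]
  w2 <- B["u", 2] - cv * B["f", 2]
  w3 <- B["u", 3] - cv * B["f", 3]
  y <- (-x0 * w1 + scene$h * w3) / (w2 + scene$tan_slope * w3)
  z <- .ground_z(scene, y)
  pr <- B["r", 1] * x0 + B["r", 2] * y + B["r", 3] * z
  pf <- B["f", 1] * x0 + B["f", 2] * y + B["f", 3] * z
  unname(cam$width / 2 + pr / pf * cam$width / (2 * cam$tan_h2))
}

#' Project the two laser lines into the image
#'
#' Renders the ground traces of the two laser sheets between two axial
#' ground distances as straight image segments (with zero roll they are
#' exactly straight).
#'
#' @param scene A [forward_scene()] object.
#' @param y_near,y_far Axial ground distances (cm) of the segment endpoints,
#'   `0 < y_near < y_far`.
#' @return A list with [image_line()] components `left` (sheet `x = -l1`)
#'   and `right` (sheet `x = +l2`).
#' @export
render_laser_lines <- function(scene, y_near, y_far) {
  .assert_class(scene, "forward_scene", "scene")
  stopifnot(y_near > 0, y_far > y_near)
  seg <- function(x0) {
    a <- project_point(scene, x0, y_near)
    b <- project_point(scene, x0, y_far)
    image_line(a$u, a$v, b$u, b$v)
  }
  list(left = seg(-scene$rig$l1), right = seg(scene$rig$l2))
}

# round to integers, dithering exact halves with the active RNG
.quantize_px <- function(x) {
  lo <- floor(x)
  frac <- x - lo
  up <- frac > 0.5
  half <- abs(frac - 0.5) < 1e-12
  if (any(half))
    up[half] <- stats::runif(sum(half)) < 0.5
  lo + as.numeric(up)
}

#' Synthesise a measurement set from a scene
#'
#' Projects the laser lines, cuts them with two reference rows, and runs the
#' canonical annotation extractor, returning both the measurements and the
#' scene's analytic ground truth. With `quantize = TRUE` all seven pixel
#' quantities are rounded to integers (exact halves dithered randomly),
#' emulating integer-pixel readings from an image analysis tool.
#'
#' @param scene A [forward_scene()] object.
#' @param near_row_v,far_row_v Raster rows cutting both projected lines,
#'   `near_row_v > far_row_v`.
#' @param quantize Round pixel quantities to integers (default `FALSE`).
#' @param seed Optional integer seed for the dithering of exact halves.
#' @return A list with `measurements` ([image_measurements()]),
#'   `annotation` ([annotation_set()]) and `truth` (list with `L` the
#'   along-laser ground distance between the two rows' back-projections,
#'   `S = L * l`, `h` the perpendicular distance from the camera to the
#'   seabed plane, `tilt_deg` the apparent tilt `camera tilt + slope`, and
#'   `pan_deg`).
#' @export
synthesize_measurements <- function(scene, near_row_v, far_row_v,
                                    quantize = FALSE, seed = NULL) {
  .assert_class(scene, "forward_scene", "scene")
  stopifnot(near_row_v > far_row_v)
  cam <- scene$cam
  uln <- .laser_u_at_row(scene, -scene$rig$l1, near_row_v)
  urn <- .laser_u_at_row(scene, scene$rig$l2, near_row_v)
  ulf <- .laser_u_at_row(scene, -scene$rig$l1, far_row_v)
  urf <- .laser_u_at_row(scene, scene$rig$l2, far_row_v)
  ann <- annotation_set(image_line(uln, near_row_v, ulf, far_row_v),
                        image_line(urn, near_row_v, urf, far_row_v),
                        near_row_v, far_row_v, cam$width, cam$height)
  meas <- measurements_from_annotation(ann)
  if (quantize) {
    if (!is.null(seed)) set.seed(seed)
    q <- .quantize_px(c(meas$n_prime, meas$n_dprime, meas$n0,
                        meas$n1, meas$n2, meas$m0, meas$m))
    meas <- image_measurements(q[1], q[2], q[3], q[4], q[5], q[6], q[7])
  }
  # analytic truth: along-laser ground distance between the two row planes
  slope <- scene$ground_slope_deg * pi / 180
  yA <- ground_point_from_pixel(scene, uln, near_row_v)$y
  yB <- ground_point_from_pixel(scene, ulf, far_row_v)$y
  L <- (yB - yA) / cos(slope)
  truth <- list(L = L, S = L * scene$rig$l,
                h = scene$h * cos(slope),
                tilt_deg = scene$tilt_deg + scene$ground_slope_deg,
                pan_deg = scene$pan_deg)
  list(measurements = meas, annotation = ann, truth = truth)
}

#' Render a synthetic still image with green laser lines
#'
#' Draws the two projected laser lines as anti-aliased green stripes
#' (Gaussian cross-section) over a configurable seabed background, for
#' exercising the detection module. With a fixed seed the output is
#' bit-reproducible.
#'
#' @param scene A [forward_scene()] object.
#' @param path Optional PNG output path.
#' @param y_range Axial ground range (cm) over which the lines are drawn;
#'   default covers every image row below the horizon.
#' @param line_width_px Full width at half maximum of the stripe, pixels.
#' @param background `"flat"`, `"gradient"` or `"speckle"`.
#' @param line_intensity Peak green excess added by a stripe, in [0, 1].
#' @param seed Integer seed for the speckle background.
#' @return The `height x width x 3` RGB array in [0, 1], invisibly.
#' @export
render_synthetic_image <- function(scene, path = NULL, y_range = NULL,
                                   line_width_px = 3,
                                   background = c("flat", "gradient",
                                                  "speckle"),
                                   line_intensity = 0.8, seed = NULL) {
  .assert_class(scene, "forward_scene", "scene")
  background <- match.arg(background)
  cam <- scene$cam
  W <- as.integer(cam$width)
  H <- as.integer(cam$height)
  if (!is.null(seed)) set.seed(seed)
  img <- array(0, dim = c(H, W, 3))
  base <- c(0.10, 0.12, 0.14)                    # dark seabed grey-blue
  for (k in 1:3) img[, , k] <- base[k]
  if (background == "gradient") {
    g <- seq(0.7, 1.3, length.out = H)           # darker far field on top
    for (k in 1:3) img[, , k] <- img[, , k] * g
  } else if (background == "speckle") {
    sp <- matrix(stats::runif(H * W, -0.05, 0.05), H, W)
    for (k in 1:3) img[, , k] <- pmin(pmax(img[, , k] + sp, 0), 1)
  }
  # apparent pose locates the horizon row; lines exist below it
  pose <- laser_pose(scene$tilt_deg + scene$ground_slope_deg,
                     scene$pan_deg, cam)
  v_hor <- pose$vp_raster[["v"]]
  vv <- (0:(H - 1))
  ok <- vv > v_hor + 2
  if (!is.null(y_range)) {
    yy <- rep(NA_real_, H)
    yy[ok] <- ground_point_from_pixel(
      scene, rep(cam$width / 2, sum(ok)), vv[ok])$y
    ok <- ok & !is.na(yy) & yy >= y_range[1] & yy <= y_range[2]
  }
  sigma <- line_width_px / (2 * sqrt(2 * log(2)))
  half <- as.integer(ceiling(3 * sigma) + 1L)
  green <- matrix(0, H, W)
  for (x0 in c(-scene$rig$l1, scene$rig$l2)) {
    uc <- rep(NA_real_, H)
    uc[ok] <- .laser_u_at_row(scene, x0, vv[ok])
    draw <- which(ok & uc > -half & uc < W - 1 + half)
    if (!length(draw)) next
    # vectorised stamp: window of columns around each row's line centre
    offs <- (-half):half
    cols <- outer(floor(uc[draw]), offs, `+`)        # 0-based columns
    vals <- line_intensity *
      exp(-(cols - uc[draw])^2 / (2 * sigma^2))
    rows <- matrix(draw, nrow = length(draw), ncol = length(offs))
    keep <- cols >= 0 & cols <= W - 1L
    idx <- cbind(rows[keep], cols[keep] + 1L)
    green[idx] <- green[idx] + vals[keep]
  }
  img[, , 2] <- pmin(img[, , 2] + green, 1)
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
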