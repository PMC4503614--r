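# shared fixtures: the published validation still and seeded random scenes

paper_cam <- function() camera_intrinsics(50.43, 29.67, 1280, 800)
paper_rig <- function() laser_rig(67, delta_l = 0.5)
paper_meas <- function()
  image_measurements(n_prime = 312, n_dprime = 232, n0 = 465,
                     n1 = 52, n2 = 29, m0 = 367, m = 143)

# annotation reproducing the validation measurement set: lines with pixel
# slopes -52/143 and +29/143 through (465, 433) and (777, 433); the near
# row sits 367 px above the bottom edge of the 1280 x 800 raster
validation_annotation <- function() {
  left <- image_line(465, 433, 465 + 52, 433 - 143)
  right <- image_line(777, 433, 777 - 29, 433 - 143)
  v_vp <- 433 - 312 * 143 / 81
  far <- v_vp + 232 * 143 / 81           # row where the pair is 232 px wide
  annotation_set(left, right, near_row_v = 433, far_row_v = far,
                 width = 1280, height = 800)
}

# measurement set with exactly zero tilt and pan (both pose brackets vanish)
zero_pose_meas <- function(n_prime = 400, n_dprime = 200, n1 = 100,
                           n2 = 100, m = 100, N = 1000, M = 800) {
  m0 <- M / 2 - n_prime / (n1 + n2) * m
  n0 <- N / 2 - n1 / (n1 + n2) * n_prime
  image_measurements(n_prime, n_dprime, n0, n1, n2, m0, m)
}

random_scene <- function(cam = paper_cam(), paperlike = FALSE) {
  if (paperlike) {
    l <- 67
    f <- stats::runif(1, 0.4, 0.6)
    forward_scene(cam, laser_rig(l, 0.5, l1 = f * l, l2 = (1 - f) * l),
                  h = stats::runif(1, 80, 200),
                  tilt_deg = stats::runif(1, 10, 30),
                  pan_deg = stats::runif(1, -5, 5))
  } else {
    l <- stats::runif(1, 50, 80)
    f <- stats::runif(1, 0.35, 0.65)
    forward_scene(cam, laser_rig(l, 0.5, l1 = f * l, l2 = (1 - f) * l),
                  h = stats::runif(1, 50, 400),
                  tilt_deg = stats::runif(1, 2, 45),
                  pan_deg = stats::runif(1, -20, 20))
  }
}

# draw a random scene plus a synthesized measurement bundle with reference
# rows placed below the horizon; retries until the measurement invariants
# (e.g. left line inside the raster) hold
draw_bundle <- function(cam = paper_cam(), quantize = FALSE,
                        paperlike = FALSE) {
  repeat {
    scn <- random_scene(cam, paperlike)
    vh <- laser_pose(scn$tilt_deg + scn$ground_slope_deg, scn$pan_deg,
                     cam)$vp_raster[["v"]]
    M <- cam$height
    near <- vh + stats::runif(1, 0.55, 0.95) * (M - vh)
    far <- vh + stats::runif(1, 0.2, 0.45) * (M - vh)
    b <- tryCatch(synthesize_measurements(scn, near, far,
                                          quantize = quantize),
                  error = function(e) NULL)
    if (!is.null(b)) return(list(scene = scn, bundle = b))
  }
}
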