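# exact pinhole forward model: projection, synthesis, rendering

test_that("horizontal aligned camera projects by similar triangles", {
  cam <- paper_cam()
  rig <- laser_rig(67, l1 = 30, l2 = 37)
  scn <- forward_scene(cam, rig, h = 100, tilt_deg = 0, pan_deg = 0)
  for (y in c(200, 500, 1500)) {
    p <- project_point(scn, 30, y)
    expect_equal(p$u, cam$width / 2 + (cam$width / 2) * (30 / y) /
                   cam$tan_h2, tolerance = 1e-12)
    # optical-axis ground track projects to the centre column
    expect_equal(project_point(scn, 0, y)$u, cam$width / 2)
  }
})

test_that("projection and back-projection are inverse", {
  set.seed(3)
  for (i in 1:20) {
    scn <- random_scene()
    x <- runif(1, -40, 40)
    y <- runif(1, 100, 2000)
    p <- project_point(scn, x, y)
    g <- ground_point_from_pixel(scn, p$u, p$v)
    expect_equal(g$x, x, tolerance = 1e-9)
    expect_equal(g$y, y, tolerance = 1e-9)
  }
})

test_that("points behind the camera are rejected", {
  scn <- forward_scene(paper_cam(), laser_rig(67), h = 100,
                       tilt_deg = 10, pan_deg = 0)
  expect_error(project_point(scn, 0, -50), "behind")
})

test_that("rendered laser lines are straight and mirror-symmetric when
           aligned", {
  cam <- paper_cam()
  scn <- forward_scene(cam, laser_rig(67), h = 120, tilt_deg = 15,
                       pan_deg = 0)
  lines <- render_laser_lines(scn, 150, 1200)
  # a third sample on each sheet falls on the two-point line
  mid <- project_point(scn, -33.5, 400)
  expect_equal(laserquad:::line_u_at(lines$left, mid$v), mid$u,
               tolerance = 1e-9)
  # symmetric rig about the centre column
  ul <- laserquad:::line_u_at(lines$left, 700)
  ur <- laserquad:::line_u_at(lines$right, 700)
  expect_equal(ul - cam$width / 2, -(ur - cam$width / 2), tolerance = 1e-9)
})

test_that("unquantized synthesis inverts exactly; simple relation holds at
           zero pose", {
  cam <- paper_cam()
  rig <- laser_rig(67)
  scn <- forward_scene(cam, rig, h = 150, tilt_deg = 20, pan_deg = 5)
  b <- synthesize_measurements(scn, 700, 350)
  est <- laser_estimate(b$measurements, cam, rig, pan_exact = TRUE)
  expect_equal(est$pose$tilt_deg, 20, tolerance = 1e-9)
  expect_equal(est$pose$pan_deg, 5, tolerance = 1e-9)
  expect_equal(est$length_L, b$truth$L, tolerance = 1e-9)
  expect_equal(est$area_S, b$truth$S, tolerance = 1e-9)
  expect_equal(est$height_h, 150, tolerance = 1e-9)
  # aligned camera: the simple-case closed form is already exact
  scn0 <- forward_scene(cam, rig, h = 120, tilt_deg = 0, pan_deg = 0)
  b0 <- synthesize_measurements(scn0, 700, 500)
  expect_equal(ground_length_simple(b0$measurements$n_prime,
                                    b0$measurements$n_dprime, cam, rig),
               b0$truth$L, tolerance = 1e-9)
})

test_that("the literal closed forms carry the documented pan factors", {
  # the plain length equation returns the perpendicular row separation
  # (along-laser length times cos pan); the plain height equation returns
  # h times cos^2 pan -- exact second-order pan behaviour
  cam <- paper_cam()
  rig <- laser_rig(67)
  for (pan in c(5, 12, -18)) {
    scn <- forward_scene(cam, rig, h = 150, tilt_deg = 20, pan_deg = pan)
    b <- synthesize_measurements(scn, 700, 350)
    est <- laser_estimate(b$measurements, cam, rig)
    cg <- cos(pan * pi / 180)
    expect_equal(est$length_L, b$truth$L * cg, tolerance = 1e-9)
    expect_equal(est$height_h, 150 * cg^2, tolerance = 1e-9)
  }
})

test_that("a sloping seabed adds to the apparent tilt (slope recovery)", {
  cam <- paper_cam()
  rig <- laser_rig(67)
  scn <- forward_scene(cam, rig, h = 150, tilt_deg = 10, pan_deg = 0,
                       ground_slope_deg = 12)
  b <- synthesize_measurements(scn, 700, 400)
  est <- laser_estimate(b$measurements, cam, rig, true_tilt_deg = 10)
  expect_equal(est$pose$tilt_deg, 22, tolerance = 1e-9)
  expect_equal(est$slope_deg, 12, tolerance = 1e-9)
  # footprint measured along the slope, height perpendicular to it
  expect_equal(est$length_L, b$truth$L, tolerance = 1e-9)
  expect_equal(est$height_h, 150 * cos(12 * pi / 180), tolerance = 1e-9)
})

test_that("quantized synthesis rounds to integers, reproducibly", {
  cam <- paper_cam()
  scn <- forward_scene(cam, laser_rig(67), h = 150, tilt_deg = 20,
                       pan_deg = 3)
  b1 <- synthesize_measurements(scn, 700, 350, quantize = TRUE, seed = 9)
  b2 <- synthesize_measurements(scn, 700, 350, quantize = TRUE, seed = 9)
  vals <- unlist(unclass(b1$measurements))
  expect_true(all(vals == round(vals)))
  expect_identical(unclass(b1$measurements), unclass(b2$measurements))
})

test_that("synthetic stills place the green stripes on the projected
           lines", {
  cam <- paper_cam()
  rig <- laser_rig(67)
  scn <- forward_scene(cam, rig, h = 120, tilt_deg = 20, pan_deg = -2)
  img <- render_synthetic_image(scn, background = "flat")
  expect_equal(dim(img), c(800, 1280, 3))
  score <- img[, , 2] - (img[, , 1] + img[, , 3]) / 2
  for (v in c(750, 500, 300)) {
    row <- score[v + 1, ]
    js <- which(row > 0.5 * max(row))
    runs <- split(js, cumsum(c(0, diff(js) > 2)))
    expect_length(runs, 2)                 # exactly two line components
    peaks <- vapply(runs, function(g) (g[which.max(row[g])] - 1),
                    numeric(1))
    truth <- c(laserquad:::.laser_u_at_row(scn, -rig$l1, v),
               laserquad:::.laser_u_at_row(scn, rig$l2, v))
    expect_lt(max(abs(sort(peaks) - sort(truth))), 0.6)
  }
})

test_that("speckle rendering is byte-reproducible for a fixed seed", {
  scn <- forward_scene(paper_cam(), laser_rig(67), h = 120, tilt_deg = 18,
                       pan_deg = 1)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  render_synthetic_image(scn, f1, background = "speckle", seed = 5)
  render_synthetic_image(scn, f2, background = "speckle", seed = 5)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("perspective cotangent sum encodes the exact height relation", {
  # cot(theta1) + cot(theta2) = l cos(lambda) / (h cos(gamma)), exactly
  set.seed(21)
  for (i in 1:25) {
    x <- draw_bundle()
    ct <- perspective_cotangents(x$bundle$measurements, x$scene$cam)
    lam <- x$scene$tilt_deg * pi / 180
    gam <- x$scene$pan_deg * pi / 180
    expect_equal(sum(ct),
                 x$scene$rig$l * cos(lam) / (x$scene$h * cos(gam)),
                 tolerance = 1e-9)
  }
})
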