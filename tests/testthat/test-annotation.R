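# annotated line pairs -> pixel measurements via the vanishing point

test_that("line intersection solves the two-line system exactly", {
  a <- image_line(0, 0, 100, 100)
  b <- image_line(100, 0, 0, 100)
  expect_equal(unname(line_intersection(a, b)), c(50, 50))
  # validation fixture lines meet far above the raster
  ann <- validation_annotation()
  vp <- line_intersection(ann$line_left, ann$line_right)
  expect_equal(unname(vp), c(665.2962963, -117.8148148), tolerance = 1e-7)
  # and the vanishing vertical matches the closed-form construction
  expect_equal(vp[["u"]], 465 + 52 / (52 + 29) * 312, tolerance = 1e-9)
})

test_that("parallel lines are reported as a vanishing point at infinity", {
  a <- image_line(100, 0, 100, 700)
  b <- image_line(500, 0, 500, 700)
  expect_error(line_intersection(a, b), "parallel")
})

test_that("the validation fixture reproduces the published measurements", {
  m <- measurements_from_annotation(validation_annotation())
  expect_equal(m$n_prime, 312, tolerance = 1e-9)
  expect_equal(m$n_dprime, 232, tolerance = 1e-9)
  expect_equal(m$n0, 465, tolerance = 1e-9)
  expect_equal(m$m0, 367, tolerance = 1e-9)
  # slope triple measured at the near row; same ratios as the published one
  expect_equal(m$n1 / m$m, 52 / 143, tolerance = 1e-12)
  expect_equal(m$n2 / m$m, 29 / 143, tolerance = 1e-12)
  # identical downstream estimates (slope-row invariance bridge)
  a <- laser_estimate(m, paper_cam(), paper_rig())
  b <- laser_estimate(paper_meas(), paper_cam(), paper_rig())
  expect_equal(a$length_L, b$length_L, tolerance = 1e-12)
  expect_equal(a$height_h, b$height_h, tolerance = 1e-12)
  expect_equal(a$pose$tilt_deg, b$pose$tilt_deg, tolerance = 1e-12)
})

test_that("left/right identity comes from position, not argument order", {
  ann <- validation_annotation()
  swapped <- annotation_set(ann$line_right, ann$line_left,
                            ann$near_row_v, ann$far_row_v, 1280, 800)
  expect_equal(unclass(measurements_from_annotation(swapped)),
               unclass(measurements_from_annotation(ann)))
})

test_that("symmetric lines give equal slope offsets", {
  left <- image_line(400, 700, 480, 300)
  right <- image_line(600, 700, 520, 300)
  ann <- annotation_set(left, right, 650, 350, 1000, 800)
  m <- measurements_from_annotation(ann)
  expect_equal(m$n1, m$n2, tolerance = 1e-9)
})

test_that("annotation of a forward scene recovers its ground truth", {
  cam <- paper_cam()
  rig <- laser_rig(67, l1 = 30, l2 = 37)
  scn <- forward_scene(cam, rig, h = 160, tilt_deg = 22, pan_deg = 6)
  lines <- render_laser_lines(scn, 120, 2500)
  ann <- annotation_set(lines$left, lines$right, 700, 300,
                        cam$width, cam$height)
  m <- measurements_from_annotation(ann)
  est <- laser_estimate(m, cam, rig, pan_exact = TRUE)
  truth <- synthesize_measurements(scn, 700, 300)$truth
  expect_equal(est$length_L, truth$L, tolerance = 1e-9)
  expect_equal(est$height_h, 160, tolerance = 1e-9)
})

test_that("inconsistent annotations are rejected", {
  ann <- validation_annotation()
  expect_error(annotation_set(ann$line_left, ann$line_right, 300, 433,
                              1280, 800), "near_row_v")
  # lines diverging upward: flip both slopes
  left <- image_line(465, 433, 465 - 52, 290)
  right <- image_line(777, 433, 777 + 29, 290)
  expect_error(
    measurements_from_annotation(
      annotation_set(left, right, 433, 290, 1280, 800)),
    "diverge")
  expect_error(image_line(100, 400, 300, 400), "horizontal")
})

test_that("annotation files round-trip in both dialects", {
  ann <- validation_annotation()
  for (ext in c("json", "csv")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_annotation(ann, path)
    back <- read_annotation(path)
    expect_equal(unclass(back$line_left), unclass(ann$line_left))
    expect_equal(unclass(back$line_right), unclass(ann$line_right))
    expect_equal(back$near_row_v, ann$near_row_v)
    expect_equal(back$far_row_v, ann$far_row_v)
    unlink(path)
  }
})

test_that("annotation schema errors name the offending field", {
  ann <- validation_annotation()
  path <- tempfile(fileext = ".json")
  write_annotation(ann, path)
  obj <- jsonlite::read_json(path)
  obj$far_row_v <- NULL
  obj$comment <- "extra metadata must be tolerated"
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_annotation(path), "far_row_v")
  obj$far_row_v <- ann$far_row_v
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_s3_class(read_annotation(path), "annotation_set")  # extras ignored
  unlink(path)
})
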