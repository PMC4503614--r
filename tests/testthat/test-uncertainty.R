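# maximal (absolute-sum) first-order uncertainty propagation

test_that("published validation still yields the known uncertainties", {
  cam <- paper_cam()
  rig <- paper_rig()
  m <- paper_meas()
  expect_equal(rel_unc_cos_tilt(m, cam), 0.01844953324, tolerance = 1e-8)
  expect_equal(rel_unc_cos_pan(m, cam), 1.257304234e-4, tolerance = 1e-6)
  est <- laser_estimate(m, cam, rig)
  expect_equal(est$delta_L, 5.548674765, tolerance = 1e-8)
  expect_equal(est$delta_S, 424.9673636, tolerance = 1e-8)
  expect_equal(est$delta_h, 5.811609455, tolerance = 1e-8)
})

test_that("area and length uncertainties differ exactly by delta_l / l", {
  cam <- paper_cam()
  m <- paper_meas()
  for (dl in c(0, 0.5, 2)) {
    rig <- laser_rig(67, delta_l = dl)
    rL <- rel_unc_length(m, cam, rig)
    rS <- rel_unc_area(m, cam, rig)
    expect_equal(rS - rL, dl / 67, tolerance = 1e-15)
  }
})

test_that("zero-pose measurements have zero cosine uncertainty", {
  cam <- camera_intrinsics(60, 40, 1000, 800)
  m <- zero_pose_meas()
  expect_equal(rel_unc_cos_tilt(m, cam), 0)
  expect_equal(rel_unc_cos_pan(m, cam), 0)
  # in that limit the length uncertainty is the row term plus delta_l / l
  rig <- laser_rig(60, delta_l = 0.5)
  expect_equal(rel_unc_length(m, cam, rig),
               (200 / 400 + 400 / 200) / 200 + 0.5 / 60, tolerance = 1e-15)
  # and the height uncertainty is the slope terms plus delta_l / l
  expect_equal(rel_unc_height(m, cam, rig),
               1 / 100 + 2 / 200 + 0.5 / 60, tolerance = 1e-15)
})

test_that("uncertainties are positive and shrink with image resolution", {
  cam <- paper_cam()
  rig <- paper_rig()
  m <- paper_meas()
  base <- c(rel_unc_cos_tilt(m, cam), rel_unc_cos_pan(m, cam),
            rel_unc_length(m, cam, rig), rel_unc_area(m, cam, rig),
            rel_unc_height(m, cam, rig))
  expect_true(all(base > 0))
  for (c_scale in c(2, 4)) {
    cam2 <- camera_intrinsics(cam$alpha_h, cam$alpha_v,
                              cam$width * c_scale, cam$height * c_scale)
    m2 <- image_measurements(m$n_prime * c_scale, m$n_dprime * c_scale,
                             m$n0 * c_scale, m$n1 * c_scale,
                             m$n2 * c_scale, m$m0 * c_scale,
                             m$m * c_scale)
    finer <- c(rel_unc_cos_tilt(m2, cam2), rel_unc_cos_pan(m2, cam2),
               rel_unc_length(m2, cam2, rig), rel_unc_area(m2, cam2, rig),
               rel_unc_height(m2, cam2, rig))
    expect_true(all(finer < base))
    base <- finer
  }
})

test_that("pan-cosine uncertainty grows with the pan magnitude", {
  cam <- paper_cam()
  m <- paper_meas()
  # shift the left line (and the vanishing vertical with it) further off
  # centre; everything else fixed
  r <- vapply(c(465, 505, 545, 585), function(n0) {
    mi <- image_measurements(m$n_prime, m$n_dprime, n0, m$n1, m$n2,
                             m$m0, m$m)
    rel_unc_cos_pan(mi, cam)
  }, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("pixel error scales the resolution terms", {
  cam <- paper_cam()
  rig <- paper_rig()
  m <- paper_meas()
  e2 <- measurement_errors(pixel_error = 2)
  expect_equal(rel_unc_cos_tilt(m, cam, e2),
               2 * rel_unc_cos_tilt(m, cam), tolerance = 1e-12)
  # delta_l contribution is unaffected by the pixel error
  r1 <- rel_unc_length(m, cam, rig, measurement_errors(1))
  r2 <- rel_unc_length(m, cam, rig, measurement_errors(2))
  expect_gt(r2, r1)
  expect_lt(r2, 2 * r1)
})

test_that("length/area/height propagation matches a finite-difference
           maximal-error oracle", {
  # independent oracle: absolute-sum of first-order finite differences of
  # the closed forms with respect to (n', n'', cos-gamma, cos-lambda, l)
  cam <- paper_cam()
  rig <- paper_rig()
  L_fn <- function(np, nd, cg, cl, l)
    (np / nd - 1) * (cam$width / np) * l / (2 * cam$tan_h2 * cl * cg)
  h_fn <- function(n1, n2, m, cg, cl, l) {
    k <- (cam$height / m) * cam$tan_h2 / cam$tan_v2 / cam$width
    cl * cg * l / (k * (n1 + n2))
  }
  for (m in list(paper_meas(),
                 image_measurements(420, 260, 500, 80, 55, 300, 200))) {
    est <- laser_estimate(m, cam, rig)
    cg <- est$pose$cos_pan
    cl <- est$pose$cos_tilt
    dcg <- est$rel_unc_cos_pan * cg
    dcl <- est$rel_unc_cos_tilt * cl
    fd <- function(f, args, deltas) {
      f0 <- do.call(f, args)
      sum(vapply(seq_along(deltas), function(i) {
        a <- args
        a[[i]] <- a[[i]] + deltas[i]
        abs(do.call(f, a) - f0)
      }, numeric(1)))
    }
    dL_fd <- fd(L_fn, list(m$n_prime, m$n_dprime, cg, cl, rig$l),
                c(1, 1, dcg, dcl, rig$delta_l))
    expect_equal(dL_fd, est$delta_L, tolerance = 0.05)
    dh_fd <- fd(h_fn, list(m$n1, m$n2, m$m, cg, cl, rig$l),
                c(1, 1, 1, dcg, dcl, rig$delta_l))
    expect_equal(dh_fd, est$delta_h, tolerance = 0.05)
    # the area bound adds one more laser-separation term exactly
    expect_equal(est$delta_S / est$area_S - est$delta_L / est$length_L,
                 rig$delta_l / rig$l, tolerance = 1e-12)
  }
})
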