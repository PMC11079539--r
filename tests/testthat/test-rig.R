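test_that("default rig carries the documented geometry and overrides apply", {
  rig <- make_default_rig()
  expect_equal(rig$baseline_mm, 60)
  expect_equal(rig$standard_height_mm, 470)
  expect_equal(rig$range_mm, c(450, 490))
  expect_equal(rig$fov_mm, c(79, 66))
  expect_equal(rig$stripes_in_fov, 15)
  rig2 <- make_default_rig(baseline_mm = 80, n_steps = 5)
  expect_equal(rig2$baseline_mm, 80)
  expect_equal(rig2$n_steps, 5L)
  expect_equal(rig2$standard_height_mm, 470)
})

test_that("rig invariants are enforced with the offending field named", {
  expect_error(make_default_rig(baseline_mm = -1), "baseline_mm")
  expect_error(make_default_rig(range_mm = c(480, 490)), "range_mm")
  expect_error(make_default_rig(n_steps = 2), "n_steps")
  expect_error(make_default_rig(image_size_px = c(790, 700)), "square")
  expect_error(make_default_rig(bogus_field = 1), "unknown")
})

test_that("pixel rays span the field of view and are unit length", {
  rig <- make_default_rig()
  ctr <- pixel_ray(rig, c(395, 330))
  expect_equal(ctr$direction, c(0, 0, 1))
  corner <- pixel_ray(rig, c(0, 0))
  t <- rig$standard_height_mm / corner$direction[3]
  expect_equal(t * corner$direction, c(-39.5, 33, 470), tolerance = 1e-12)
  for (px in list(c(3, 7), c(512.25, 100.5), c(789, 659))) {
    expect_equal(sum(pixel_ray(rig, px)$direction^2), 1, tolerance = 1e-12)
  }
  expect_error(pixel_ray(rig, c(-1, 0)), "bounds")
  expect_error(pixel_ray(rig, c(0, 660)), "bounds")
})

test_that("phase planes contain the projector and trace stripes on the reference plane", {
  rig <- make_default_rig()
  proj <- c(rig$baseline_mm, 0, 0)
  for (phi in c(0, 2 * pi, -7.3, 40)) {
    pl <- phase_plane(rig, phi)
    expect_equal(sum(pl$normal^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum((proj - pl$point) * pl$normal)), 1e-9)
  }
  # one full fringe period on the reference plane = fov width / stripe count
  p0 <- phase_plane(rig, 0)
  p1 <- phase_plane(rig, 2 * pi)
  expect_equal(p1$point[1] - p0$point[1], 79 / 15, tolerance = 1e-12)
})

test_that("triangulation inverts the reference phase and matches the closed form", {
  rig <- make_default_rig()
  # a pixel observing exactly its reference-plane phase sits on the plane
  f0 <- 15 / 79
  for (px in list(c(395, 330), c(100, 200), c(600.5, 50))) {
    x_ref <- (px[1] - 395) * 0.1
    pt <- triangulate_pixel(rig, px, 2 * pi * f0 * x_ref)
    expect_equal(pt[3], 470, tolerance = 1e-9)
  }
  # centre pixel, phase deficit pi: the small-angle closed form
  d <- 60; L <- 470
  h_cf <- L * pi / (pi + 2 * pi * f0 * d)
  phi_meas <- 0 - pi   # reference phase at the centre is 0
  pt <- triangulate_pixel(rig, c(395, 330), phi_meas)
  expect_equal(L - pt[3], h_cf, tolerance = 0.02 * h_cf)
  # triangulated point lies on the pixel ray
  ray <- pixel_ray(rig, c(123, 456))
  pt <- triangulate_pixel(rig, c(123, 456), 5.5)
  cross <- c(ray$direction[2] * pt[3] - ray$direction[3] * pt[2],
             ray$direction[3] * pt[1] - ray$direction[1] * pt[3],
             ray$direction[1] * pt[2] - ray$direction[2] * pt[1])
  expect_lt(sqrt(sum(cross^2)) / sqrt(sum(pt^2)), 1e-12)
})

test_that("exact triangulation converges to the phase-to-height closed form as h -> 0", {
  rig <- make_default_rig()
  f0 <- fringe3d:::fringe_frequency(rig, "high")
  d <- 60; L <- 470
  h_of_dphi <- function(dphi) {
    pt <- triangulate_pixel(rig, c(395, 330), -dphi)
    L - pt[3]
  }
  # at |h| = 1 mm the relative difference is below 0.5 %
  dphi_1mm <- 2 * pi * f0 * d * 1 / (L - 1)
  h_cf <- L * dphi_1mm / (dphi_1mm + 2 * pi * f0 * d)
  expect_lt(abs(h_of_dphi(dphi_1mm) - h_cf) / abs(h_cf), 0.005)
  # and the agreement tightens as h shrinks
  dphi_01 <- dphi_1mm / 10
  h_cf_01 <- L * dphi_01 / (dphi_01 + 2 * pi * f0 * d)
  expect_lt(abs(h_of_dphi(dphi_01) - h_cf_01) / abs(h_cf_01),
            abs(h_of_dphi(dphi_1mm) - h_cf) / abs(h_cf) + 1e-12)
})

test_that("near-parallel ray and phase plane raise a degenerate-geometry error", {
  rig <- make_default_rig()
  # the phase plane whose stripe trace passes x = baseline contains the
  # optical axis, so the centre ray never crosses it
  expect_error(triangulate_pixel(rig, c(395, 330), 2 * pi * (15 / 79) * 60),
               "degenerate")
})

test_that("rig configurations round-trip through JSON", {
  rig <- make_default_rig(baseline_mm = 55, scan_direction = "y")
  f <- tempfile(fileext = ".json")
  write_rig_config(rig, f)
  rig2 <- read_rig_config(f)
  expect_equal(rig2, rig)
})
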