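test_that("profiles sample the expected stations and anchor their endpoints", {
  rig <- test_rig()
  hm <- simulate_and_reconstruct(rig, flat_surface(470), 0, 1)
  prof <- extract_profile(hm, c(-10, 0), c(10, 0), 0.1)
  expect_equal(nrow(prof$points), 201L)
  expect_lt(max(abs(prof$h)), 1e-6)
  expect_equal(prof$points[1, c("x", "y")], c(x = -10, y = 0))
  expect_equal(prof$points[201, c("x", "y")], c(x = 10, y = 0))
  expect_equal(path_length(prof), 20, tolerance = 1e-6)
})

test_that("a half-pipe cross-section matches the analytic circle", {
  hm <- halfpipe_recon()
  prof <- extract_profile(hm, c(-15, 0), c(15, 0), 0.1)
  apex_h <- 470 - 455
  u <- prof$points[, "x"]
  truth <- apex_h - (21 - sqrt(21^2 - u^2))
  expect_lt(max(abs(prof$h - truth)), 0.02)
})

test_that("invalid stations are bridged when short and fatal when long", {
  rig <- test_rig()
  hm <- scene_height_map(rig, flat_surface(470))
  # knock out one pixel column (0.5 mm wide)
  col <- 80L
  hm$valid_mask[, col] <- FALSE
  hm$h[, col] <- NA_real_
  # at 0.5 mm stations the hole spans <= 3 stations: bridged
  prof <- expect_silent(extract_profile(hm, c(-10, 0), c(10, 0), 0.5))
  expect_false(anyNA(prof$h))
  # at 0.1 mm stations the same hole spans ~10 stations: unmeasurable
  expect_error(extract_profile(hm, c(-10, 0), c(10, 0), 0.1),
               "unmeasurable")
})

test_that("path length always dominates the chord and converges on refinement", {
  hm <- halfpipe_recon()
  for (ep in list(list(c(-12, 3), c(9, -6)), list(c(0, -10), c(0, 10)),
                  list(c(-15, 0), c(15, 0)))) {
    prof <- extract_profile(hm, ep[[1]], ep[[2]], 0.1)
    expect_gte(path_length(prof), sqrt(sum((ep[[2]] - ep[[1]])^2)) - 1e-9)
  }
  # Richardson check on a smooth section at fine pitch: halving the step
  # moves the result by < 0.01 %
  fine <- scene_height_map(make_default_rig(), half_pipe_surface(21))
  p1 <- path_length(extract_profile(fine, c(-15, 0), c(15, 0), 0.1))
  p2 <- path_length(extract_profile(fine, c(-15, 0), c(15, 0), 0.05))
  expect_lt(abs(p2 - p1) / p1, 1e-4)
})

test_that("virtual surfaces recover planes exactly and circles to the sagitta bound", {
  rig <- test_rig()
  flat <- scene_height_map(rig, flat_surface(470))
  vs <- fit_virtual_surface(flat, c(-15, 15, -15, 15), 2)
  expect_lt(max(abs(vs$coefficients[-1])), 1e-9)
  expect_lt(vs$rms_residual_mm, 1e-9)
  # noiseless half-pipe annulus, degree 2, 30-mm ROI
  hp <- scene_height_map(rig, half_pipe_surface(21))
  vs2 <- fit_virtual_surface(hp, c(-15, 15, -15, 15), 2)
  # oracle: best 1-D quadratic fit of the circular sag over the same
  # u-values bounds the attainable residual
  sel <- hp$valid_mask & hp$x >= -15 & hp$x <= 15 & hp$y >= -15 &
    hp$y <= 15 & !(abs(hp$x) <= 9 & abs(hp$y) <= 9)
  u <- hp$x[sel]
  oracle_fit <- stats::lm.fit(cbind(1, u, u^2), hp$h[sel])
  oracle_rms <- sqrt(mean(oracle_fit$residuals^2))
  # the 2-D basis nests the 1-D one, so its residual can only be smaller
  expect_lte(vs2$rms_residual_mm, oracle_rms + 1e-12)
  expect_gte(vs2$rms_residual_mm, 0.8 * oracle_rms)
  expect_lt(vs2$rms_residual_mm, 0.1)
  # held-out lesion zone predicted to < 0.1 mm rms
  excl <- abs(hp$x) <= 0.6 * 15 & abs(hp$y) <= 0.6 * 15
  pred <- predict_surface(vs2, hp$x[excl], hp$y[excl])
  expect_lt(sqrt(mean((pred - hp$h[excl])^2)), 0.1)
})

test_that("degree-0 fits report the height spread of a tilted plane", {
  rig <- test_rig()
  ramp <- fringe3d:::new_scene(function(x, y) 470 + 0.3 * x,
                               function(x, y) rep_len(1, length(x)),
                               c(-39.5, 39.5, -33, 33), list(type = "ramp"))
  hm <- scene_height_map(rig, ramp)
  roi <- c(-12, 12, -12, 12)
  vs <- fit_virtual_surface(hm, roi, 0, exclusion_scale = 0)
  # brute-force oracle: rms about the mean over the same pixels
  sel <- hm$x >= roi[1] & hm$x <= roi[2] & hm$y >= roi[3] & hm$y <= roi[4]
  oracle <- sqrt(mean((hm$h[sel] - mean(hm$h[sel]))^2))
  expect_equal(vs$rms_residual_mm, oracle, tolerance = 0.1 * oracle)
  # a uniform-in-x spread has sd = spread / sqrt(12)
  expect_equal(oracle, 0.3 * 24 / sqrt(12), tolerance = 0.01 * oracle)
  expect_error(fit_virtual_surface(hm, c(-1, 1, -1, 1), 6), "few")
})

test_that("lesion extraction finds the level set and honours seed points", {
  rig <- test_rig()
  sc <- stomach_lesion_scene()
  hm <- scene_height_map(rig, sc)
  vs <- fit_virtual_surface(hm, c(-12.5, 12.5, -12.5, 12.5), 2)
  mask <- extract_lesion(hm, vs, 0.5)
  # footprint ~ the 0.5 mm level set of the cosine bump:
  # 0.5 = 3 (1 + cos(pi r / 5)) / 2  =>  r = 5 acos(-2/3) / pi
  r_level <- 5 * acos(-2 / 3) / pi
  xs <- hm$x[mask$mask]
  expect_equal(diff(range(xs)), 2 * r_level, tolerance = 0.15 * 2 * r_level)
  # no lesion on a flat scene
  flat <- scene_height_map(rig, flat_surface(470))
  vsf <- fit_virtual_surface(flat, c(-12.5, 12.5, -12.5, 12.5), 2)
  expect_error(extract_lesion(flat, vsf, 0.5), "no lesion")
  # two bumps: the seed picks the smaller one
  two <- add_lesion(add_lesion(half_pipe_surface(21),
                               lesion_spec(c(-8, 0), 10, 3)),
                    lesion_spec(c(8, 0), 6, 2))
  hm2 <- scene_height_map(rig, two)
  vs2 <- fit_virtual_surface(hm2, c(-16, 16, -16, 16), 2,
                             exclusion_scale = 0.8)
  m_small <- extract_lesion(hm2, vs2, 0.5, seed_point = c(8, 0))
  m_large <- extract_lesion(hm2, vs2, 0.5)
  expect_lt(sum(m_small$mask), sum(m_large$mask))
  expect_gt(mean(hm2$x[m_small$mask]), 0)
  expect_lt(mean(hm2$x[m_large$mask]), 0)
})

test_that("depressed lesions are segmented with the sign flag", {
  rig <- test_rig()
  sc <- add_lesion(flat_surface(470), lesion_spec(c(0, 0), 10, -3))
  hm <- scene_height_map(rig, sc)
  vs <- fit_virtual_surface(hm, c(-12.5, 12.5, -12.5, 12.5), 2)
  mask <- extract_lesion(hm, vs, 0.5, sign = -1)
  expect_gt(sum(mask$mask), 0)
  lm <- lesion_diameters(hm, mask, vs)
  expect_gt(lm$max_height_mm, 2.5)   # depth, via the sign convention
})

test_that("circular bumps give isotropic diameters measured along the surface", {
  rig <- make_default_rig()   # fine pitch for sub-degree direction search
  sc <- add_lesion(flat_surface(470), lesion_spec(c(0, 0), 10, 3))
  hm <- scene_height_map(rig, sc)
  vs <- fit_virtual_surface(hm, c(-12.5, 12.5, -12.5, 12.5), 2)
  mask <- extract_lesion(hm, vs, 0.5)
  lm <- lesion_diameters(hm, mask, vs)
  expect_lt(abs(lm$major_diameter_mm - lm$minor_diameter_mm) /
              lm$major_diameter_mm, 0.02)
  expect_gte(lm$major_diameter_mm, lm$minor_diameter_mm)
  # surface path dominates the straight footprint chord
  expect_gte(lm$major_diameter_mm, lm$chord_major_mm)
  # and matches the analytic arc across the bump between the same endpoints
  truth <- true_path_length(sc, lm$major_endpoints["p", ],
                            lm$major_endpoints["q", ])
  expect_equal(lm$major_diameter_mm, truth, tolerance = 0.01 * truth)
})

test_that("flank polynomial base paths recover spans, tilts and arcs", {
  rig <- test_rig()
  # flat flanks: base path equals the euclidean span
  flat <- scene_height_map(rig, add_lesion(flat_surface(470),
                                           lesion_spec(c(0, 0), 10, 3)))
  prof <- extract_profile(flat, c(-10, 0), c(10, 0), 0.1)
  span_arc <- stats::approx(prof$s, prof$arc_coordinate,
                            xout = c(4.5, 15.5))$y
  bp <- base_path_from_flanks(prof, span_arc, degree = 2)
  expect_equal(as.numeric(bp), 11, tolerance = 0.01)
  # tilted plane, degree 1: span / cos(tilt) exactly
  tilt <- 0.25
  ramp <- fringe3d:::new_scene(function(x, y) 470 + tilt * x,
                               function(x, y) rep_len(1, length(x)),
                               c(-39.5, 39.5, -33, 33), list(type = "ramp"))
  hmr <- scene_height_map(rig, ramp)
  profr <- extract_profile(hmr, c(-10, 0), c(10, 0), 0.1)
  arc_span <- stats::approx(profr$s, profr$arc_coordinate,
                            xout = c(5, 15))$y
  bpr <- base_path_from_flanks(profr, arc_span, degree = 1)
  expect_equal(as.numeric(bpr), 10 * sqrt(1 + tilt^2), tolerance = 1e-3)
  # half-pipe flanks, degree 2, 21-mm span centred at the apex
  hp <- scene_height_map(rig, half_pipe_surface(21))
  prof_hp <- extract_profile(hp, c(-15, 0), c(15, 0), 0.05)
  arc_mid <- stats::approx(prof_hp$s, prof_hp$arc_coordinate,
                           xout = c(15 - 10.5, 15 + 10.5))$y
  bph <- base_path_from_flanks(prof_hp, arc_mid, degree = 2)
  truth <- 2 * 21 * asin(10.5 / 21)
  expect_equal(as.numeric(bph), truth, tolerance = 0.01 * truth)
  # one-sided flanks only: warn and extrapolate
  expect_warning(
    base_path_from_flanks(profr, stats::approx(profr$s, profr$arc_coordinate,
                                               xout = c(0.05, 15))$y, 1),
    "one-sided")
  expect_error(
    suppressWarnings(
      base_path_from_flanks(profr,
                            stats::approx(profr$s, profr$arc_coordinate,
                                          xout = c(0.05, 19.95))$y, 3)),
    "insufficient")
})
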