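test_that("summary statistics follow their closed forms", {
  s <- summary_stats(c(-1, 1))
  expect_equal(s$sd, 1)
  expect_equal(s$three_sigma, 3)
  z <- summary_stats(c(0, 0, 0))
  expect_equal(z$sd, 0)
  expect_equal(z$three_sigma, 0)
  ref <- c(1, 2, 3, 4)
  s2 <- summary_stats(rep(0, 4), measured = ref, reference = ref)
  expect_equal(s2$r_squared, 1)
  # constant reference: correlation undefined, reported missing
  s3 <- summary_stats(c(0.1, -0.1, 0), measured = c(1, 2, 3),
                      reference = c(2, 2, 2))
  expect_true(is.na(s3$r_squared))
  expect_error(summary_stats(1), ">= 2")
})

test_that("R-squared is invariant to affine rescaling of the reference", {
  set.seed(1)
  truth <- stats::runif(50, 0, 15)
  meas <- truth + stats::rnorm(50, sd = 0.1)
  a <- summary_stats(meas - truth, meas, truth)$r_squared
  b <- summary_stats(meas - truth, meas, 3.7 * truth - 12)$r_squared
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the marker harness counts points as markers x repeats x directions", {
  rig <- test_rig()
  rep1 <- height_accuracy_experiment(rig, repeats = 2, noise_sd = 1,
                                     seed = 11, directions = "orthogonal")
  expect_equal(rep1$n_data_points, 2 * 88)
  expect_equal(rep1$three_sigma_mm, 3 * rep1$sd_mm)
  expect_equal(sum(rep1$histogram$counts), rep1$n_data_points)
  rep2 <- height_accuracy_experiment(rig, repeats = 1, noise_sd = 1,
                                     seed = 11)
  expect_equal(rep2$n_data_points, 2 * 88)
  expect_setequal(unique(rep2$per_point_errors$direction),
                  c("orthogonal", "parallel"))
})

test_that("the harness is deterministic in the master seed", {
  rig <- test_rig()
  a <- height_accuracy_experiment(rig, repeats = 1, noise_sd = 2, seed = 5,
                                  directions = "orthogonal")
  b <- height_accuracy_experiment(rig, repeats = 1, noise_sd = 2, seed = 5,
                                  directions = "orthogonal")
  expect_identical(a$per_point_errors, b$per_point_errors)
  c <- height_accuracy_experiment(rig, repeats = 1, noise_sd = 2, seed = 6,
                                  directions = "orthogonal")
  expect_false(identical(a$per_point_errors$error, c$per_point_errors$error))
})

test_that("summary SD is invariant to marker and direction ordering", {
  rig <- test_rig()
  rep1 <- height_accuracy_experiment(rig, repeats = 1, noise_sd = 2,
                                     seed = 8)
  tab <- rep1$per_point_errors
  shuffled <- tab[sample.int(nrow(tab)), ]
  expect_equal(summary_stats(shuffled$error)$sd, rep1$sd_mm)
})

test_that("noiseless marker heights are essentially exact", {
  rig <- test_rig()
  rep0 <- height_accuracy_experiment(rig, repeats = 1, noise_sd = 0,
                                     seed = 1, directions = "orthogonal")
  expect_lt(rep0$sd_mm, 0.02)
  expect_gt(rep0$r_squared_by_direction[["orthogonal"]], 0.9999)
})

test_that("marker-height scatter grows with the noise level", {
  rig <- test_rig()
  sds <- vapply(c(0.5, 2, 8), function(ns) {
    r <- height_accuracy_experiment(rig, repeats = 5, noise_sd = ns,
                                    seed = 21, directions = "orthogonal")
    r$sd_mm
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("length sections and the lateral check meet their planar bounds", {
  rig <- test_rig()
  flat_case <- list(list(label = "flat", scene = flat_surface(470),
                         p = c(-5, 0), q = c(5, 0), type = "surface"))
  rep0 <- length_accuracy_experiment(rig, cases = flat_case,
                                     smoothing = FALSE, noise_sd = 0,
                                     seed = 2, lateral_check = FALSE)
  expect_lt(rep0$length_errors_pct$percent_error, 0.01)
})

test_that("smoothing improves noisy length accuracy in most runs", {
  rig <- test_rig()
  case <- list(list(label = "A", scene = stomach_lesion_scene(),
                    p = c(-7, 0), q = c(7, 0), type = "surface"))
  wins <- vapply(1:10, function(s) {
    on_ <- length_accuracy_experiment(rig, cases = case, smoothing = TRUE,
                                      noise_sd = 2, seed = s,
                                      lateral_check = FALSE)
    off <- length_accuracy_experiment(rig, cases = case, smoothing = FALSE,
                                      noise_sd = 2, seed = s,
                                      lateral_check = FALSE)
    on_$length_errors_pct$percent_error <= off$length_errors_pct$percent_error
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("doubling the repeats leaves the expected error SD unchanged", {
  rig <- test_rig()
  sd_small <- vapply(1:3, function(s) {
    height_accuracy_experiment(rig, repeats = 2, noise_sd = 2,
                               seed = 300 + s,
                               directions = "orthogonal")$sd_mm
  }, numeric(1))
  sd_large <- height_accuracy_experiment(rig, repeats = 4, noise_sd = 2,
                                         seed = 400,
                                         directions = "orthogonal")$sd_mm
  # same estimand: agreement well within Monte-Carlo scatter
  expect_lt(abs(mean(sd_small) - sd_large) / sd_large, 0.5)
})
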