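test_that("joint fit recovers noiseless parameters (inverse crime)", {
  sq <- seq_params()
  dict <- fix_dict_small(sq)
  basis <- compute_t1_basis(dict)
  truth <- c(1600, 800, 1, 5, -1)
  curve <- joint_model_curve(1600, 800, 1, 5, -1, sq)
  fit <- fit_joint_t1_pixel(curve, sq, dict, basis)
  expect_lt(abs(fit[["t1_pre"]] - 1600) / 1600, 1e-3)
  expect_lt(abs(fit[["t1_post"]] - 800) / 800, 1e-3)
  expect_lt(abs(fit[["m0"]] - 1), 1e-3)
  # scale equivariance: scaling the curve scales m0 only
  fit_k <- fit_joint_t1_pixel(3.7 * curve, sq, dict, basis)
  expect_lt(abs(fit_k[["t1_pre"]] - fit[["t1_pre"]]) / 1600, 1e-3)
  expect_lt(abs(fit_k[["m0"]] - 3.7 * fit[["m0"]]) / 3.7, 1e-3)
  expect_equal(n_fit_parameters(TRUE), 5L)
  expect_equal(n_fit_parameters(FALSE), 8L)
})

test_that("blood model fits pure-IR curves and shows Look-Locker bias", {
  sq <- seq_params()
  dict <- fix_dict_small(sq)
  basis <- compute_t1_basis(dict)
  prep <- ecvtask:::prepare_fit_dictionary(dict, basis)
  curve <- joint_model_curve(2200, 600, 2, 0, -1, sq)
  fit <- ecvtask:::fit_joint_curve(curve, sq, prep, alpha_fixed = 0)
  expect_lt(abs(fit[["t1_pre"]] - 2200) / 2200, 0.005)
  expect_lt(abs(fit[["t1_post"]] - 600) / 600, 0.005)
  # alpha = 0 model applied to a readout-saturated (alpha = 5) curve is
  # biased toward the shorter apparent T1* = -TR / log(E1 cos a)
  curve5 <- joint_model_curve(2200, 600, 1, 5, -1, sq)
  fit5 <- ecvtask:::fit_joint_curve(curve5, sq, prep, alpha_fixed = 0)
  t1_star <- -sq$tr / log(exp(-sq$tr / 2200) * cos(5 * pi / 180))
  expect_lt(fit5[["t1_pre"]], 2200)
  expect_gt(fit5[["t1_pre"]], 0.8 * t1_star)
})

test_that("blood selection finds elevated-m0 pools and rejects flats", {
  m0 <- matrix(1, 32, 32)
  m0[10:14, 10:14] <- 2         # blood pool
  m0[c(1:3), ] <- NA            # unfitted border
  mask <- select_blood_pixels(m0)
  expect_true(all(which(mask) %in% which(!is.na(m0) & m0 > 1.5)))
  expect_gte(sum(mask), 0.9 * 25)
  expect_error(select_blood_pixels(matrix(1, 16, 16)), "constant")
  # threshold at the maximum still selects the argmax pixel's component
  m2 <- matrix(1, 16, 16)
  m2[8, 8] <- 5
  m2[8, 9] <- 5
  m2[3, 3] <- 2
  expect_true(select_blood_pixels(m2, min_pixels = 1L)[8, 8])
})

test_that("weighted blood fitting matches the single-pixel limit", {
  sq <- seq_params()
  dict <- fix_dict_small(sq)
  basis <- compute_t1_basis(dict)
  curve <- joint_model_curve(2100, 500, 1.8, 0, -0.9, sq)
  frames <- rbind(curve, curve * 2)        # two pixels, same shape
  mask <- matrix(c(TRUE, FALSE), 2, 1)
  w <- matrix(c(1.5, 1), 2, 1)
  f1 <- fit_blood_t1(frames, mask, w, sq, dict, basis)
  prep <- ecvtask:::prepare_fit_dictionary(dict, basis)
  f2 <- ecvtask:::fit_joint_curve(curve, sq, prep, alpha_fixed = 0)
  expect_lt(abs(f1[["t1_pre"]] - f2[["t1_pre"]]), 1)
  expect_error(fit_blood_t1(frames, mask & FALSE, w, sq, dict, basis),
               "empty")
})

test_that("ECV equations reproduce hand arithmetic and edge cases", {
  maps <- structure(list(t1_pre = matrix(1600, 2, 2),
                         t1_post = matrix(800, 2, 2)),
                    class = "parameter_maps")
  blood <- c(t1_pre = 2000, t1_post = 500)
  res <- compute_ecv(maps, blood, hct = 0.45,
                     septal_mask = matrix(TRUE, 2, 2))
  expect_equal(mean(res$delta_r1_myo), 0.625, tolerance = 1e-12)
  expect_equal(res$delta_r1_blood, 1.5, tolerance = 1e-12)
  expect_equal(res$septal_ecv, (1 - 0.45) * 0.625 / 1.5 * 100,
               tolerance = 1e-12)
  # hct = 0 with equal delta R1 gives 100%
  maps2 <- structure(list(t1_pre = matrix(2000, 1, 1),
                          t1_post = matrix(500, 1, 1)),
                     class = "parameter_maps")
  r2 <- compute_ecv(maps2, blood, hct = 1e-12,
                    septal_mask = matrix(TRUE, 1, 1))
  expect_equal(r2$septal_ecv, 100, tolerance = 1e-6)
  # t1_post = t1_pre in myocardium -> 0%
  maps3 <- structure(list(t1_pre = matrix(1600, 1, 1),
                          t1_post = matrix(1600, 1, 1)),
                     class = "parameter_maps")
  expect_equal(compute_ecv(maps3, blood, 0.4,
                           septal_mask = matrix(TRUE, 1, 1))$septal_ecv, 0)
  expect_error(compute_ecv(maps, c(t1_pre = 500, t1_post = 2000), 0.4),
               "positive")
  expect_error(compute_ecv(maps, blood, hct = 1.5), "hct")
})

test_that("ECV is invariant under affine R1 calibration", {
  expect_lt(verify_ecv_invariance(1600, 800, 2000, 500, 0.45,
                                  slope = 1.166, intercept = -0.331),
            1e-12)
  expect_lt(verify_ecv_invariance(1600, 800, 2000, 500, 0.45,
                                  slope = 2, intercept = 0), 1e-12)
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    worst <- max(worst,
                 verify_ecv_invariance(runif(1, 1200, 2000),
                                       runif(1, 500, 1100),
                                       runif(1, 1800, 2600),
                                       runif(1, 300, 700),
                                       runif(1, 0.2, 0.6),
                                       slope = runif(1, 0.5, 2),
                                       intercept = runif(1, -1, 1)))
  }
  expect_lt(worst, 1e-10)
  expect_error(apply_linear_calibration(1, 0, 0.3), "slope")
  # negative control: an intercept applied to delta R1 (wrong placement)
  # does change ECV -- guards against mis-placing the calibration
  r1 <- c(myo = 0.625, blo = 1.5)
  ecv0 <- 0.55 * r1["myo"] / r1["blo"] * 100
  ecv_bad <- 0.55 * (1.166 * r1["myo"] - 0.331) /
    (1.166 * r1["blo"] - 0.331) * 100
  expect_gt(abs(ecv_bad - ecv0), 1)
})

test_that("reporting statistics match hand calculations", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  st <- report_stats(a, b)
  # hand-computed Welch t: equal variances/sizes -> t = -1 / sqrt(5/6)...
  se <- sqrt(var(a) / 4 + var(b) / 4)
  expect_equal(st$welch$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  st2 <- report_stats(a, b, x = 1:5, y = 2 * (1:5) + 3)
  expect_equal(st2$pearson$r, 1, tolerance = 1e-12)
  # identical groups -> t = 0, p = 1
  st3 <- report_stats(a, a)
  expect_equal(st3$welch$t, 0)
  expect_equal(st3$welch$p, 1)
  # repeatability block
  set.seed(5)
  ra <- rnorm(8, 20, 2)
  rb <- ra + rnorm(8, 0, 0.5)
  st4 <- report_stats(a, b, rep_a = ra, rep_b = rb)
  expect_true(st4$icc21 > 0.8 && st4$icc21 <= 1)
  expect_equal(st4$bland_altman$bias, mean(ra - rb), tolerance = 1e-12)
  expect_equal(st4$rms_within_sd, sqrt(mean((ra - rb)^2) / 2),
               tolerance = 1e-12)
  # ICC(2,1) oracle: perfect agreement -> 1
  expect_equal(icc_2_1(cbind(1:6, 1:6)), 1, tolerance = 1e-12)
})

test_that("cardiac temporal resolution follows heart rate and bin count", {
  expect_equal(cardiac_temporal_resolution(300, 10), 20)
  expect_equal(cardiac_temporal_resolution(450, 10), 60000 / 450 / 10)
  expect_error(cardiac_temporal_resolution(-5, 10), "heart_rate")
})
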