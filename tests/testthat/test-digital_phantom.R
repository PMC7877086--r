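test_that("phantom geometry is labeled consistently", {
  sq <- fix_seq_small()
  ph <- make_phantom(phantom_config(), sq)
  expect_gt(sum(ph$labels == 2L), 0)                 # myocardium present
  # blood pool fully enclosed by myocardium: every blood-adjacent
  # non-blood pixel is myocardium
  blood <- ph$labels == 3L
  myo <- ph$labels == 2L
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    src_r <- seq_len(nrow(m)) - dr
    src_c <- seq_len(ncol(m)) - dc
    ok_r <- src_r >= 1 & src_r <= nrow(m)
    ok_c <- src_c >= 1 & src_c <= ncol(m)
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  ring <- (shift(blood, 1, 0) | shift(blood, -1, 0) |
             shift(blood, 0, 1) | shift(blood, 0, -1)) & !blood
  expect_true(all(myo[ring]))
  expect_gt(sum(ph$masks$septal), 0)
  # label areas match analytic areas within a boundary band
  r_px <- phantom_config()$geometry$r_blood * sq$matrix
  expect_lt(abs(sum(blood) - pi * r_px^2), 2 * pi * r_px + 4)
  r_a <- phantom_config()$geometry$r_aorta * sq$matrix
  expect_lt(abs(sum(ph$labels == 4L) - pi * r_a^2), 2 * pi * r_a + 4)
})

test_that("static phantom renders identical frames at equal t1 index", {
  sq <- fix_seq_small()
  cfg <- phantom_config(contraction_amplitude = 0, resp_translation = 0,
                        lag_shift = 0, noise_sigma = 0)
  f1 <- render_frame(3 * sq$tr, "pre", cfg, sq)
  f2 <- render_frame(3 * sq$tr + sq$recovery_period, "pre", cfg, sq)
  expect_lt(max(Mod(f1 - f2)), 1e-12)
})

test_that("rendered frames reproduce per-tissue signal curves", {
  sq <- fix_seq_small()
  cfg <- phantom_config(contraction_amplitude = 0, resp_translation = 0,
                        lag_shift = 0, noise_sigma = 0)
  curves <- ecvtask:::tissue_signal_curves(cfg, sq, "pre")
  ph <- make_phantom(cfg, sq)
  ctr <- round(cfg$geometry$lv_center * sq$matrix)
  for (n in c(1L, 50L, 400L)) {
    fr <- render_frame((n - 1) * sq$tr, "pre", cfg, sq)
    got <- Re(fr[ctr[2], ctr[1]])
    expect_lt(abs(got - curves$blood[n] * cfg$tissues$blood$m0), 1e-9)
  }
})

test_that("acquisition counts, alternation, and ky conventions hold", {
  sq <- fix_seq_small(n_ir = 2L)
  ds <- acquire(phantom_config(), sq, seed = 5)
  per_scan <- sq$n_ir_pulses * sq$readouts_per_period
  expect_equal(nrow(ds$lines), 2L * per_scan)
  m <- ds$meta
  for (s in c("pre", "post")) {
    ms <- m[m$scan == s, ]
    expect_equal(nrow(ms), per_scan)
    # strict alternation: odd ordinals imaging, even ordinals training
    expect_true(all(ms$is_training == (ms$ordinal %% 2 == 0)))
    expect_true(all(diff(ms$timestamp) > 0))
  }
  expect_true(all(m$ky_index[m$is_training] == 0L))
  expect_true(all(m$ky_index >= -sq$matrix / 2 &
                    m$ky_index <= sq$matrix / 2 - 1))
  expect_true(all(m$t1_index >= 1 & m$t1_index <= sq$readouts_per_period))
})

test_that("DC line equals the transform of the column-summed image", {
  sq <- fix_seq_small(n_ir = 1L)
  cfg <- phantom_config(contraction_amplitude = 0, resp_translation = 0,
                        lag_shift = 0, noise_sigma = 0)
  ds <- acquire(cfg, sq, seed = 1)
  i <- which(ds$meta$is_training)[4]
  fr <- render_frame(ds$meta$timestamp[i], "pre", cfg, sq)
  m <- sq$matrix
  colsum <- colSums(fr) / sqrt(m)
  dc <- stats::fft(colsum)[c((m / 2 + 1):m, 1:(m / 2))] / sqrt(m)
  expect_lt(max(Mod(ds$lines[i, ] - dc)), 1e-10)
})

test_that("acquisition is bit-identical under the same seed", {
  sq <- fix_seq_small(n_ir = 1L)
  a <- acquire(phantom_config(), sq, seed = 9)
  b <- acquire(phantom_config(), sq, seed = 9)
  expect_identical(a$lines, b$lines)
  expect_identical(a$meta, b$meta)
  c <- acquire(phantom_config(), sq, seed = 10)
  expect_false(identical(a$lines, c$lines))
})

test_that("imaging ky histogram is consistent with Gaussian density", {
  sq <- seq_params(matrix = 64, n_ir_pulses = 20)
  ds <- acquire(phantom_config(), sq, seed = 3)
  ky <- ds$meta$ky_index[!ds$meta$is_training]
  sd_target <- sq$matrix / 6
  # chi-square GOF against the truncated, integer-rounded Gaussian
  edges <- seq(-sq$matrix / 2 - 0.5, sq$matrix / 2 - 0.5, by = 1)
  p <- diff(pnorm(edges, 0, sd_target))
  p[1] <- p[1] + pnorm(edges[1], 0, sd_target)
  p[length(p)] <- p[length(p)] + pnorm(edges[length(edges)], 0, sd_target,
                                       lower.tail = FALSE)
  obs <- tabulate(ky + sq$matrix / 2 + 1, nbins = sq$matrix)
  keep <- p * length(ky) >= 5
  chi2 <- sum((obs[keep] - length(ky) * p[keep])^2 /
                (length(ky) * p[keep]))
  df <- sum(keep) - 1
  expect_gt(pchisq(chi2, df, lower.tail = FALSE), 0.01)
})

test_that("Parseval: sampled line energy bounded by frame energy", {
  sq <- fix_seq_small(n_ir = 1L)
  cfg <- phantom_config(noise_sigma = 0)
  ds <- acquire(cfg, sq, seed = 2)
  for (i in c(1L, 15L, 300L)) {
    fr <- render_frame(ds$meta$timestamp[i], ds$meta$scan[i], cfg, sq)
    expect_lte(sum(Mod(ds$lines[i, ])^2), sum(Mod(fr)^2) + 1e-9)
  }
})

test_that("voxel size follows fov / matrix", {
  expect_equal(in_plane_voxel_size(seq_params()), 0.3125)
  expect_equal(round(in_plane_voxel_size(seq_params()), 2), 0.31)
  expect_equal(in_plane_voxel_size(seq_params(matrix = 40)), 1.0)
  expect_equal(in_plane_voxel_size(seq_params(fov = 64, matrix = 128)), 0.5)
})

test_that("invalid configurations error", {
  expect_error(phantom_config(hct = 1.2), "hct")
  expect_error(phantom_config(noise_sigma = -1), "noise_sigma")
  expect_error(acquire(phantom_config(), fix_seq_small(1),
                       gaussian_sigma_ky = 0), "gaussian_sigma_ky")
})
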