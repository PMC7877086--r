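test_that("wavelet transform is orthonormal and invertible", {
  set.seed(1)
  x <- matrix(rnorm(64 * 64), 64)
  w <- dwt2(x)
  expect_lt(max(abs(idwt2(w) - x)), 1e-12)
  expect_lt(abs(sum(w^2) - sum(x^2)), 1e-8)
  z <- matrix(complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32)),
              32)
  expect_lt(max(Mod(idwt2(dwt2(z)) - z)), 1e-12)
})

test_that("training tensor cells hold bin means with a correct mask", {
  sq <- fix_seq_small(n_ir = 3L)
  ds <- acquire(phantom_config(), sq, seed = 4)
  dict <- fix_dict_small(sq)
  bb <- compute_block_t1_basis(dict, rank = 12)
  bins <- bin_motion(ds, bb, seed = 1)
  tt <- form_training_tensor(ds, bins)
  expect_equal(dim(tt$data), c(sq$matrix, 10L, 5L,
                               2L * sq$readouts_per_period))
  expect_gt(mean(tt$mask), 0)
  expect_lt(mean(tt$mask), 1)
  # spot-check one occupied cell against a hand-computed mean
  b <- bins$bins[ds$meta$is_training, ]
  lines <- ds$lines[ds$meta$is_training, , drop = FALSE]
  nn <- sq$readouts_per_period
  tau <- b$t1_index + nn * (b$scan == "post")
  pick <- which(tau == tau[1] & b$cardiac_bin == b$cardiac_bin[1] &
                  b$resp_bin == b$resp_bin[1])
  manual <- colMeans(lines[pick, , drop = FALSE])
  expect_lt(max(Mod(tt$data[, b$cardiac_bin[1], b$resp_bin[1], tau[1]] -
                      manual)), 1e-12)
  expect_equal(tt$counts[b$cardiac_bin[1], b$resp_bin[1], tau[1]],
               length(pick))
})

test_that("completion recovers a synthetic multilinear-rank tensor", {
  set.seed(21)
  u1 <- rand_orthonormal(32, 8)
  u2 <- rand_orthonormal(10, 3)
  u3 <- rand_orthonormal(5, 2)
  u4 <- rand_orthonormal(64, 4)
  g <- array(rnorm(8 * 3 * 2 * 4), c(8, 3, 2, 4))
  truth <- ecvtask:::tensor_mode_mult(
    ecvtask:::tensor_mode_mult(
      ecvtask:::tensor_mode_mult(
        ecvtask:::tensor_mode_mult(g, u1, 1), u2, 2), u3, 3), u4, 4)
  mask <- array(runif(length(truth)) < 0.4, dim(truth))
  data <- truth
  data[!mask] <- 0
  comp <- complete_training_tensor(list(data = data + 0i, mask = mask),
                                   u4, ranks = c(8, 3, 2), tol = 1e-9,
                                   max_iter = 300)
  rel <- sqrt(sum(Mod(comp - truth)^2) / sum(truth^2))
  expect_lt(rel, 1e-3)
  # fully observed tensor in the model subspace is a fixed point
  comp2 <- complete_training_tensor(list(data = truth + 0i,
                                         mask = array(TRUE, dim(truth))),
                                    u4, ranks = c(8, 3, 2), max_iter = 5)
  expect_lt(sqrt(sum(Mod(comp2 - truth)^2) / sum(truth^2)), 1e-10)
})

test_that("masking more entries never lowers the observed residual", {
  set.seed(22)
  u4 <- rand_orthonormal(32, 3)
  g <- array(rnorm(6 * 4 * 3 * 3), c(6, 4, 3, 3))
  truth <- ecvtask:::tensor_mode_mult(g, u4, 4)
  truth <- truth + array(rnorm(length(truth), sd = 0.05), dim(truth))
  base_mask <- array(runif(length(truth)) < 0.7, dim(truth))
  res <- c()
  for (frac in c(0.7, 0.5, 0.3)) {
    mask <- base_mask & array(runif(length(truth)) < frac / 0.7,
                              dim(truth))
    comp <- suppressWarnings(
      complete_training_tensor(list(data = truth * mask + 0i, mask = mask),
                               u4, ranks = c(4, 3, 2), max_iter = 80))
    # residual on the ORIGINAL observed set (fit quality degrades with
    # fewer observations)
    res <- c(res, sqrt(sum(Mod(comp[base_mask] - truth[base_mask])^2)))
  }
  expect_true(all(diff(res) > -1e-8))
})

test_that("HOSVD factors are orthonormal and reassemble the tensor", {
  set.seed(23)
  u4 <- rand_orthonormal(40, 5)
  g <- array(rnorm(7 * 5 * 4 * 5), c(7, 5, 4, 5))
  x <- ecvtask:::tensor_mode_mult(
    ecvtask:::tensor_mode_mult(g, rand_orthonormal(12, 7), 1), u4, 4)
  x <- x + 0i
  fi <- extract_factors(x, u4, ranks = c(7, 5, 4))
  expect_lt(max(Mod(crossprod(Conj(fi$u_c), fi$u_c) - diag(5))), 1e-10)
  expect_lt(max(Mod(crossprod(Conj(fi$u_r), fi$u_r) - diag(4))), 1e-10)
  # U_k Phi reassembles the mode-1 unfolding
  x1 <- ecvtask:::tensor_unfold(x, 1)
  expect_lt(max(Mod(fi$u_k %*% fi$phi - x1)) / max(Mod(x1)), 1e-8)
  expect_error(extract_factors(x, u4, ranks = c(100, 5, 4)), "rank")
})

test_that("truncated HOSVD error respects the discarded-spectrum bound", {
  set.seed(24)
  x <- array(rnorm(16 * 8 * 5 * 20), c(16, 8, 5, 20)) + 0i
  u4 <- diag(20)[, 1:20]           # identity: no t1 truncation
  ranks <- c(10, 5, 3)
  fi <- extract_factors(x, u4, ranks = ranks)
  # reassemble from core and factors
  rec <- fi$core
  rec <- ecvtask:::tensor_mode_mult(rec, fi$u_k, 1)
  rec <- ecvtask:::tensor_mode_mult(rec, fi$u_c, 2)
  rec <- ecvtask:::tensor_mode_mult(rec, fi$u_r, 3)
  rec <- ecvtask:::tensor_mode_mult(rec, fi$u_t1, 4)
  err2 <- sum(Mod(rec - x)^2)
  bound <- 0
  for (mode in 1:3) {
    sv <- svd(ecvtask:::tensor_unfold(x, mode))$d
    bound <- bound + sum(sv[(ranks[mode] + 1):length(sv)]^2)
  }
  expect_lte(err2, bound * (1 + 1e-10))
})

test_that("spatial basis solver matches CG on the lambda = 0 problem", {
  set.seed(25)
  m <- 16
  l <- 3
  nt <- 400
  u_true <- matrix(complex(real = rnorm(m * m * l),
                           imaginary = rnorm(m * m * l)), m * m, l)
  phi <- t(rand_orthonormal(nt, l)) + 0i
  ky <- sample(seq(-m / 2, m / 2 - 1), nt, replace = TRUE)
  op <- ecvtask:::make_encoding_operator(ky, phi, m)
  lines <- op$forward(u_true)
  # FISTA path (lambda = 0) through a synthetic factored_image
  fi <- structure(list(phi = phi, k_card = 1L, k_resp = 1L, n_tau = nt,
                       rank = l, u_x = NULL), class = "factored_image")
  ds <- list(lines = lines,
             meta = data.frame(is_training = rep(FALSE, nt),
                               ky_index = ky, t1_index = seq_len(nt),
                               scan = "pre"),
             seq = list(readouts_per_period = nt))
  bins <- list(bins = data.frame(cardiac_bin = 1L, resp_bin = 1L,
                                 t1_index = seq_len(nt),
                                 scan = "pre"),
               k_card = 1L, k_resp = 1L)
  fi1 <- solve_spatial_basis(ds, bins, fi,
                             recon_config(lambda = 0, max_iter = 200,
                                          tol = 1e-12),
                             solver = "fista")
  cg <- solve_realtime_spatial(lines, ky, phi, m, tol = 1e-10,
                               max_iter = 300)
  expect_lt(sqrt(sum(Mod(fi1$u_x - cg)^2) / sum(Mod(cg)^2)), 1e-4)
  expect_lt(sqrt(sum(Mod(fi1$u_x - u_true)^2) / sum(Mod(u_true)^2)), 1e-3)
  # objective nonincreasing after restart handling
  obj <- attr(fi1$u_x, "objective")
  expect_true(all(diff(obj) <= 1e-8 * obj[1]))
  expect_error(recon_config(lambda = -1), "lambda")
})

test_that("rank-1 factored image reconstructs its outer product", {
  m <- 8
  u <- matrix(complex(real = rnorm(m * m)), m * m, 1)
  phi <- matrix(complex(real = rnorm(10)), 1, 10)
  fi <- structure(list(phi = phi, k_card = 1L, k_resp = 1L, n_tau = 10L,
                       rank = 1L, u_x = u), class = "factored_image")
  img <- reconstruct_image(fi, 1, 1, 1:10)
  expect_equal(dim(img), c(m, m, 10L))
  expect_lt(max(Mod(img[, , 3] - matrix(u * phi[1, 3], m, m))), 1e-12)
  expect_error(reconstruct_image(fi, 2, 1, 1), "cardiac_bin")
})

test_that("recovery error is nondecreasing in noise level", {
  # scaled-down sweep: score the completed training tensor against the
  # noiseless reference at three noise levels (the full-pipeline sweep is
  # out of test budget; the tensor stage inherits the noise monotonically)
  sq <- seq_params(matrix = 48, n_ir_pulses = 8)
  base <- phantom_config()
  sigma0 <- noise_sigma_for_snr(base, sq, snr = 30)
  dict <- fix_dict_small(sq)
  t1b <- compute_t1_basis(dict)
  ref <- NULL
  errs <- c()
  for (fac in c(0, 1, 4)) {
    cfg <- phantom_config(noise_sigma = fac * sigma0)
    ds <- acquire(cfg, sq, seed = 99)
    tb <- true_bins(ds, 6, 3)
    bins <- list(bins = data.frame(readout_id = ds$meta$readout_id,
                                   scan = ds$meta$scan,
                                   is_training = ds$meta$is_training,
                                   cardiac_bin = tb$cardiac_bin,
                                   resp_bin = tb$resp_bin,
                                   t1_index = ds$meta$t1_index),
                 k_card = 6L, k_resp = 3L)
    tt <- form_training_tensor(ds, bins)
    comp <- suppressWarnings(
      complete_training_tensor(tt, t1b, ranks = c(NA, 4, 3),
                               max_iter = 40))
    if (fac == 0) {
      ref <- comp
      errs <- c(errs, 0)
    } else {
      errs <- c(errs, sqrt(sum(Mod(comp - ref)^2) / sum(Mod(ref)^2)))
    }
  }
  expect_true(all(diff(errs) > 0))
})
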