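test_that("closed-form block matches the per-TR stepping oracle", {
  sq <- seq_params()
  set.seed(11)
  for (i in 1:10) {
    t1 <- runif(1, 100, 3000)
    m0 <- runif(1, 0.5, 2)
    alpha <- runif(1, 0.5, 7.5)
    b <- runif(1, -1, 0)
    m_init <- runif(1, -1, 1) * m0
    tis <- tissue_params(t1, t1 / 2, m0 = m0, alpha = alpha, b = b)
    cf <- simulate_ir_flash_block(tis, sq, m_init = m_init)
    or <- step_ir_block(m_init, t1, m0, alpha, b, sq)
    expect_lt(max(abs(cf$trace - or$trace)), 1e-10)
    expect_lt(max(abs(cf$signal - or$signal)), 1e-10)
    expect_lt(abs(cf$m_end - or$m_end), 1e-10)
  }
})

test_that("pure inversion-recovery limit follows m0(1 - 2 exp(-t/T1))", {
  sq <- seq_params()
  tis <- tissue_params(1200, 600, m0 = 1, alpha = 0, b = -1)
  blk <- simulate_ir_flash_block(tis, sq, m_init = 1)
  t <- seq_len(sq$readouts_per_period) * sq$tr
  expect_lt(max(abs(blk$trace - (1 - 2 * exp(-t / 1200)))), 1e-12)
  # longitudinal zero crossing at t = T1 ln 2
  crossing <- t[which(blk$trace > 0)[1]]
  expect_lt(abs(crossing - 1200 * log(2)), sq$tr)
})

test_that("b = 0 leaves the FLASH steady state undisturbed", {
  sq <- seq_params()
  tis <- tissue_params(1500, 700, alpha = 5, b = 0)
  e1 <- exp(-sq$tr / 1500)
  mss <- (1 - e1) / (1 - e1 * cos(5 * pi / 180))
  blk <- simulate_ir_flash_block(tis, sq, m_init = mss)
  expect_lt(diff(range(blk$signal)), 1e-12)
  expect_lt(abs(periodic_steady_state(tis, sq) - mss), 1e-12)
})

test_that("periodic steady state is the fixed point of the block map", {
  sq <- seq_params()
  tis <- tissue_params(1500, 750, alpha = 5, b = -1)
  m_star <- periodic_steady_state(tis, sq)
  # closed form vs brute-force iteration of 100 blocks
  m <- tis$m0
  for (i in 1:100) {
    m <- step_ir_block(m, 1500, tis$m0, tis$alpha, tis$b, sq)$m_end
  }
  expect_lt(abs(m - m_star), 1e-9)
  # fixed-point property
  blk <- simulate_ir_flash_block(tis, sq, m_init = m_star)
  expect_lt(abs(blk$m_end - m_star), 1e-9 * tis$m0)
  # T1 -> 0 limit: instantaneous recovery to m0
  tis0 <- tissue_params(1e-3, 5e-4, m0 = 1.4, alpha = 5, b = -1)
  expect_lt(abs(periodic_steady_state(tis0, sq) - 1.4), 1e-9)
})

test_that("joint pair shares parameters and stacks the two blocks", {
  sq <- seq_params()
  tis <- tissue_params(1600, 800, m0 = 1, alpha = 5, b = -1)
  jp <- simulate_joint_pair(tis, sq)
  pre <- simulate_ir_flash_block(tis, sq, t1 = "pre")
  post <- simulate_ir_flash_block(tis, sq, t1 = "post")
  expect_identical(jp$concatenated, c(pre$signal, post$signal))
  expect_length(jp$concatenated, 2 * sq$readouts_per_period)
  # continuity: t1_pre -> t1_post makes the halves agree
  tis2 <- tissue_params(800 + 1e-6, 800, alpha = 5, b = -1)
  jp2 <- simulate_joint_pair(tis2, sq)
  expect_lt(max(abs(jp2$pre_curve - jp2$post_curve)), 1e-8)
  expect_error(tissue_params(700, 800), "t1_pre > t1_post")
})

test_that("signal is bounded and recovery is monotone between excitations", {
  sq <- seq_params()
  set.seed(7)
  for (i in 1:20) {
    m0 <- runif(1, 0.5, 2)
    tis <- tissue_params(runif(1, 200, 3000), 100, m0 = m0,
                         alpha = runif(1, 0.5, 7.5), b = runif(1, -1, 0))
    blk <- simulate_ir_flash_block(tis, sq)
    expect_true(all(abs(blk$trace) <= m0 + 1e-12))
    if (tis$b < -0.5) {
      # post-inversion longitudinal recovery toward steady state
      expect_true(all(diff(blk$trace[1:100]) > -1e-12))
    }
  }
})

test_that("dictionary has the combinatorial atom count and bounded atoms", {
  sq <- seq_params()
  gs <- dictionary_grid_spec(n_t1 = 3, n_alpha = 1, n_b = 1)
  d <- build_dictionary(gs, sq)
  expect_equal(ncol(d$atoms), 3)              # choose(3, 2) admissible pairs
  expect_equal(n_dictionary_atoms(dictionary_grid_spec()),
               choose(101, 2) * 15 * 21)
  d2 <- fix_dict_small(sq)
  expect_equal(ncol(d2$atoms), n_dictionary_atoms(d2$grid_spec))
  expect_true(all(d2$grid[, "t1_pre"] > d2$grid[, "t1_post"]))
  # atoms are l2-normalized, hence every sample is <= 1 <= m0 sin(a) scale
  expect_true(all(abs(colSums(d2$atoms^2) - 1) < 1e-12))
  expect_error(build_dictionary(dictionary_grid_spec(n_t1 = 1), sq),
               "empty")
})

test_that("T1 basis is orthonormal and captures every atom to tolerance", {
  sq <- seq_params()
  d <- fix_dict_small(sq)
  bs <- compute_t1_basis(d)
  u <- bs$basis
  expect_lt(max(abs(crossprod(u) - diag(bs$rank))), 1e-10)
  expect_true(all(diff(bs$singular_values) <= 1e-8))
  resid <- sqrt(pmax(colSums(d$atoms^2) -
                       colSums(crossprod(u, d$atoms)^2), 0))
  expect_lt(max(resid), 1e-3)
  # energy captured is nondecreasing in rank
  frac <- cumsum(bs$singular_values^2) / sum(bs$singular_values^2)
  expect_true(all(diff(frac) >= -1e-15))
  # single-atom dictionary: rank-1 basis equals the atom up to sign
  d1 <- build_dictionary(dictionary_grid_spec(n_t1 = 2, n_alpha = 1,
                                              n_b = 1), sq)
  b1 <- compute_t1_basis(d1, rank = 1)
  expect_lt(min(max(abs(b1$basis - d1$atoms)),
                max(abs(b1$basis + d1$atoms))), 1e-10)
  expect_error(compute_t1_basis(d, rank = 1e5), "rank")
})

test_that("blocked Gram accumulation matches the materialized SVD", {
  sq <- seq_params()
  gs <- dictionary_grid_spec(n_t1 = 10, n_alpha = 3, n_b = 3)
  b_mat <- compute_t1_basis(build_dictionary(gs, sq))
  b_blk <- compute_t1_basis(build_dictionary(gs, sq, max_atoms = 1))
  expect_equal(b_mat$rank, b_blk$rank)
  expect_lt(max(abs(abs(b_mat$basis) - abs(b_blk$basis))), 1e-7)
})

test_that("sequence parameter validation enforces the timing invariant", {
  expect_error(seq_params(tr = -1), "tr")
  expect_error(seq_params(readouts_per_period = 500, recovery_period = 2912),
               "recovery period")
  expect_equal(seq_params()$readouts_per_period * seq_params()$tr, 2912)
  expect_error(tissue_params(1000, 500, b = 0.5), "b must")
  expect_error(tissue_params(1000, 500, m0 = -1), "m0")
})
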