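# Self-gated respiratory/cardiac binning from the interleaved k-space
# center (training) lines, without ECG or bellows signals.
#
# The modification to plain k-means is the use of the Bloch-simulated
# T1-recovery model while building motion features: each scan's per-column
# block template (the motion-averaged signal evolution within one inversion
# block) is projected onto the single-block T1 subspace and subtracted, so
# relaxation contrast does not masquerade as motion.  Respiration is
# estimated as a rigid shift from multi-lag phase slopes along the fully
# sampled frequency-encode axis; the cardiac phase is tracked by lock-in
# demodulation at the detected heart rate with a sign-rectified contrast
# envelope.  Pre- and post-contrast scans are processed with one shared
# heart-rate estimate and clustered together so both share one set of bins.

#' Real-time temporal basis from the training data
#'
#' Top right singular vectors of the stacked training-line matrix
#' (k-samples x readout times), pre- and post-contrast scans concatenated
#' along time.
#'
#' @param training complex matrix `[matrix x n_training_times]`
#' @param rank basis size `L_rt`
#' @return object of class `realtime_basis`: `phi` (`L_rt x n_times`, rows
#'   orthonormal), `singular_values`, `spatial` (left vectors)
#' @export
estimate_realtime_basis <- function(training, rank = 16L) {
  if (rank > min(dim(training))) {
    stop("estimate_realtime_basis: rank exceeds data dimensions")
  }
  sv <- svd(training, nu = rank, nv = 0)
  u <- sv$u[, seq_len(rank), drop = FALSE]
  phi_raw <- crossprod(Conj(u), training)
  phi <- phi_raw / sv$d[seq_len(rank)]
  structure(list(phi = phi, singular_values = sv$d, spatial = u,
                 rank = as.integer(rank)),
            class = "realtime_basis")
}

#' Recover real-time spatial coefficients (ungated reconstruction)
#'
#' Least-squares solution of `min || d_im - Omega(E U Phi_rt) ||^2` by
#' conjugate gradient on the normal equations.  Each imaging readout
#' contributes one ky line of the unitary 2D FFT of the frame `U phi_t`.
#'
#' @param lines complex imaging lines `[n_im x matrix]`, centered-kx order
#' @param ky centered ky index per imaging readout
#' @param phi_im real-time temporal basis evaluated at the imaging readout
#'   times, `[L_rt x n_im]`
#' @param m image matrix size
#' @param tol relative residual-norm tolerance
#' @param max_iter CG iteration cap
#' @return complex spatial coefficient matrix `[m*m x L_rt]`
#' @export
solve_realtime_spatial <- function(lines, ky, phi_im, m, tol = 1e-6,
                                   max_iter = 50L) {
  if (nrow(lines) == 0) stop("solve_realtime_spatial: no imaging data")
  op <- make_encoding_operator(ky, phi_im, m)
  rhs <- op$adjoint(lines)
  cg_solve(function(u) op$adjoint(op$forward(u)), rhs, tol = tol,
           max_iter = max_iter)
}

# Encoding operator shared by the real-time and tensor-subspace solvers.
# forward: U [m*m x L] -> predicted lines [n x m] (centered-kx order);
# adjoint: lines -> [m*m x L].  Images are vec'd y-fastest.
#' @keywords internal
make_encoding_operator <- function(ky, phi, m, chunk = 2048L) {
  n <- length(ky)
  stopifnot(ncol(phi) == n)
  rows <- k_to_row(ky, m)
  ord <- centered_order(m)
  inv_ord <- order(ord)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  forward <- function(u) {
    out <- matrix(0+0i, n, m)
    for (ix in chunks) {
      y <- u %*% phi[, ix, drop = FALSE]           # m*m x nc frames
      nc <- length(ix)
      dim(y) <- c(m, m * nc)
      z <- stats::mvfft(y) / sqrt(m)               # FFT along y
      dim(z) <- c(m, m, nc)
      lin <- rep(rows[ix], each = m) + m * rep(0:(m - 1), times = nc) +
        m * m * rep(seq_len(nc) - 1L, each = m)
      sel <- matrix(z[lin], nc, m, byrow = TRUE)   # [nc x m] ky rows
      sel <- t(stats::mvfft(t(sel))) / sqrt(m)     # FFT along x
      out[ix, ] <- sel[, ord, drop = FALSE]
    }
    out
  }
  adjoint <- function(lines) {
    l <- nrow(phi)
    g <- matrix(0+0i, m * m, l)
    for (ix in chunks) {
      nc <- length(ix)
      sel <- lines[ix, inv_ord, drop = FALSE]
      sel <- t(stats::mvfft(t(sel), inverse = TRUE)) / sqrt(m)
      z <- array(0+0i, c(m, m, nc))
      lin <- rep(rows[ix], each = m) + m * rep(0:(m - 1), times = nc) +
        m * m * rep(seq_len(nc) - 1L, each = m)
      z[lin] <- t(sel)
      dim(z) <- c(m, m * nc)
      y <- stats::mvfft(z, inverse = TRUE) / sqrt(m)
      dim(y) <- c(m * m, nc)
      g <- g + y %*% Conj(t(phi[, ix, drop = FALSE]))
    }
    g
  }
  list(forward = forward, adjoint = adjoint)
}

# Conjugate gradient for Hermitian positive semidefinite systems.
#' @keywords internal
cg_solve <- function(amul, b, tol = 1e-6, max_iter = 50L) {
  x <- matrix(0+0i, nrow(b), ncol(b))
  r <- b
  p <- r
  rs <- sum(Mod(r)^2)
  rs0 <- rs
  if (rs0 == 0) return(x)
  for (i in seq_len(max_iter)) {
    if (sqrt(rs / rs0) < tol) break
    ap <- amul(p)
    alpha <- rs / Re(sum(Conj(p) * ap))
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(Mod(r)^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' Assign the T1-recovery index to each readout
#'
#' The index is the readout ordinal since the most recent inversion pulse.
#'
#' @param timestamps readout times (ms), nondecreasing within a scan
#' @param ir_pulse_times inversion pulse times (ms)
#' @return integer vector of indices (1..N)
#' @export
assign_t1_index <- function(timestamps, ir_pulse_times) {
  blk <- findInterval(timestamps, sort(ir_pulse_times))
  if (any(blk == 0)) stop("assign_t1_index: readout precedes first IR pulse")
  idx <- integer(length(timestamps))
  for (b in unique(blk)) {
    sel <- blk == b
    idx[sel] <- rank(timestamps[sel], ties.method = "first")
  }
  idx
}

# complex-safe per-group row means (template over blocks)
#' @keywords internal
#' @noRd
complex_rowsum_mean <- function(x, g) {
  cnt <- as.vector(table(g))
  (rowsum(Re(x), g) + 1i * rowsum(Im(x), g)) / cnt
}

#' Remove T1-recovery contrast from a training time series
#'
#' For each scan, the block template (mean over inversion blocks at equal
#' within-block readout index) is projected onto the single-block
#' T1-recovery subspace and subtracted from every block, leaving motion and
#' noise.  Operates on any multichannel time series whose columns are
#' readouts.
#'
#' @param training complex matrix `[channels x n_training_times]`
#' @param meta_tr metadata rows for the training readouts (needs `scan`,
#'   `ir_block_index`, `t1_index`)
#' @param block_basis a [compute_block_t1_basis] result
#' @return list with `residual` (same shape), `template_env` (per readout
#'   RMS template magnitude)
#' @export
remove_t1_contrast <- function(training, meta_tr, block_basis) {
  resid <- training
  env <- numeric(ncol(training))
  for (s in unique(meta_tr$scan)) {
    sel <- which(meta_tr$scan == s)
    taus <- sort(unique(meta_tr$t1_index[sel]))
    ti <- match(meta_tr$t1_index[sel], taus)
    tpl <- complex_rowsum_mean(t(training[, sel, drop = FALSE]), ti)
    q <- qr.Q(qr(block_basis$basis[taus, , drop = FALSE]))
    tpl <- q %*% (crossprod(Conj(q), tpl))       # Bloch-projected template
    resid[, sel] <- training[, sel, drop = FALSE] - t(tpl)[, ti, drop = FALSE]
    env[sel] <- sqrt(rowMeans(Mod(tpl)^2))[ti]
  }
  list(residual = resid, template_env = env)
}

# Multi-lag phase-slope shift estimator along the frequency-encode axis.
# Returns the apparent x-translation (pixels) per readout plus a
# reliability weight (accumulator magnitude).
#' @keywords internal
estimate_shift_series <- function(lines_unc, meta_tr, m) {
  kx <- fftshift_vec(seq(-m / 2, m / 2 - 1))
  dshift <- numeric(nrow(lines_unc))
  wrel <- numeric(nrow(lines_unc))
  for (s in unique(meta_tr$scan)) {
    sel <- which(meta_tr$scan == s)
    taus <- sort(unique(meta_tr$t1_index[sel]))
    ti <- match(meta_tr$t1_index[sel], taus)
    tpl <- complex_rowsum_mean(lines_unc[sel, , drop = FALSE], ti)
    r <- lines_unc[sel, , drop = FALSE] * Conj(tpl[ti, , drop = FALSE])
    o <- order(kx)
    oc <- o[abs(kx[o]) <= m / 4]
    ro <- r[, oc, drop = FALSE]
    # remove the time-invariant per-kx phase so the ramp is linear in kx
    rm <- colMeans(ro)
    ro <- ro * rep(Conj(rm) / pmax(Mod(rm), 1e-30), each = nrow(ro))
    nro <- ncol(ro)
    acc1 <- rowSums(ro[, -1, drop = FALSE] * Conj(ro[, -nro, drop = FALSE]))
    d1 <- -Arg(acc1) * m / (2 * pi)
    dnum <- d1 * Mod(acc1)
    dden <- Mod(acc1)
    for (lag in c(2L, 4L, 8L)) {
      if (nro <= lag) next
      dl_acc <- rowSums(ro[, -(1:lag), drop = FALSE] *
                          Conj(ro[, 1:(nro - lag), drop = FALSE]))
      dl <- d1 - Arg(dl_acc * exp(2i * pi * lag * d1 / m)) * m / (2 * pi * lag)
      wl <- lag^2 * Mod(dl_acc)
      dnum <- dnum + dl * wl
      dden <- dden + wl
    }
    dshift[sel] <- dnum / pmax(dden, 1e-30)
    wrel[sel] <- Mod(acc1)
  }
  list(shift = dshift, weight = wrel)
}

# Reliability-weighted circular Gaussian smoothing.
#' @keywords internal
#' @noRd
gauss_smooth_weighted <- function(x, w, sd_samp) {
  n <- length(x)
  d <- c(0:(n - 1))
  d <- ifelse(d > n / 2, d - n, d)
  h <- exp(-0.5 * (d / sd_samp)^2)
  h <- h / sum(h)
  fh <- stats::fft(h)
  num <- Re(stats::fft(stats::fft(w * x) * fh, inverse = TRUE)) / n
  den <- Re(stats::fft(stats::fft(w) * fh, inverse = TRUE)) / n
  num / pmax(den, 1e-6 * max(den))
}

# low-pass keeping DC, brick wall at `cutoff` Hz
#' @keywords internal
#' @noRd
lowpass_keep_dc <- function(x, dt, cutoff) {
  mu <- mean(x)
  as.vector(bandpass_cols(matrix(x - mu), dt, c(0, cutoff))) + mu
}

#' Respiratory and cardiac binning by modified k-means
#'
#' Stages: (i) T1-contrast removal using the Bloch block model
#' ([remove_t1_contrast]); (ii) respiratory displacement estimation from
#' multi-lag k-space phase slopes, reliability-smoothed and band-limited to
#' the respiratory band; (iii) k-means over the displacement feature with
#' `k_resp` clusters, ordered so the most populated cluster
#' (end-expiration dwell) is bin 1; (iv) cardiac lock-in phase tracking at
#' the spectral-peak heart rate on respiratory-shift-corrected,
#' contrast-sign-rectified residual profiles, combined across an
#' automatically selected heart ROI by a rank-1 SVD; (v) per-scan phase
#' anchoring so end-diastole (maximal projected heart mass late in the
#' recovery) is phase zero; (vi) k-means of `(cos, sin)` of the anchored
#' phase with `k_card` clusters ordered by circular mean.  Imaging readouts
#' inherit the bins of the nearest-in-time training readout of the same
#' scan.  Both scans are processed together and share bins.
#'
#' @param ds a [acquire] result (both scans)
#' @param block_basis single-block T1 basis from [compute_block_t1_basis]
#' @param k_resp,k_card number of respiratory / cardiac bins
#' @param resp_cutoff respiratory band upper edge (Hz)
#' @param card_search heart-rate search band (Hz)
#' @param lockin_bw lock-in low-pass half-bandwidth (Hz); keep below the
#'   inversion-block repetition rate to reject contrast sidebands
#' @param roi_energy fraction of residual energy defining the heart ROI
#' @param seed k-means seed
#' @return object of class `bin_assignment`: data frame `bins` with
#'   per-readout `cardiac_bin`, `resp_bin`, `t1_index`, `scan`, plus
#'   ordering metadata and diagnostics (`heart_rate_hz`, `resp_feature`,
#'   `cardiac_phase`)
#' @export
bin_motion <- function(ds, block_basis, k_resp = 5L, k_card = 10L,
                       resp_cutoff = 2.2, card_search = c(3, 9),
                       lockin_bw = 0.25, roi_energy = 0.6, seed = 1L) {
  meta <- ds$meta
  tr_sel <- which(meta$is_training)
  meta_tr <- meta[tr_sel, ]
  m <- ncol(ds$lines)
  nn <- ds$seq$readouts_per_period
  inv_ord <- order(centered_order(m))
  lines_unc <- ds$lines[tr_sel, inv_ord, drop = FALSE]
  scans <- unique(meta_tr$scan)
  dt <- diff(meta_tr$timestamp[meta_tr$scan == scans[1]])[1] / 1000
  n_tr <- nrow(meta_tr)

  ## respiratory feature -------------------------------------------------
  sh <- estimate_shift_series(lines_unc, meta_tr, m)
  resp_feat <- numeric(n_tr)
  for (s in scans) {
    sel <- which(meta_tr$scan == s)
    mf <- stats::runmed(sh$shift[sel], 7)
    w <- pmin(sh$weight[sel] / stats::median(sh$weight[sel]), 2)^2
    st1 <- gauss_smooth_weighted(mf, w, 0.05 / dt)
    resp_feat[sel] <- lowpass_keep_dc(st1, dt, resp_cutoff)
  }
  if (stats::sd(resp_feat) < 1e-12) {
    resp_bin_tr <- rep(1L, n_tr)
    if (k_resp > 1L) {
      stop("bin_motion: no respiratory motion detected; k_resp exceeds the number of distinct states")
    }
  } else {
    set.seed(seed)
    km_r <- stats::kmeans(resp_feat, centers = k_resp, nstart = 25L,
                          iter.max = 300L, algorithm = "Lloyd")
    if (min(km_r$size) == 0L) {
      stop("bin_motion: empty respiratory cluster; reduce k_resp")
    }
    cen <- as.numeric(km_r$centers)
    dwell <- which.max(tabulate(km_r$cluster, k_resp))
    r_order <- order(abs(cen - cen[dwell]))
    r_map <- integer(k_resp)
    r_map[r_order] <- seq_len(k_resp)
    resp_bin_tr <- r_map[km_r$cluster]
  }

  ## cardiac phase -------------------------------------------------------
  kx <- fftshift_vec(seq(-m / 2, m / 2 - 1))
  lines_corr <- lines_unc * exp(2i * pi * outer(resp_feat, kx) / m)
  prof <- t(stats::mvfft(t(lines_corr), inverse = TRUE)) / sqrt(m)
  rem <- remove_t1_contrast(t(prof), meta_tr, block_basis)
  resid <- t(rem$residual)                      # [n_tr x m]
  # shared heart-rate estimate from smoothed average spectra
  fgrid <- seq(card_search[1], card_search[2], by = 0.02)
  pacc <- numeric(length(fgrid))
  for (s in scans) {
    sel <- which(meta_tr$scan == s)
    n <- length(sel)
    f <- (0:(n - 1)) / (n * dt)
    half <- f <= 1 / (2 * dt)
    p <- rowSums(Mod(stats::mvfft(resid[sel, , drop = FALSE]))^2)
    pacc <- pacc + stats::approx(f[half], p[half], xout = fgrid,
                                 rule = 2)$y
  }
  pacc <- as.numeric(stats::filter(pacc, rep(1 / 9, 9), sides = 2,
                                   circular = TRUE))
  fc <- fgrid[which.max(pacc)]
  theta <- numeric(n_tr)
  for (s in scans) {
    sel <- which(meta_tr$scan == s)
    x <- resid[sel, , drop = FALSE]
    n <- length(sel)
    f <- (0:(n - 1)) / (n * dt)
    fmag <- pmin(f, 1 / dt - f)
    en_col <- colSums(Mod(x)^2)
    oc <- order(en_col, decreasing = TRUE)
    rc <- oc[cumsum(en_col[oc]) <= roi_energy * sum(en_col)]
    if (length(rc) < 4) rc <- oc[seq_len(min(4, length(oc)))]
    xr <- x[, rc, drop = FALSE]
    # sign-rectify the T1-contrast envelope per column: adjacent-index
    # residuals correlate across blocks with the envelope sign product
    taus <- sort(unique(meta_tr$t1_index[sel]))
    ti <- match(meta_tr$t1_index[sel], taus)
    blk <- meta_tr$ir_block_index[sel]
    nt <- length(taus)
    nb <- max(blk)
    for (j in seq_along(rc)) {
      v <- matrix(0+0i, nt, nb)
      v[cbind(ti, blk)] <- xr[, j]
      corr <- Re(rowSums(v[-1, , drop = FALSE] * Conj(v[-nt, , drop = FALSE])))
      corr <- as.numeric(stats::filter(corr, rep(1 / 7, 7), sides = 2,
                                       circular = TRUE))
      sgn <- cumprod(c(1, ifelse(corr >= 0, 1, -1)))
      xr[, j] <- xr[, j] * sgn[ti]
    }
    osc <- exp(-2i * pi * fc * (0:(n - 1)) * dt)
    z <- xr * osc
    fz <- stats::mvfft(z)
    fz[fmag > lockin_bw, ] <- 0
    z <- stats::mvfft(fz, inverse = TRUE) / n
    sv <- svd(z, nu = 0, nv = 1)
    zt <- z %*% Conj(sv$v[, 1])
    theta[sel] <- Arg(zt) + 2 * pi * fc * (0:(n - 1)) * dt
  }
  # per-scan anchoring: end-diastole (max heart mass late in recovery) = 0
  prof_mag <- Mod(prof)
  en_all <- colSums(Mod(resid)^2)
  ohc <- order(en_all, decreasing = TRUE)
  heart_cols <- ohc[cumsum(en_all[ohc]) <= roi_energy * sum(en_all)]
  if (length(heart_cols) < 4) heart_cols <- ohc[seq_len(min(4, m))]
  mass <- rowSums(prof_mag[, heart_cols, drop = FALSE])
  late <- meta_tr$t1_index > 0.7 * nn
  for (s in scans) {
    sel <- which(meta_tr$scan == s)
    lsel <- sel[late[sel]]
    sector <- floor(((theta[lsel] %% (2 * pi)) / (2 * pi)) * 24) + 1
    msec <- tapply(mass[lsel], factor(sector, levels = 1:24), mean)
    msec[is.na(msec)] <- mean(mass[lsel])
    msec <- as.numeric(stats::filter(msec, rep(1 / 5, 5), sides = 2,
                                     circular = TRUE))
    th0 <- (which.max(msec) - 0.5) / 24 * 2 * pi
    theta[sel] <- theta[sel] - th0
  }
  set.seed(seed + 1L)
  km_c <- stats::kmeans(cbind(cos(theta), sin(theta)), centers = k_card,
                        nstart = 25L, iter.max = 300L, algorithm = "Lloyd")
  if (min(km_c$size) == 0L) {
    stop("bin_motion: empty cardiac cluster; reduce k_card")
  }
  cmn <- vapply(seq_len(k_card), function(j) {
    Arg(mean(exp(1i * theta[km_c$cluster == j]))) %% (2 * pi)
  }, numeric(1))
  c_order <- order(cmn)
  c_map <- integer(k_card)
  c_map[c_order] <- seq_len(k_card)
  card_bin_tr <- c_map[km_c$cluster]

  ## propagate to all readouts ------------------------------------------
  card_bin <- integer(nrow(meta))
  resp_bin <- integer(nrow(meta))
  for (s in unique(meta$scan)) {
    sel <- which(meta$scan == s)
    tsel <- which(meta_tr$scan == s)
    ts_tr <- meta_tr$timestamp[tsel]
    left <- pmax(findInterval(meta$timestamp[sel], ts_tr), 1L)
    right <- pmin(left + 1L, length(tsel))
    use_r <- abs(ts_tr[right] - meta$timestamp[sel]) <
      abs(ts_tr[left] - meta$timestamp[sel])
    nearest <- ifelse(use_r, right, left)
    card_bin[sel] <- card_bin_tr[tsel][nearest]
    resp_bin[sel] <- resp_bin_tr[tsel][nearest]
  }
  structure(list(bins = data.frame(readout_id = meta$readout_id,
                                   scan = meta$scan,
                                   is_training = meta$is_training,
                                   cardiac_bin = card_bin,
                                   resp_bin = resp_bin,
                                   t1_index = meta$t1_index),
                 k_card = as.integer(k_card), k_resp = as.integer(k_resp),
                 end_expiration_bin = 1L, end_diastole_bin = 1L,
                 heart_rate_hz = fc, resp_feature = resp_feat,
                 cardiac_phase = theta, seed = as.integer(seed)),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf(paste0("bin assignment: %d readouts, %d cardiac x %d ",
                     "respiratory bins (heart rate %.2f Hz)\n"),
              nrow(x$bins), x$k_card, x$k_resp, x$heart_rate_hz))
  invisible(x)
}

#' Score a bin assignment against simulator ground truth
#'
#' Fraction of readouts whose predicted bin equals the true bin or an
#' adjacent one (cyclically for cardiac bins).
#'
#' @param bins a [bin_motion] result
#' @param ds the [acquire] dataset it was computed from
#' @return list with `cardiac`, `resp` adjacent-accuracy fractions
#' @export
bin_accuracy <- function(bins, ds) {
  tb <- true_bins(ds, bins$k_card, bins$k_resp)
  dc <- abs(bins$bins$cardiac_bin - tb$cardiac_bin)
  dc <- pmin(dc, bins$k_card - dc)          # cyclic distance
  dr <- abs(bins$bins$resp_bin - tb$resp_bin)
  list(cardiac = mean(dc <= 1), resp = mean(dr <= 1))
}
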