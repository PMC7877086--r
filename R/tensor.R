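# Bloch-constrained low-rank tensor completion of the binned training
# tensor, HOSVD factor extraction, and wavelet-regularized spatial-basis
# recovery.
#
# The multidimensional image is modeled as a low-rank tensor whose mode-1
# (spatial/k-readout) unfolding factorizes as U_x Phi, with the temporal
# subspace Phi assembled from per-dimension factors (cardiac, respiratory,
# T1 recovery) and a core tensor.  Tensor mode order throughout:
# (k-readout, cardiac, respiratory, t1), with the t1 dimension being the
# 2N-length pre+post concatenation.  Mode-1 unfolding uses column-major
# (cardiac-fastest) column ordering, so
#   D_(1) = U_k G_(1) (U_t1 (x) U_r (x) U_c)^T .

#' Mode-n unfolding of a 4-way array
#' @keywords internal
tensor_unfold <- function(a, mode) {
  d <- dim(a)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(a, perm), d[mode])
}

#' Inverse of [tensor_unfold]
#' @keywords internal
tensor_fold <- function(mat, mode, dims) {
  perm <- c(mode, setdiff(seq_along(dims), mode))
  a <- array(mat, dims[perm])
  aperm(a, order(perm))
}

#' Mode-n product with the conjugate transpose of a factor (projection to
#' coefficients) or with a factor (expansion)
#' @keywords internal
tensor_mode_mult <- function(a, m, mode) {
  d <- dim(a)
  x <- m %*% tensor_unfold(a, mode)
  d[mode] <- nrow(m)
  tensor_fold(x, mode, d)
}

#' Form the binned 4-way training tensor
#'
#' Cell `(k, c, r, tau)` holds the mean of all training lines assigned to
#' cardiac bin c, respiratory bin r, and T1 index tau (pre-contrast scans
#' occupy tau = 1..N, post-contrast tau = N+1..2N).
#'
#' @param ds a [acquire] result
#' @param bins a [bin_motion] result covering all training readouts
#' @return object of class `training_tensor`: complex `data`
#'   `[matrix x k_card x k_resp x 2N]`, logical `mask` of observed cells,
#'   integer `counts`, and dimensions
#' @export
form_training_tensor <- function(ds, bins) {
  meta <- ds$meta
  tr <- which(meta$is_training)
  if (!length(tr)) stop("form_training_tensor: no training readouts")
  b <- bins$bins[tr, ]
  m <- ncol(ds$lines)
  nn <- ds$seq$readouts_per_period
  kc <- bins$k_card
  kr <- bins$k_resp
  tau <- b$t1_index + nn * as.integer(b$scan == "post")
  cell <- b$cardiac_bin + kc * (b$resp_bin - 1L) + kc * kr * (tau - 1L)
  lines <- ds$lines[tr, , drop = FALSE]
  sums <- rowsum(Re(lines), cell) + 1i * rowsum(Im(lines), cell)
  counts <- as.vector(table(cell))
  ids <- sort(unique(cell))
  data <- array(0+0i, c(m, kc, kr, 2L * nn))
  cnt <- array(0L, c(kc, kr, 2L * nn))
  cnt[ids] <- counts
  # scatter means: cells indexed along (c, r, tau); k fills the first mode
  means <- sums / counts
  for (i in seq_along(ids)) {
    id <- ids[i] - 1L
    cc <- id %% kc + 1L
    rr <- (id %/% kc) %% kr + 1L
    tt <- id %/% (kc * kr) + 1L
    data[, cc, rr, tt] <- means[i, ]
  }
  mask <- cnt > 0L
  if (!any(mask)) stop("form_training_tensor: all cells empty")
  structure(list(data = data, mask = mask, counts = cnt,
                 k_card = kc, k_resp = kr, n = nn, m = m),
            class = "training_tensor")
}

#' @export
print.training_tensor <- function(x, ...) {
  cat(sprintf("training tensor %d x %d x %d x %d, %.1f%% of cells observed\n",
              x$m, x$k_card, x$k_resp, 2 * x$n, 100 * mean(x$mask)))
  invisible(x)
}

# initial fill: per-fiber regression onto the T1 subspace where the fiber
# has enough observed entries; remaining fibers use the per-k mean
# coefficient.  mask4 is the full 4-way observation mask.
#' @keywords internal
#' @noRd
init_completion <- function(data, mask4, u) {
  m <- dim(data)[1]
  kc <- dim(data)[2]
  kr <- dim(data)[3]
  lt <- ncol(u)
  filled <- data
  coef_acc <- vector("list", m)
  pend <- list()
  k_uniform <- all(apply(mask4, c(2, 3, 4), function(z) all(z) || !any(z)))
  for (cc in seq_len(kc)) {
    for (rr in seq_len(kr)) {
      if (k_uniform) {
        obs <- which(mask4[1, cc, rr, ])
        if (length(obs) >= lt + 2) {
          uo <- u[obs, , drop = FALSE]
          rhs <- crossprod(Conj(uo), t(data[, cc, rr, obs, drop = FALSE][, 1, 1, ]))
          gram <- crossprod(Conj(uo), uo)
          gram <- gram + diag(1e-9 * max(Re(diag(gram)), 1e-300), lt)
          coef <- solve(gram, rhs)                         # lt x m
          filled[, cc, rr, ] <- t(u %*% coef)
          filled[, cc, rr, obs] <- data[, cc, rr, obs]
          for (k in seq_len(m)) {
            coef_acc[[k]] <- cbind(coef_acc[[k]], coef[, k])
          }
        } else {
          pend <- c(pend, list(c(cc, rr)))
        }
      } else {
        for (k in seq_len(m)) {
          obs <- which(mask4[k, cc, rr, ])
          if (length(obs) >= lt + 2) {
            uo <- u[obs, , drop = FALSE]
            gram <- crossprod(Conj(uo), uo)
            gram <- gram + diag(1e-9 * max(Re(diag(gram)), 1e-300), lt)
            coef <- solve(gram, crossprod(Conj(uo), data[k, cc, rr, obs]))
            filled[k, cc, rr, ] <- u %*% coef
            filled[k, cc, rr, obs] <- data[k, cc, rr, obs]
            coef_acc[[k]] <- cbind(coef_acc[[k]], coef)
          } else {
            pend <- c(pend, list(c(k, cc, rr)))
          }
        }
      }
    }
  }
  if (length(pend)) {
    mean_coef <- vapply(coef_acc, function(x) {
      if (is.null(x)) rep(0+0i, lt) else rowMeans(x)
    }, complex(lt))                                      # lt x m
    fallback <- t(u %*% mean_coef)                       # m x 2N
    for (p in pend) {
      if (k_uniform) {
        obs <- which(mask4[1, p[1], p[2], ])
        filled[, p[1], p[2], ] <- fallback
        if (length(obs)) filled[, p[1], p[2], obs] <- data[, p[1], p[2], obs]
      } else {
        obs <- which(mask4[p[1], p[2], p[3], ])
        filled[p[1], p[2], p[3], ] <- fallback[p[1], ]
        if (length(obs)) {
          filled[p[1], p[2], p[3], obs] <- data[p[1], p[2], p[3], obs]
        }
      }
    }
  }
  filled
}

#' Bloch-constrained low-rank tensor completion
#'
#' Alternating projection algorithm: (a) project the t1 mode onto the span
#' of the dictionary basis `U_T1` (the Bloch constraint; this is also the
#' t1-mode rank truncation), (b) truncate the multilinear rank of the
#' remaining modes by HOSVD, (c) restore the observed entries.  Iterated to
#' a relative-change tolerance.  Missing cells are initialized by
#' subspace regression along each (k, c, r) fiber.
#'
#' @param tt a [form_training_tensor] result (or a compatible list with
#'   `data` and `mask` for synthetic use)
#' @param t1_basis a [compute_t1_basis] result spanning the 2N-length
#'   concatenated curves (or any orthonormal basis matrix)
#' @param ranks multilinear ranks `(L_k, L_c, L_r)` for modes 1..3; `NA`
#'   leaves a mode untruncated
#' @param tol relative-change stopping tolerance
#' @param max_iter iteration cap
#' @param verbose print progress
#' @return completed complex array, with attributes `iterations` and
#'   `rel_change`
#' @export
complete_training_tensor <- function(tt, t1_basis, ranks = c(NA, 6, 4),
                                     tol = 1e-6, max_iter = 250L,
                                     verbose = FALSE) {
  u <- if (inherits(t1_basis, "t1_basis")) t1_basis$basis else t1_basis
  data <- tt$data
  d <- dim(data)
  if (nrow(u) != d[4]) {
    stop("complete_training_tensor: T1 basis length does not match the t1 mode")
  }
  mask4 <- if (length(dim(tt$mask)) == 3) {
    rep_mask4(tt$mask, d[1])      # training lines observe every k sample
  } else {
    tt$mask
  }
  obs_idx <- which(mask4)
  obs_val <- data[obs_idx]
  x <- init_completion(data, mask4, u)
  uh <- Conj(t(u))
  prev <- x
  it <- 0L
  rel <- Inf
  for (it in seq_len(max_iter)) {
    # (a) Bloch projection of the t1 mode
    x4 <- tensor_unfold(x, 4)
    x <- tensor_fold(u %*% (uh %*% x4), 4, d)
    # (b) HOSVD truncation of modes 1..3
    for (mode in 1:3) {
      lk <- ranks[mode]
      if (is.na(lk) || lk >= d[mode]) next
      xm <- tensor_unfold(x, mode)
      g <- xm %*% Conj(t(xm))
      ev <- eigen(g, symmetric = TRUE)
      uk <- ev$vectors[, seq_len(lk), drop = FALSE]
      x <- tensor_fold(uk %*% (Conj(t(uk)) %*% xm), mode, d)
    }
    # (c) data consistency
    x[obs_idx] <- obs_val
    rel <- sqrt(sum(Mod(x - prev)^2) / max(sum(Mod(prev)^2), 1e-300))
    if (verbose && it %% 25 == 0) {
      message(sprintf("  completion iter %d: rel change %.3e", it, rel))
    }
    if (rel < tol) break
    prev <- x
  }
  if (rel >= tol) {
    warning(sprintf(paste0("complete_training_tensor: not converged after ",
                           "%d iterations (rel change %.2e); returning ",
                           "best iterate"), max_iter, rel))
  }
  # return the model (projected) iterate, not the data-consistent one:
  # observed cells are often single noisy lines, and the low-rank x
  # Bloch-subspace model is the denoiser
  x4 <- tensor_unfold(x, 4)
  x <- tensor_fold(u %*% (uh %*% x4), 4, d)
  for (mode in 1:3) {
    lk <- ranks[mode]
    if (is.na(lk) || lk >= d[mode]) next
    xm <- tensor_unfold(x, mode)
    g <- xm %*% Conj(t(xm))
    ev <- eigen(g, symmetric = TRUE)
    uk <- ev$vectors[, seq_len(lk), drop = FALSE]
    x <- tensor_fold(uk %*% (Conj(t(uk)) %*% xm), mode, d)
  }
  attr(x, "iterations") <- it
  attr(x, "rel_change") <- rel
  x
}

#' @keywords internal
#' @noRd
rep_mask4 <- function(mask3, m) {
  aperm(array(mask3, c(dim(mask3), m)), c(4, 1, 2, 3))
}

#' Extract HOSVD factors and assemble the temporal subspace
#'
#' Cardiac and respiratory factor matrices come from the mode SVDs of the
#' completed training tensor; the T1 factor is fixed to the Bloch
#' dictionary basis.  The core is the all-mode coefficient tensor and the
#' temporal subspace is `Phi = G_(1) (U_t1 (x) U_r (x) U_c)^T`, whose
#' columns are indexed by `(c, r, tau)` with c fastest.
#'
#' @param completed completed tensor from [complete_training_tensor]
#' @param t1_basis the `t1_basis` used for completion
#' @param ranks `(L_k, L_c, L_r)`; `NA` keeps the full mode dimension
#' @return object of class `factored_image` with `u_c`, `u_r`, `u_t1`,
#'   `u_k`, `core`, `phi`, bin/frame dimensions, and an empty `u_x` slot
#' @export
extract_factors <- function(completed, t1_basis, ranks = c(24, 6, 4)) {
  u_t1 <- if (inherits(t1_basis, "t1_basis")) t1_basis$basis else t1_basis
  d <- dim(completed)
  if (any(ranks > d[1:3], na.rm = TRUE)) {
    stop("extract_factors: rank exceeds mode dimension")
  }
  facs <- vector("list", 3)
  for (mode in 1:3) {
    xm <- tensor_unfold(completed, mode)
    lk <- ranks[mode]
    if (is.na(lk)) lk <- d[mode]
    g <- xm %*% Conj(t(xm))
    ev <- eigen(g, symmetric = TRUE)
    facs[[mode]] <- ev$vectors[, seq_len(min(lk, d[mode])), drop = FALSE]
  }
  core <- completed
  core <- tensor_mode_mult(core, Conj(t(facs[[1]])), 1)
  core <- tensor_mode_mult(core, Conj(t(facs[[2]])), 2)
  core <- tensor_mode_mult(core, Conj(t(facs[[3]])), 3)
  core <- tensor_mode_mult(core, Conj(t(u_t1)), 4)
  g1 <- tensor_unfold(core, 1)        # L_k x (L_c L_r L_t1)
  kron3 <- kronecker(u_t1, kronecker(facs[[3]], facs[[2]])) # (c fastest)
  phi <- g1 %*% t(kron3)
  structure(list(u_k = facs[[1]], u_c = facs[[2]], u_r = facs[[3]],
                 u_t1 = u_t1, core = core, phi = phi,
                 k_card = d[2], k_resp = d[3], n_tau = d[4],
                 rank = nrow(phi), u_x = NULL),
            class = "factored_image")
}

#' @export
print.factored_image <- function(x, ...) {
  cat(sprintf(paste0("factored image: rank %d temporal subspace over ",
                     "%d cardiac x %d respiratory bins x %d frames%s\n"),
              x$rank, x$k_card, x$k_resp, x$n_tau,
              if (is.null(x$u_x)) " (spatial basis not yet solved)" else ""))
  invisible(x)
}

#' Column of the temporal subspace for a bin/frame triple
#' @param fi a [extract_factors] result
#' @param cardiac_bin,resp_bin,tau 1-based indices
#' @keywords internal
phi_column_index <- function(fi, cardiac_bin, resp_bin, tau) {
  stopifnot(all(cardiac_bin >= 1 & cardiac_bin <= fi$k_card),
            all(resp_bin >= 1 & resp_bin <= fi$k_resp),
            all(tau >= 1 & tau <= fi$n_tau))
  cardiac_bin + fi$k_card * (resp_bin - 1L) +
    fi$k_card * fi$k_resp * (tau - 1L)
}

#' Reconstruction configuration
#'
#' @param ranks multilinear ranks `(L_k, L_c, L_r)` of the training-tensor
#'   HOSVD; the t1-mode rank equals the dictionary basis rank
#' @param lambda wavelet regularization weight; `NULL` scales
#'   `lambda_rel` by the peak wavelet coefficient of the adjoint image
#' @param lambda_rel relative weight used when `lambda` is `NULL`
#' @param wavelet_levels decomposition levels of the Daubechies-4 transform
#' @param max_iter FISTA iteration cap
#' @param tol relative objective-change tolerance
#' @export
recon_config <- function(ranks = c(32, 6, 4), lambda = NULL,
                         lambda_rel = 1e-4, wavelet_levels = 3L,
                         max_iter = 100L, tol = 1e-6) {
  if (!is.null(lambda) && lambda < 0) stop("recon_config: lambda must be >= 0")
  stopifnot(all(ranks[!is.na(ranks)] >= 1))
  structure(list(ranks = ranks, lambda = lambda, lambda_rel = lambda_rel,
                 wavelet_levels = as.integer(wavelet_levels),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "recon_config")
}

#' Wavelet-regularized spatial-basis recovery
#'
#' Solves `min_U ||d_im - Omega(E U Phi)||^2 + lambda ||W U||_1` by
#' monotone FISTA (proximal gradient with momentum and restart), where `E`
#' is the unitary 2D Fourier transform, `Omega` samples one ky line per
#' imaging readout, and `W` applies the orthonormal Daubechies-4 transform
#' to each spatial basis column.
#'
#' @param ds a [acquire] result
#' @param bins a [bin_motion] result
#' @param fi a [extract_factors] result
#' @param config a [recon_config]
#' @param solver `"auto"` (CG when `lambda = 0`, FISTA otherwise),
#'   `"fista"`, or `"cg"` (least-squares only)
#' @param verbose print objective progress
#' @return `fi` with `u_x` (`[m*m x L]`) filled in and convergence
#'   diagnostics in `attr(fi$u_x, "objective")`
#' @export
solve_spatial_basis <- function(ds, bins, fi, config = recon_config(),
                                solver = c("auto", "fista", "cg"),
                                verbose = FALSE) {
  solver <- match.arg(solver)
  meta <- ds$meta
  im <- which(!meta$is_training)
  if (!length(im)) stop("solve_spatial_basis: no imaging data")
  b <- bins$bins[im, ]
  nn <- ds$seq$readouts_per_period
  m <- ncol(ds$lines)
  tau <- b$t1_index + nn * as.integer(b$scan == "post")
  cols <- phi_column_index(fi, b$cardiac_bin, b$resp_bin, tau)
  phi_obs <- fi$phi[, cols, drop = FALSE]
  # precondition: normalize the rows of Phi (their norms span orders of
  # magnitude, which stalls proximal gradient); the scales are restored in
  # the solution columns and absorbed into per-column thresholds
  row_scale <- sqrt(rowSums(Mod(phi_obs)^2))
  row_scale[row_scale == 0] <- 1
  phi_obs <- phi_obs / row_scale
  d_im <- ds$lines[im, , drop = FALSE]
  ky <- meta$ky_index[im]
  op <- make_encoding_operator(ky, phi_obs, m)
  lev <- config$wavelet_levels
  wt <- function(u) apply(u, 2, function(col) as.vector(dwt2(matrix(col, m, m), lev)))
  wti <- function(u) apply(u, 2, function(col) as.vector(idwt2(matrix(col, m, m), lev)))
  atb <- op$adjoint(d_im)
  lambda <- config$lambda %||% (config$lambda_rel * max(Mod(wt(atb))))
  if (solver == "auto") solver <- if (lambda == 0) "cg" else "fista"
  if (solver == "cg") {
    if (lambda != 0) stop("solve_spatial_basis: cg solver requires lambda = 0")
    v <- cg_solve(function(u) op$adjoint(op$forward(u)), atb,
                  tol = config$tol, max_iter = config$max_iter)
    fi$u_x <- sweep(v, 2, row_scale, "/")
    attr(fi$u_x, "objective") <- sum(Mod(op$forward(v) - d_im)^2)
    attr(fi$u_x, "lambda") <- 0
    return(fi)
  }
  # Lipschitz constant of the data term by power iteration
  set.seed(0)
  v <- matrix(complex(real = stats::rnorm(nrow(atb) * ncol(atb)),
                      imaginary = stats::rnorm(nrow(atb) * ncol(atb))),
              nrow(atb), ncol(atb))
  for (i in 1:8) {
    v <- op$adjoint(op$forward(v))
    nv <- sqrt(sum(Mod(v)^2))
    v <- v / nv
  }
  lip <- 2 * nv * 1.05
  step <- 1 / lip
  u <- atb * 0
  z <- u
  tmom <- 1
  obj <- numeric(0)
  # the l1 penalty acts on the energy-normalized (preconditioned) basis
  # columns, so every temporal direction is shrunk on the same scale
  soft_cols <- function(w) soft_threshold(w, step * lambda)
  fval <- function(u) {
    r <- op$forward(u) - d_im
    sum(Mod(r)^2) + lambda * sum(Mod(wt(u)))
  }
  f_prev <- fval(u)
  for (it in seq_len(config$max_iter)) {
    grad <- 2 * op$adjoint(op$forward(z) - d_im)
    u_new <- wti(soft_cols(wt(z - step * grad)))
    f_new <- fval(u_new)
    if (f_new > f_prev) {            # restart momentum
      tmom <- 1
      u_new <- wti(soft_cols(wt(u - step * 2 *
                                  op$adjoint(op$forward(u) - d_im))))
      f_new <- fval(u_new)
    }
    t_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    z <- u_new + ((tmom - 1) / t_new) * (u_new - u)
    u <- u_new
    tmom <- t_new
    obj <- c(obj, f_new)
    if (verbose && it %% 5 == 0) {
      message(sprintf("  FISTA iter %d: objective %.6e", it, f_new))
    }
    if (abs(f_prev - f_new) < config$tol * max(f_prev, 1e-300)) {
      f_prev <- f_new
      break
    }
    f_prev <- f_new
  }
  fi$u_x <- sweep(u, 2, row_scale, "/")    # undo the preconditioning
  attr(fi$u_x, "objective") <- obj
  attr(fi$u_x, "lambda") <- lambda
  fi
}

#' Reconstruct images for selected bins and inversion-time frames
#'
#' @param fi a [solve_spatial_basis] result (with `u_x`)
#' @param cardiac_bin,resp_bin scalar bin indices
#' @param tau integer vector of t1 frame indices (1..2N)
#' @return complex array `[m x m x length(tau)]`
#' @export
reconstruct_image <- function(fi, cardiac_bin, resp_bin, tau) {
  if (is.null(fi$u_x)) stop("reconstruct_image: spatial basis not solved")
  cols <- phi_column_index(fi, cardiac_bin, resp_bin, tau)
  y <- fi$u_x %*% fi$phi[, cols, drop = FALSE]
  m <- as.integer(sqrt(nrow(y)))
  array(y, c(m, m, length(tau)))
}
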