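# Joint pre/post-contrast IR-FLASH signal model.
#
# The sequence is a continuous low-flip-angle FLASH readout train with
# repeated non-selective inversion pulses every `recovery_period` ms.  One
# inversion block holds N = `readouts_per_period` TRs.  Within a block the
# longitudinal magnetization follows the standard Look-Locker recursion:
# inversion scales m by g(b), each TR applies excitation (cos(alpha)) and
# free relaxation toward m0 (E1 = exp(-TR/T1)), driving m to the apparent
# steady state M* = m0 (1 - E1) / (1 - E1 cos(alpha)) with apparent rate
# (E1 cos(alpha)) per TR.  The readout signal is the longitudinal
# magnetization at each excitation times sin(alpha).

#' Acquisition timing and geometry parameters
#'
#' Defaults reproduce the small-animal protocol this package targets:
#' 128x128 matrix over a 40 mm field of view (0.3125 mm in-plane voxels),
#' TR/TE = 7.0/2.4 ms, 5 degree nominal flip angle, 85 inversion pulses with
#' a recovery period of N x TR = 2912 ms (~2.9 s) holding N = 416 readouts.
#'
#' @param tr repetition time (ms)
#' @param te echo time (ms, informational; no T2* decay is modeled)
#' @param flip_nominal nominal FLASH flip angle (degrees)
#' @param recovery_period time between adjacent inversion pulses (ms)
#' @param n_ir_pulses number of inversion blocks per scan
#' @param readouts_per_period number of readouts N per inversion block
#' @param matrix image matrix size (square)
#' @param fov field of view (mm)
#' @param slice_thickness slice thickness (mm)
#' @return an object of class `seq_params`
#' @export
seq_params <- function(tr = 7.0, te = 2.4, flip_nominal = 5,
                       recovery_period = 2912, n_ir_pulses = 85,
                       readouts_per_period = 416, matrix = 128, fov = 40,
                       slice_thickness = 1.5) {
  stopifnot(tr > 0, n_ir_pulses >= 1, readouts_per_period >= 1,
            matrix > 0, fov > 0)
  if (readouts_per_period * tr > recovery_period + tr) {
    stop("seq_params: readouts_per_period * tr exceeds the recovery period")
  }
  structure(list(tr = tr, te = te, flip_nominal = flip_nominal,
                 recovery_period = recovery_period,
                 n_ir_pulses = as.integer(n_ir_pulses),
                 readouts_per_period = as.integer(readouts_per_period),
                 matrix = as.integer(matrix), fov = fov,
                 slice_thickness = slice_thickness),
            class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(paste0("IR-FLASH sequence: TR %.1f ms, flip %.1f deg, ",
                     "%d x %d over %.0f mm (%.4f mm voxels)\n"),
              x$tr, x$flip_nominal, x$matrix, x$matrix, x$fov,
              in_plane_voxel_size(x)))
  cat(sprintf("  %d IR blocks of N = %d readouts, recovery period %.0f ms\n",
              x$n_ir_pulses, x$readouts_per_period, x$recovery_period))
  invisible(x)
}

#' Tissue relaxation and excitation parameters
#'
#' @param t1_pre native (pre-contrast) T1 (ms)
#' @param t1_post post-contrast T1 (ms); must be shorter than `t1_pre`
#' @param m0 thermal equilibrium longitudinal magnetization (arbitrary units)
#' @param alpha actual FLASH flip angle experienced by the tissue (degrees)
#' @param b inversion efficiency in `[-1, 0]`: -1 is a perfect inversion,
#'   0 means the pulse leaves the magnetization untouched.  The longitudinal
#'   magnetization is scaled by `1 + 2 b` at each inversion.
#' @return an object of class `tissue_params`
#' @export
tissue_params <- function(t1_pre, t1_post, m0 = 1, alpha = 5, b = -1) {
  stopifnot(is.finite(t1_pre), is.finite(t1_post))
  if (!(t1_pre > t1_post && t1_post > 0)) {
    stop("tissue_params: require t1_pre > t1_post > 0")
  }
  if (!(b >= -1 && b <= 0)) stop("tissue_params: b must lie in [-1, 0]")
  if (!(m0 > 0)) stop("tissue_params: m0 must be positive")
  structure(list(t1_pre = t1_pre, t1_post = t1_post, m0 = m0,
                 alpha = alpha, b = b),
            class = "tissue_params")
}

#' Longitudinal scaling factor of the inversion pulse
#' @keywords internal
#' @noRd
inv_factor <- function(b) 1 + 2 * b

#' FLASH apparent steady state m0 (1 - E1) / (1 - E1 cos a)
#' @keywords internal
#' @noRd
flash_steady_state <- function(m0, e1, cosa) m0 * (1 - e1) / (1 - e1 * cosa)

#' Simulate one IR-FLASH inversion block
#'
#' Closed-form evaluation of the Look-Locker recursion for a single
#' inversion block of N TRs.  The inversion scales the input magnetization
#' by `1 + 2 b`; each TR then applies excitation (factor cos(alpha)) and
#' free relaxation toward `m0`.  `trace[n]` is the longitudinal magnetization
#' after n complete TR cycles,
#' `trace[n] = M* + (g(b) m_init - M*) (E1 cos a)^n`;
#' the readout signal at excitation n is the magnetization *before* that
#' cycle's scaling, `signal[n] = sin(alpha) * trace[n-1]` (with
#' `trace[0] = g(b) m_init`).  `mz` holds those pre-excitation values.
#'
#' @param tissue a [tissue_params] object
#' @param seq a [seq_params] object
#' @param m_init longitudinal magnetization just before the inversion pulse;
#'   defaults to the periodic steady state of the repeated-block sequence
#' @param t1 which T1 to use, `"pre"` or `"post"` (default `"pre"`)
#' @return list with `trace`, `signal`, `mz` (all length N) and `m_end`,
#'   the magnetization just before the next inversion (after any gap between
#'   the last readout and the end of the recovery period)
#' @export
simulate_ir_flash_block <- function(tissue, seq, m_init = NULL,
                                    t1 = c("pre", "post")) {
  t1 <- match.arg(t1)
  t1v <- if (t1 == "pre") tissue$t1_pre else tissue$t1_post
  if (!is.finite(t1v) || t1v <= 0) stop("simulate_ir_flash_block: T1 must be positive")
  if (is.null(m_init)) {
    m_init <- periodic_steady_state(tissue, seq, t1 = t1)
  }
  stopifnot(is.finite(m_init))
  ir_block_closed_form(m_init, t1v, tissue$m0, tissue$alpha, tissue$b, seq)
}

#' @keywords internal
#' @noRd
ir_block_closed_form <- function(m_init, t1, m0, alpha, b, seq) {
  n <- seq$readouts_per_period
  a <- alpha * pi / 180
  e1 <- exp(-seq$tr / t1)
  r <- e1 * cos(a)
  mss <- flash_steady_state(m0, e1, cos(a))
  m_inv <- inv_factor(b) * m_init
  pw <- r^(seq_len(n))
  trace <- mss + (m_inv - mss) * pw
  mz <- c(m_inv, trace[-n])
  gap <- seq$recovery_period - n * seq$tr
  m_end <- m0 + (trace[n] - m0) * exp(-gap / t1)
  list(trace = trace, signal = sin(a) * mz, mz = mz, m_end = m_end)
}

#' Periodic steady state of the repeated inversion-block sequence
#'
#' The inversion block map is affine in the input magnetization,
#' `m_end = A + R m`, with `R = g(b) (E1 cos a)^N exp(-gap/T1)`; its fixed
#' point (the magnetization just before each inversion once the sequence has
#' become periodic) is `A / (1 - R)`, available in closed form.
#'
#' @inheritParams simulate_ir_flash_block
#' @return scalar longitudinal magnetization just before an inversion pulse
#' @export
periodic_steady_state <- function(tissue, seq, t1 = c("pre", "post")) {
  t1 <- match.arg(t1)
  t1v <- if (t1 == "pre") tissue$t1_pre else tissue$t1_post
  n <- seq$readouts_per_period
  a <- tissue$alpha * pi / 180
  e1 <- exp(-seq$tr / t1v)
  r <- e1 * cos(a)
  mss <- flash_steady_state(tissue$m0, e1, cos(a))
  gap <- seq$recovery_period - n * seq$tr
  eg <- exp(-gap / t1v)
  bigr <- inv_factor(tissue$b) * r^n * eg
  biga <- tissue$m0 * (1 - eg) + eg * mss * (1 - r^n)
  biga / (1 - bigr)
}

#' Jointly simulate a pre/post-contrast block pair
#'
#' One native and one post-contrast inversion block are simulated with a
#' shared equilibrium magnetization, flip angle, and inversion efficiency;
#' each block starts from its own periodic steady state.  The concatenated
#' 2N-sample curve is the atom shape used throughout dictionary matching,
#' tensor completion, and pixel-wise fitting.
#'
#' @inheritParams simulate_ir_flash_block
#' @return list of class `joint_signal` with `pre_curve`, `post_curve`,
#'   `concatenated` (length 2N) and `t1_index` (readout index within block)
#' @export
simulate_joint_pair <- function(tissue, seq) {
  if (!(tissue$t1_pre > tissue$t1_post)) {
    stop("simulate_joint_pair: t1_pre must exceed t1_post")
  }
  pre <- simulate_ir_flash_block(tissue, seq, t1 = "pre")
  post <- simulate_ir_flash_block(tissue, seq, t1 = "post")
  structure(list(pre_curve = pre$signal, post_curve = post$signal,
                 concatenated = c(pre$signal, post$signal),
                 t1_index = rep(seq_len(seq$readouts_per_period), 2)),
            class = "joint_signal")
}

#' Dictionary grid specification
#'
#' The default reproduces the full published grid: 101 T1 values from 100 to
#' 3000 ms (admissible pairs with `t1_pre > t1_post` only), 15 flip angles
#' from 0.5 to 7.5 degrees, 21 inversion efficiencies from -1 to 0, i.e.
#' choose(101, 2) * 15 * 21 = 1,590,750 atoms.  Materializing that dense
#' 1664 x 1.59e6 atom matrix needs ~10 GiB, so [build_dictionary] only
#' materializes atoms for grids up to `max_atoms`; the T1 basis can still be
#' computed on arbitrarily large grids by blocked Gram accumulation
#' ([compute_t1_basis]).  `reduced = TRUE` gives a coarser grid used by the
#' reconstruction/fitting pipeline defaults.
#'
#' @param n_t1,t1_range T1 grid size and range (ms)
#' @param n_alpha,alpha_range flip-angle grid size and range (degrees)
#' @param n_b,b_range inversion-efficiency grid size and range
#' @param reduced logical; return the coarser pipeline default grid
#' @return list of grid vectors (`t1`, `alpha`, `b`) of class `grid_spec`
#' @export
dictionary_grid_spec <- function(n_t1 = 101, t1_range = c(100, 3000),
                                 n_alpha = 15, alpha_range = c(0.5, 7.5),
                                 n_b = 21, b_range = c(-1, 0),
                                 reduced = FALSE) {
  if (reduced) {
    n_t1 <- 31; n_alpha <- 7; n_b <- 9
  }
  spec <- list(t1 = seq(t1_range[1], t1_range[2], length.out = n_t1),
               alpha = seq(alpha_range[1], alpha_range[2],
                           length.out = n_alpha),
               b = seq(b_range[1], b_range[2], length.out = n_b))
  if (any(spec$t1 <= 0)) stop("dictionary_grid_spec: T1 values must be positive")
  structure(spec, class = "grid_spec")
}

#' Number of dictionary atoms implied by a grid specification
#'
#' Atoms correspond to tuples `(t1_pre, t1_post, alpha, b)` with
#' `t1_pre > t1_post`, so the count is `choose(n_t1, 2) * n_alpha * n_b`.
#' @param grid_spec a [dictionary_grid_spec]
#' @export
n_dictionary_atoms <- function(grid_spec) {
  choose(length(grid_spec$t1), 2) * length(grid_spec$alpha) *
    length(grid_spec$b)
}

# Atom block for one (alpha, b) slice: all admissible (t1_pre, t1_post)
# pairs, l2-normalized columns of length 2N.  m0 is fixed to 1 (a pure
# scale).  Vectorized: one closed-form block per T1 value, then pair columns.
#' @keywords internal
#' @noRd
atom_block <- function(t1_grid, alpha, b, seq, normalize = TRUE) {
  nt <- length(t1_grid)
  nn <- seq$readouts_per_period
  sig <- matrix(0, nn, nt)
  for (i in seq_len(nt)) {
    # single-T1 periodic block signal (pre and post halves share the model)
    tis <- list(t1_pre = t1_grid[i], t1_post = t1_grid[i] / 2, m0 = 1,
                alpha = alpha, b = b)
    class(tis) <- "tissue_params"
    m_star <- periodic_steady_state(tis, seq, t1 = "pre")
    sig[, i] <- ir_block_closed_form(m_star, t1_grid[i], 1, alpha, b,
                                     seq)$signal
  }
  pairs <- which(upper.tri(matrix(0, nt, nt)), arr.ind = TRUE)
  pre_idx <- pairs[, 2]   # larger T1 index = t1_pre
  post_idx <- pairs[, 1]
  atoms <- rbind(sig[, pre_idx, drop = FALSE], sig[, post_idx, drop = FALSE])
  if (normalize) {
    atoms <- sweep(atoms, 2, sqrt(colSums(atoms^2)), "/")
  }
  list(atoms = atoms,
       grid = cbind(t1_pre = t1_grid[pre_idx], t1_post = t1_grid[post_idx],
                    alpha = alpha, b = b))
}

#' Build the joint pre/post T1 dictionary
#'
#' Simulates the joint block pair over every admissible grid tuple
#' (`t1_pre > t1_post`), with `m0` fixed to 1 and each atom l2-normalized.
#' For grids whose atom count exceeds `max_atoms` the dense atom matrix is
#' not materialized (`atoms = NULL`); [compute_t1_basis] then accumulates
#' the 2N x 2N Gram matrix in blocks instead.
#'
#' @param grid_spec a [dictionary_grid_spec]
#' @param seq a [seq_params] object
#' @param max_atoms materialization limit for the dense atom matrix
#' @return object of class `t1_dictionary` with `grid` (matrix of tuples),
#'   `atoms` (2N x n_atoms matrix or NULL), `grid_spec`, `seq`
#' @export
build_dictionary <- function(grid_spec = dictionary_grid_spec(reduced = TRUE),
                             seq = seq_params(), max_atoms = 2e5) {
  n_atoms <- n_dictionary_atoms(grid_spec)
  if (n_atoms == 0) stop("build_dictionary: empty admissible grid")
  materialize <- n_atoms <= max_atoms
  atoms <- NULL
  grids <- vector("list", length(grid_spec$alpha) * length(grid_spec$b))
  blocks <- if (materialize) grids else NULL
  k <- 0
  for (b in grid_spec$b) {
    for (a in grid_spec$alpha) {
      k <- k + 1
      blk <- atom_block(grid_spec$t1, a, b, seq)
      grids[[k]] <- blk$grid
      if (materialize) blocks[[k]] <- blk$atoms
    }
  }
  if (materialize) atoms <- do.call(cbind, blocks)
  structure(list(grid = do.call(rbind, grids), atoms = atoms,
                 grid_spec = grid_spec, seq = seq, n_atoms = n_atoms),
            class = "t1_dictionary")
}

#' @export
print.t1_dictionary <- function(x, ...) {
  cat(sprintf("Joint pre/post T1 dictionary: %d atoms of length %d (%s)\n",
              x$n_atoms, 2L * x$seq$readouts_per_period,
              if (is.null(x$atoms)) "not materialized" else "materialized"))
  invisible(x)
}

#' T1-recovery temporal basis from the dictionary SVD
#'
#' Left singular vectors of the (l2-normalized) atom matrix.  The
#' decomposition is computed from the 2N x 2N Gram matrix, accumulated in
#' `(alpha, b)` blocks, so it works for grids too large to materialize.
#' The rank defaults to the smallest rank capturing `energy` of the total
#' squared-singular-value spectrum.
#'
#' Automatic rank selection defaults to the smallest rank whose worst-case
#' atom projection residual (relative l2) is below `max_residual`; a global
#' spectral-energy criterion is available via `energy`.  The worst-case rule
#' is used because the atom spectrum decays so fast that a global energy
#' fraction leaves individual extreme-parameter atoms poorly represented.
#'
#' @param dict a [build_dictionary] result
#' @param rank basis rank `L_T1`; if NULL chosen automatically
#' @param energy optional spectral energy fraction for rank selection
#' @param max_residual worst-atom relative residual tolerance for rank
#'   selection (default rule)
#' @return object of class `t1_basis` with orthonormal `basis`
#'   (2N x rank), `singular_values`, `rank`, and `energy_captured`
#' @export
compute_t1_basis <- function(dict, rank = NULL, energy = NULL,
                             max_residual = 1e-3) {
  nn2 <- 2L * dict$seq$readouts_per_period
  if (!is.null(rank) && rank > nn2) {
    stop("compute_t1_basis: rank exceeds curve length")
  }
  if (!is.null(rank) && rank > dict$n_atoms) {
    stop("compute_t1_basis: rank exceeds number of atoms")
  }
  each_block <- function(fun) {
    for (b in dict$grid_spec$b) {
      for (a in dict$grid_spec$alpha) {
        fun(atom_block(dict$grid_spec$t1, a, b, dict$seq)$atoms)
      }
    }
  }
  if (!is.null(dict$atoms)) {
    gram <- tcrossprod(dict$atoms)
  } else {
    gram <- matrix(0, nn2, nn2)
    each_block(function(a) gram <<- gram + tcrossprod(a))
  }
  eg <- eigen(gram, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (is.null(rank)) {
    if (!is.null(energy)) {
      frac <- cumsum(ev) / sum(ev)
      rank <- which(frac >= energy)[1]
    } else {
      # smallest rank with max-atom residual <= max_residual (second pass)
      rmax <- min(nn2, max(2L, sum(ev > ev[1] * 1e-28)))
      u_full <- eg$vectors[, seq_len(rmax), drop = FALSE]
      worst <- numeric(rmax)  # worst residual^2 at each candidate rank
      score <- function(a) {
        c2 <- crossprod(u_full, a)^2           # rmax x n_atoms
        cum <- apply(c2, 2, cumsum)
        if (rmax == 1L) cum <- matrix(cum, nrow = 1L)
        resid2 <- outer(rep(1, rmax), colSums(a^2)) - cum
        resid2[resid2 < 0] <- 0
        worst <<- pmax(worst, apply(resid2, 1, max))
      }
      if (!is.null(dict$atoms)) score(dict$atoms) else each_block(score)
      hit <- which(sqrt(worst) <= max_residual)
      rank <- if (length(hit)) hit[1] else rmax
    }
  }
  structure(list(basis = eg$vectors[, seq_len(rank), drop = FALSE],
                 singular_values = sqrt(ev),
                 rank = as.integer(rank),
                 energy_captured = sum(ev[seq_len(rank)]) / sum(ev)),
            class = "t1_basis")
}

#' Single-block T1 basis (one recovery period)
#'
#' Same construction as [compute_t1_basis] but on single-block curves of
#' length N (both halves of every atom contribute).  Used by the binning
#' stage to remove T1-recovery contrast block by block.
#'
#' @inheritParams compute_t1_basis
#' @return a `t1_basis` whose `basis` is N x rank
#' @export
compute_block_t1_basis <- function(dict, rank = NULL, energy = 0.9999) {
  nn <- dict$seq$readouts_per_period
  gram <- matrix(0, nn, nn)
  for (b in dict$grid_spec$b) {
    for (a in dict$grid_spec$alpha) {
      blk <- atom_block(dict$grid_spec$t1, a, b, dict$seq, normalize = FALSE)
      half <- cbind(blk$atoms[seq_len(nn), , drop = FALSE],
                    blk$atoms[nn + seq_len(nn), , drop = FALSE])
      half <- sweep(half, 2, sqrt(colSums(half^2)), "/")
      gram <- gram + tcrossprod(half)
    }
  }
  eg <- eigen(gram, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (is.null(rank)) {
    frac <- cumsum(ev) / sum(ev)
    rank <- which(frac >= energy)[1]
  }
  structure(list(basis = eg$vectors[, seq_len(rank), drop = FALSE],
                 singular_values = sqrt(ev), rank = as.integer(rank),
                 energy_captured = sum(ev[seq_len(rank)]) / sum(ev)),
            class = "t1_basis")
}
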