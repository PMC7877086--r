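# Beating, breathing 2D short-axis rat-heart phantom and Cartesian
# line-by-line k-space acquisition simulator.
#
# Geometry is parameterized in fractions of the field of view so the same
# configuration renders at any matrix size.  Structures: torso/chest
# (ellipse), LV blood pool (disk), myocardial annulus, descending aorta
# (disk), air background.  Cardiac motion is a radial contraction of the
# annulus conserving wall area (incompressible myocardium) plus a small
# phase-lagged in-plane displacement of the heart (a surrogate for twist /
# base-apex shortening) so that the cardiac cycle traces a genuine loop in
# feature space rather than a line.  Respiratory motion is a rigid
# in-plane translation with an end-expiration dwell (sin^4 waveform).
# Cardiac phase is quantized to `n_cardiac_phases` states per cycle (10 ms
# at 300 bpm), below the 20 ms bin resolution targeted downstream.

#' Digital phantom configuration
#'
#' Defaults state the acquisition conditions this package emulates: heart
#' rate ~300 bpm, respiration ~60 cpm, hematocrit 0.42, k-space SNR 30,
#' and 9.4 T rat tissue T1s (myocardium 1550/800 ms pre/post, blood
#' 2200/450 ms, chest wall 900/550 ms).  Blood proton density (m0) is
#' slightly above muscle; its inflow brightening arises from the dynamics
#' when `inflow = TRUE` (spins flow through the slice between TRs and are
#' never saturated by the readout train), which also makes the pure-IR
#' (alpha = 0) blood model the correct fit.
#'
#' @param heart_rate beats per minute
#' @param resp_rate respiration cycles per minute
#' @param contraction_amplitude fractional systolic reduction of the LV
#'   inner radius
#' @param resp_translation peak respiratory in-plane translation (mm)
#' @param resp_direction unit vector (x, y) of the respiratory translation;
#'   a diagonal direction is the default so that both the frequency- and
#'   phase-encode axes see the motion
#' @param lag_shift amplitude (FOV fraction) of the phase-lagged cardiac
#'   displacement component; 0 disables it
#' @param n_cardiac_phases number of discrete cardiac states per cycle
#' @param tissues named list of [tissue_params] for `body`, `myo`, `blood`
#' @param geometry named list of structure centers/radii in FOV fractions
#' @param noise_sigma complex k-space noise standard deviation per sample;
#'   if `NULL`, derived from `snr` (peak magnitude of the noiseless k-space
#'   center line over noise sigma)
#' @param snr k-space SNR used when `noise_sigma` is NULL
#' @param inflow logical; emulate inflow of unexcited blood spins
#' @param hct hematocrit fraction in (0, 1)
#' @param seed default random seed for [acquire]
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(heart_rate = 300, resp_rate = 60,
                           contraction_amplitude = 0.25,
                           resp_translation = 1.5,
                           resp_direction = c(0.6, 0.8),
                           lag_shift = 0.012,
                           n_cardiac_phases = 20L,
                           tissues = list(
                             body  = tissue_params(900, 550, m0 = 0.8,
                                                   alpha = 5, b = -0.95),
                             myo   = tissue_params(1550, 800, m0 = 1.0,
                                                   alpha = 5, b = -0.95),
                             blood = tissue_params(2200, 450, m0 = 1.1,
                                                   alpha = 5, b = -0.95)),
                           geometry = list(
                             torso_center = c(0.50, 0.54),
                             torso_semi   = c(0.40, 0.36),
                             lv_center    = c(0.46, 0.44),
                             r_blood      = 0.075,
                             r_myo_outer  = 0.145,
                             aorta_center = c(0.52, 0.70),
                             r_aorta      = 0.0375,
                             septal_angles = c(135, 225)),
                           noise_sigma = NULL, snr = 30,
                           inflow = TRUE, hct = 0.42, seed = 1L) {
  stopifnot(heart_rate > 0, resp_rate > 0, hct > 0, hct < 1,
            contraction_amplitude >= 0, contraction_amplitude < 1,
            n_cardiac_phases >= 1)
  if (!is.null(noise_sigma) && noise_sigma < 0) {
    stop("phantom_config: noise_sigma must be nonnegative")
  }
  resp_direction <- resp_direction / sqrt(sum(resp_direction^2))
  structure(list(heart_rate = heart_rate, resp_rate = resp_rate,
                 contraction_amplitude = contraction_amplitude,
                 resp_translation = resp_translation,
                 resp_direction = resp_direction,
                 lag_shift = lag_shift,
                 n_cardiac_phases = as.integer(n_cardiac_phases),
                 tissues = tissues, geometry = geometry,
                 noise_sigma = noise_sigma, snr = snr, inflow = inflow,
                 hct = hct, seed = as.integer(seed)),
            class = "phantom_config")
}

#' In-plane voxel size
#'
#' @param seq a [seq_params] object
#' @return voxel edge length, `fov / matrix` (mm)
#' @export
in_plane_voxel_size <- function(seq) {
  stopifnot(seq$matrix > 0)
  seq$fov / seq$matrix
}

# cardiac contraction waveform on [0, 1): 0 at end-diastole (phase 0)
#' @keywords internal
#' @noRd
contraction_waveform <- function(p) sin(pi * (p %% 1))^2

# respiratory displacement waveform on [0, 1): sin^4 dwells near 0
#' @keywords internal
#' @noRd
resp_waveform <- function(p) sin(pi * (p %% 1))^4

#' @keywords internal
#' @noRd
cardiac_phase_index <- function(t, config) {
  period <- 60000 / config$heart_rate               # ms
  p <- (t %% period) / period
  pmin(floor(p * config$n_cardiac_phases) + 1L, config$n_cardiac_phases)
}

#' @keywords internal
#' @noRd
resp_displacement_px <- function(t, config, seq) {
  period <- 60000 / config$resp_rate
  s <- resp_waveform((t %% period) / period)
  amp <- s * config$resp_translation / in_plane_voxel_size(seq)
  list(s = s, dx = amp * config$resp_direction[1],
       dy = amp * config$resp_direction[2])
}

# Structure masks at a given cardiac state.  w = contraction in [0,1],
# w_lag = lagged displacement waveform value.
#' @keywords internal
phantom_masks <- function(config, seq, w = 0, w_lag = 0) {
  m <- seq$matrix
  g <- config$geometry
  fr <- (seq_len(m) - 0.5) / m
  x <- matrix(fr, m, m, byrow = TRUE)   # column coordinate
  y <- matrix(fr, m, m)                 # row coordinate
  lv <- g$lv_center + c(0, config$lag_shift * w_lag)
  r_in0 <- g$r_blood
  r_out0 <- g$r_myo_outer
  r_in <- r_in0 * (1 - config$contraction_amplitude * w)
  r_out <- sqrt(r_in^2 + r_out0^2 - r_in0^2)   # conserve wall area
  if (r_out >= min(g$torso_semi)) stop("phantom_masks: heart exceeds torso")
  d_lv2 <- (x - lv[1])^2 + (y - lv[2])^2
  blood <- d_lv2 <= r_in^2
  myo <- d_lv2 <= r_out^2 & !blood
  aorta <- (x - g$aorta_center[1])^2 + (y - g$aorta_center[2])^2 <=
    g$r_aorta^2
  torso <- ((x - g$torso_center[1]) / g$torso_semi[1])^2 +
    ((y - g$torso_center[2]) / g$torso_semi[2])^2 <= 1
  if (any(aorta & (blood | myo))) {
    stop("phantom_masks: aorta overlaps the LV structures")
  }
  body <- torso & !blood & !myo & !aorta
  ang <- atan2(y - lv[2], x - lv[1]) * 180 / pi   # degrees, (-180, 180]
  ang <- (ang + 360) %% 360
  septal <- myo & ang >= g$septal_angles[1] & ang <= g$septal_angles[2]
  list(body = body, myo = myo, blood = blood, aorta = aorta,
       septal = septal, r_in = r_in, r_out = r_out)
}

#' Rasterize the phantom at the reference state
#'
#' Reference state is end-diastole (no contraction) at end-expiration (no
#' respiratory displacement) -- the state downstream maps are produced in.
#'
#' @param config a [phantom_config]
#' @param seq a [seq_params]
#' @return object of class `phantom` with integer `labels` (0 background,
#'   1 body, 2 myocardium, 3 LV blood, 4 aorta), per-pixel `t1_pre`,
#'   `t1_post`, `m0` maps, logical `masks` (including `septal`), and the
#'   tissue table
#' @export
make_phantom <- function(config = phantom_config(), seq = seq_params()) {
  mk <- phantom_masks(config, seq, w = 0, w_lag = 0)
  m <- seq$matrix
  labels <- matrix(0L, m, m)
  labels[mk$body] <- 1L
  labels[mk$myo] <- 2L
  labels[mk$blood] <- 3L
  labels[mk$aorta] <- 4L
  t1_pre <- t1_post <- m0 <- matrix(0, m, m)
  tiss_of <- c("body", "myo", "blood", "blood")
  for (lab in 1:4) {
    tp <- config$tissues[[tiss_of[lab]]]
    t1_pre[labels == lab] <- tp$t1_pre
    t1_post[labels == lab] <- tp$t1_post
    m0[labels == lab] <- tp$m0
  }
  if (!any(mk$myo)) stop("make_phantom: empty myocardium")
  structure(list(labels = labels, t1_pre = t1_pre, t1_post = t1_post,
                 m0 = m0, masks = mk, config = config, seq = seq),
            class = "phantom")
}

# Per-tissue readout signal curves (length N) for one scan.  Blood classes
# optionally use inflow dynamics: longitudinal magnetization follows the
# pure-IR recursion (alpha = 0; fresh spins are never excited) while the
# readout pulse still tips sin(flip_nominal) of it into the transverse
# plane.
#' @keywords internal
tissue_signal_curves <- function(config, seq, scan = c("pre", "post")) {
  scan <- match.arg(scan)
  curves <- list()
  for (nm in c("body", "myo", "blood")) {
    tp <- config$tissues[[nm]]
    if (nm == "blood" && config$inflow) {
      tp0 <- tp
      tp0$alpha <- 0
      blk <- simulate_ir_flash_block(tp0, seq, t1 = scan)
      curves[[nm]] <- sin(seq$flip_nominal * pi / 180) * blk$mz
    } else {
      curves[[nm]] <- simulate_ir_flash_block(tp, seq, t1 = scan)$signal
    }
  }
  curves$aorta <- curves$blood
  curves
}

#' Render one image frame of the moving phantom
#'
#' Builds the structure masks at the cardiac state of time `t`, weights them
#' by each tissue's IR-FLASH signal at the readout index since the last
#' inversion, and applies the respiratory translation as a k-space phase
#' ramp (band-limited cyclic subpixel shift).
#'
#' @param t time since scan start (ms)
#' @param scan_label `"pre"` or `"post"`
#' @param config a [phantom_config]
#' @param seq a [seq_params]
#' @return complex image matrix `[matrix x matrix]`
#' @export
render_frame <- function(t, scan_label, config = phantom_config(),
                         seq = seq_params()) {
  scan_label <- match.arg(scan_label, c("pre", "post"))
  n <- seq$readouts_per_period
  t1_idx <- pmin(floor((t %% seq$recovery_period) / seq$tr) + 1L, n)
  ph <- cardiac_phase_index(t, config)
  pc <- (ph - 0.5) / config$n_cardiac_phases
  w <- contraction_waveform(pc)
  wl <- contraction_waveform(pc - 0.15)
  mk <- phantom_masks(config, seq, w = w, w_lag = wl)
  curves <- tissue_signal_curves(config, seq, scan_label)
  img <- matrix(0, seq$matrix, seq$matrix)
  for (nm in c("body", "myo", "blood", "aorta")) {
    img[mk[[nm]]] <- img[mk[[nm]]] +
      curves[[nm]][t1_idx] * config$tissues[[if (nm == "aorta") "blood"
                                             else nm]]$m0
  }
  disp <- resp_displacement_px(t, config, seq)
  if (abs(disp$dy) + abs(disp$dx) < 1e-12) return(img + 0i)
  m <- seq$matrix
  kk <- fftshift_vec(seq(-m / 2, m / 2 - 1))  # centered k per FFT index
  ramp <- exp(-2i * pi * outer(kk * disp$dy, kk * disp$dx, "+") / m)
  ufft2(ufft2(img) * ramp, inverse = TRUE)
}

#' Noise sigma giving a target image-domain SNR
#'
#' SNR uses the standard MRI definition: mean myocardial signal magnitude
#' (in the fully sampled reference frame at end-diastole/end-expiration,
#' late in the native recovery) divided by the per-pixel noise standard
#' deviation.  With unitary Fourier transforms the per-pixel image noise
#' SD equals the per-sample k-space noise SD, so the returned sigma is
#' applied directly to every k-space sample.
#'
#' @inheritParams render_frame
#' @param snr target SNR
#' @export
noise_sigma_for_snr <- function(config, seq, snr = 30) {
  img <- render_frame((seq$readouts_per_period - 1) * seq$tr, "pre",
                      config, seq)
  myo <- phantom_masks(config, seq, w = 0, w_lag = 0)$myo
  mean(Mod(img[myo])) / snr
}

#' Simulate the full two-scan k-space acquisition
#'
#' Reproduces the interleaved sampling scheme: readouts every TR; odd
#' readouts are imaging lines with Gaussian-density random ky, even
#' readouts are training lines at ky = 0; `n_ir_pulses` inversion blocks of
#' N readouts per scan; pre- and post-contrast scans with identical
#' parameters and independent periodic steady states.  Complex Gaussian
#' noise is added per k-space sample.  Lines are stored in centered-kx
#' order (DC at column matrix/2 + 1).
#'
#' @param config a [phantom_config]
#' @param seq a [seq_params]
#' @param gaussian_sigma_ky standard deviation (in ky index units) of the
#'   Gaussian phase-encode density; default `matrix / 6`
#' @param seed integer seed; defaults to `config$seed`
#' @return object of class `kspace_dataset`: complex `lines`
#'   `[n_readouts x matrix]`, `meta` data frame (timestamp, ky_index,
#'   is_training, scan_label, ir_block_index, t1_index, cardiac phase and
#'   respiratory displacement ground truth), `ground_truth` (reference
#'   phantom + motion traces), `seq`, `config`, `noise_sigma`, `seed`
#' @export
acquire <- function(config = phantom_config(), seq = seq_params(),
                    gaussian_sigma_ky = NULL, seed = config$seed) {
  m <- seq$matrix
  if (is.null(gaussian_sigma_ky)) gaussian_sigma_ky <- m / 6
  if (gaussian_sigma_ky <= 0) stop("acquire: gaussian_sigma_ky must be > 0")
  sigma <- config$noise_sigma %||% noise_sigma_for_snr(config, seq,
                                                       config$snr)
  set.seed(seed)
  n <- seq$readouts_per_period
  n_ro <- seq$n_ir_pulses * n
  nph <- config$n_cardiac_phases
  # per-phase tissue mask FFTs (m0-weighted), shared by both scans
  fcache <- vector("list", nph)
  tiss_m0 <- c(body = config$tissues$body$m0, myo = config$tissues$myo$m0,
               blood = config$tissues$blood$m0,
               aorta = config$tissues$blood$m0)
  for (ph in seq_len(nph)) {
    pc <- (ph - 0.5) / nph
    mk <- phantom_masks(config, seq, w = contraction_waveform(pc),
                        w_lag = contraction_waveform(pc - 0.15))
    fcache[[ph]] <- lapply(c("body", "myo", "blood", "aorta"), function(nm) {
      ufft2(mk[[nm]] * tiss_m0[[nm]])
    })
    names(fcache[[ph]]) <- c("body", "myo", "blood", "aorta")
  }
  scans <- c("pre", "post")
  all_lines <- vector("list", 2)
  all_meta <- vector("list", 2)
  for (si in 1:2) {
    scan <- scans[si]
    curves <- tissue_signal_curves(config, seq, scan)
    ordinal <- seq_len(n_ro)
    t <- (ordinal - 1) * seq$tr
    t1_idx <- ((ordinal - 1L) %% n) + 1L
    ir_block <- ((ordinal - 1L) %/% n) + 1L
    is_training <- ordinal %% 2L == 0L
    ky <- integer(n_ro)
    n_im <- sum(!is_training)
    ky[!is_training] <- pmax(pmin(round(stats::rnorm(n_im, 0,
                                                     gaussian_sigma_ky)),
                                  m / 2 - 1), -m / 2)
    ph <- cardiac_phase_index(t, config)
    disp <- resp_displacement_px(t, config, seq)
    lines <- matrix(0+0i, n_ro, m)
    for (p in unique(ph)) {
      sel <- which(ph == p)
      rows <- k_to_row(ky[sel], m)
      acc <- matrix(0+0i, length(sel), m)
      for (nm in c("body", "myo", "blood", "aorta")) {
        acc <- acc + curves[[nm]][t1_idx[sel]] *
          fcache[[p]][[nm]][rows, , drop = FALSE]
      }
      kx <- fftshift_vec(seq(-m / 2, m / 2 - 1))  # per uncentered column
      acc <- acc * exp(-2i * pi * ky[sel] * disp$dy[sel] / m)
      acc <- acc * exp(-2i * pi * outer(disp$dx[sel], kx) / m)
      lines[sel, ] <- acc
    }
    if (sigma > 0) {
      lines <- lines + complex(real = stats::rnorm(length(lines), 0, sigma),
                               imaginary = stats::rnorm(length(lines), 0,
                                                        sigma))
    }
    lines <- lines[, centered_order(m), drop = FALSE]  # center kx (DC mid+1)
    all_lines[[si]] <- lines
    all_meta[[si]] <- data.frame(
      scan = scan, ordinal = ordinal, timestamp = t,
      ir_block_index = ir_block, t1_index = t1_idx,
      is_training = is_training, ky_index = ky,
      cardiac_phase = ph, resp_s = disp$s, resp_dx_px = disp$dx,
      resp_dy_px = disp$dy)
  }
  meta <- do.call(rbind, all_meta)
  meta$readout_id <- seq_len(nrow(meta))
  gt <- list(phantom = make_phantom(config, seq),
             cardiac_phase = meta$cardiac_phase,
             resp_s = meta$resp_s)
  structure(list(lines = do.call(rbind, all_lines), meta = meta,
                 ground_truth = gt, seq = seq, config = config,
                 noise_sigma = sigma,
                 gaussian_sigma_ky = gaussian_sigma_ky,
                 seed = as.integer(seed)),
            class = "kspace_dataset")
}

#' @export
print.kspace_dataset <- function(x, ...) {
  cat(sprintf(paste0("k-space dataset: %d readouts (%d training / %d ",
                     "imaging) x %d samples, 2 scans\n"),
              nrow(x$lines), sum(x$meta$is_training),
              sum(!x$meta$is_training), ncol(x$lines)))
  cat(sprintf("  noise sigma %.3g, seed %d\n", x$noise_sigma, x$seed))
  invisible(x)
}

#' Ground-truth motion bins for scoring
#'
#' Cardiac truth: the discrete cardiac phase mapped onto `k_card` equal
#' phase bins (bin 1 starts at end-diastole).  Respiratory truth: the
#' noiseless displacement trace quantized into `k_resp` states by a
#' deterministic 1D Lloyd quantizer (bin 1 = end-expiration dwell).
#'
#' @param ds a [acquire] result
#' @param k_card,k_resp bin counts
#' @return data frame with `cardiac_bin` and `resp_bin` per readout
#' @export
true_bins <- function(ds, k_card = 10L, k_resp = 5L) {
  nph <- ds$config$n_cardiac_phases
  card <- ceiling(ds$meta$cardiac_phase * k_card / nph)
  resp <- quantize_1d(ds$meta$resp_s, k_resp)$label
  data.frame(cardiac_bin = as.integer(card), resp_bin = as.integer(resp))
}
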