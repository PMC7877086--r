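#' @keywords internal
"_PACKAGE"

# ---- FFT conventions --------------------------------------------------------
# Images are indexed [row = y, col = x].  k-space uses a *centered* integer
# index convention: k in [-M/2, M/2 - 1], with DC (k = 0) in the middle of a
# stored line after fftshift.  All transforms are unitary (scaled by 1/sqrt(M)
# per dimension) so that Parseval holds exactly and adjoint = inverse.

#' Unitary 1D FFT along columns of a matrix
#' @keywords internal
#' @noRd
ufft_cols <- function(x, inverse = FALSE) {
  n <- nrow(x)
  stats::mvfft(x, inverse = inverse) / sqrt(n)
}

#' Unitary 2D FFT of a matrix (image -> k-space), uncentered storage
#' @keywords internal
#' @noRd
ufft2 <- function(x, inverse = FALSE) {
  stats::fft(x, inverse = inverse) / sqrt(length(x))
}

#' Shift a vector/matrix so that the DC index (1) moves to the center
#' @keywords internal
#' @noRd
fftshift_vec <- function(v) {
  n <- length(v)
  v[c((n / 2 + 1):n, 1:(n / 2))]
}

#' @keywords internal
#' @noRd
ifftshift_vec <- function(v) {
  n <- length(v)
  v[c((n / 2 + 1):n, 1:(n / 2))]
}

#' Map centered k index in [-M/2, M/2-1] to 1-based uncentered FFT index
#' @keywords internal
#' @noRd
k_to_row <- function(k, m) ((k + m) %% m) + 1L

#' Columns to shuffle a stored (centered) line back to uncentered FFT order
#' @keywords internal
#' @noRd
centered_order <- function(m) c((m / 2 + 1):m, 1:(m / 2))

# ---- misc numerics ----------------------------------------------------------

#' Deterministic 1D Lloyd quantizer (k-means in one dimension)
#'
#' Quantile-seeded Lloyd iterations; used both to define ground-truth
#' respiratory motion states in the phantom and to score binning.  Returns
#' cluster labels ordered by increasing center value.
#'
#' @param x numeric vector
#' @param k number of levels
#' @param iter maximum Lloyd iterations
#' @return list with `label` (1..k, ordered by center) and `centers`
#' @keywords internal
quantize_1d <- function(x, k, iter = 100L) {
  stopifnot(k >= 1L, length(x) >= k)
  cen <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE,
                         type = 8)
  cen <- sort(unique(cen))
  while (length(cen) < k) cen <- sort(c(cen, max(cen) + seq_along(cen)))
  for (i in seq_len(iter)) {
    bound <- (cen[-1] + cen[-k]) / 2
    lab <- findInterval(x, bound) + 1L
    new <- vapply(seq_len(k), function(j) {
      if (any(lab == j)) mean(x[lab == j]) else cen[j]
    }, numeric(1))
    if (max(abs(new - cen)) < 1e-12 * (1 + max(abs(cen)))) {
      cen <- new
      break
    }
    cen <- new
  }
  bound <- (cen[-1] + cen[-k]) / 2
  list(label = findInterval(x, bound) + 1L, centers = cen)
}

#' Soft-threshold operator (complex-safe)
#' @keywords internal
#' @noRd
soft_threshold <- function(x, t) {
  a <- Mod(x)
  s <- pmax(a - t, 0)
  out <- x
  nz <- a > 0
  out[nz] <- x[nz] * (s[nz] / a[nz])
  out[!nz] <- 0
  out
}

#' Analytic-signal phase of a real time series (discrete Hilbert transform)
#' @keywords internal
#' @noRd
analytic_phase <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(f * h, inverse = TRUE) / n
  Arg(z)
}

#' Zero-phase FFT band-pass filter applied to each column
#'
#' @param y numeric matrix, rows are time samples
#' @param dt sampling interval (s)
#' @param band length-2 numeric, passband in Hz
#' @keywords internal
bandpass_cols <- function(y, dt, band) {
  n <- nrow(y)
  f <- c(0, seq_len(n - 1)) / (n * dt)
  f <- pmin(f, 1 / dt - f)  # two-sided frequency magnitude
  keep <- f >= band[1] & f <= band[2]
  fy <- stats::mvfft(y)
  fy[!keep, ] <- 0
  Re(stats::mvfft(fy, inverse = TRUE)) / n
}

#' Otsu threshold of a numeric vector
#' @keywords internal
#' @noRd
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) {
    stop("otsu_threshold: input is constant; cannot separate classes")
  }
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Connected components of a logical mask (4-connectivity)
#'
#' Two-pass flood fill returning an integer label image (0 = background).
#' @keywords internal
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          q <- r2 + (c2 - 1L) * nr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
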