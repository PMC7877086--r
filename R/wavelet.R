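# Orthonormal Daubechies-4 discrete wavelet transform (periodic), used as
# the sparsifying transform of the spatial-basis regularizer.  The
# single-level analysis operator for length n is materialized once as an
# orthogonal n x n matrix (n <= a few hundred here, so dense is cheapest)
# and cached per session.

.db4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))

.wavelet_cache <- new.env(parent = emptyenv())

#' @keywords internal
#' @noRd
dwt_step_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])
  stopifnot(n %% 2 == 0, n >= 4)
  h <- .db4_lo
  g <- rev(h) * c(1, -1, 1, -1)
  w <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (j in 0:3) {
      col <- ((2 * (k - 1) + j) %% n) + 1
      w[k, col] <- w[k, col] + h[j + 1]
      w[n / 2 + k, col] <- w[n / 2 + k, col] + g[j + 1]
    }
  }
  .wavelet_cache[[key]] <- w
  w
}

#' 2D periodic Daubechies-4 wavelet transform
#'
#' Orthonormal multi-level decomposition of a square image (complex
#' allowed); `idwt2` inverts it exactly.
#'
#' @param x square matrix, side a multiple of `2^levels`
#' @param levels decomposition levels
#' @return coefficient matrix of the same size
#' @export
dwt2 <- function(x, levels = 3L) {
  n <- nrow(x)
  stopifnot(ncol(x) == n, n %% (2^levels) == 0)
  out <- x
  size <- n
  for (l in seq_len(levels)) {
    w <- dwt_step_matrix(size)
    blk <- out[seq_len(size), seq_len(size), drop = FALSE]
    out[seq_len(size), seq_len(size)] <- w %*% blk %*% t(w)
    size <- size / 2
  }
  out
}

#' @rdname dwt2
#' @export
idwt2 <- function(x, levels = 3L) {
  n <- nrow(x)
  stopifnot(ncol(x) == n, n %% (2^levels) == 0)
  out <- x
  sizes <- n / 2^(seq_len(levels) - 1)
  for (size in rev(sizes)) {
    w <- dwt_step_matrix(size)
    blk <- out[seq_len(size), seq_len(size), drop = FALSE]
    out[seq_len(size), seq_len(size)] <- t(w) %*% blk %*% w
  }
  out
}
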