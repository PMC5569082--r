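#' Chirp-Z transform along matrix columns
#'
#' Evaluates `X[m', col] = sum_j x[j, col] * a^(-j) * w^(j * m')` for
#' `m' = 0, ..., m - 1` using Bluestein's algorithm, i.e. the z-transform of
#' each column on the spiral contour `z_m = a * w^(-m)`. With
#' `a = 1, w = exp(-2i pi / N), m = N` this reduces exactly to the DFT.
#'
#' @param x Numeric or complex matrix (columns are signals) or a vector.
#' @param m Number of output points.
#' @param w Ratio between contour points (complex scalar).
#' @param a Starting point of the contour (complex scalar).
#' @return Complex matrix `m x ncol(x)` (or a vector if `x` was one).
#' @export
czt <- function(x, m, w, a = 1 + 0i) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  stopifnot(m >= 1, n >= 1)
  # chirp powers via angles (numerically stable for |w| = 1, the only case
  # used here; general |w| != 1 handled through log)
  lw <- log(as.complex(w))
  la <- log(as.complex(a))
  j <- 0:(n - 1)
  mm <- 0:(m - 1)
  wj2 <- exp(lw * j^2 / 2)
  wm2 <- exp(lw * mm^2 / 2)
  y <- x * (exp(-la * j) * wj2)
  L <- stats::nextn(n + m - 1, 2)
  # circular convolution with the chirp filter h_j = w^(-j^2 / 2)
  h <- complex(length.out = L)
  h[1:m] <- exp(-lw * mm^2 / 2)
  if (n > 1) h[L - (1:(n - 1)) + 1] <- exp(-lw * (1:(n - 1))^2 / 2)
  fh <- stats::fft(h)
  ypad <- rbind(y, matrix(0 + 0i, L - n, ncol(y)))
  g <- stats::mvfft(stats::mvfft(ypad) * fh, inverse = TRUE) / L
  out <- g[1:m, , drop = FALSE] * wm2
  if (vec) out[, 1] else out
}
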