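#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not perturb the
#' caller's RNG stream. A `NULL` seed evaluates the expression unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x Angles, rad.
#' @return Wrapped angles.
#' @export
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Tukey (tapered cosine) window
#'
#' Flat over the central `1 - alpha` fraction with cosine tapers to zero at
#' both ends; used to apodize spectra before the depth transform.
#'
#' @param n Window length.
#' @param alpha Total taper fraction in `[0, 1]`.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.25) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (alpha == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

# derive a deterministic sub-seed (kept < 2^31) from a base seed and indices
sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 40009 + 12345) %% 2147483647
  }
  as.integer(s)
}
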