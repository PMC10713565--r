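#' Simulate a fractional Brownian motion sample path
#'
#' Exact-distribution simulation by circulant embedding of the increment
#' (fractional Gaussian noise) covariance (Davies--Harte construction).
#' The returned path starts at 0 and has `n - 1` stationary increments with
#' unit-scale self-similarity, `E[X(t)^2] = t^(2H)` for integer lags `t`.
#'
#' @param n Path length (number of points, including the starting 0); `>= 16`.
#' @param h Hurst exponent, strictly inside (0, 1).
#' @param seed Optional integer seed; when supplied the path is reproducible.
#' @return Numeric vector of length `n`, `X[1] == 0`.
#' @examples
#' x <- simulate_fbm_profile(256, 0.7, seed = 1)
#' @export
simulate_fbm_profile <- function(n, h, seed = NULL) {
  stopifnot(length(n) == 1, length(h) == 1)
  if (!is.finite(h) || h <= 0 || h >= 1)
    stop("Hurst exponent `h` must lie strictly in (0, 1), got ", h)
  if (!is.finite(n) || n < 16) stop("`n` must be >= 16")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  lam <- fgn_eigenvalues(n - 1L, h)
  m <- length(lam)  # embedding size 2(n-1)
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  incr <- Re(stats::fft(sqrt(lam / m) * z))[seq_len(n - 1L)]
  c(0, cumsum(incr))
}

# Eigenvalues of the circulant embedding of the fGn autocovariance for m
# increments. For fBm the embedding is non-negative definite in theory; tiny
# negative eigenvalues from floating point are zeroed, larger ones are an
# error (the spec'd failure mode, never a silent approximation).
fgn_eigenvalues <- function(m, h) {
  k <- 0:m
  gamma_k <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) +
                    abs(k - 1)^(2 * h))
  row1 <- c(gamma_k, gamma_k[m:2])  # length 2m, circulant first row
  lam <- Re(stats::fft(row1))
  tol <- 1e-8 * max(lam)
  if (min(lam) < -tol)
    stop("circulant embedding not non-negative definite (min eigenvalue ",
         format(min(lam)), "); cannot simulate exactly")
  pmax(lam, 0)
}

#' Simulate a fractional Brownian sheet
#'
#' Separable anisotropic Gaussian random field: the increment field has the
#' product covariance of two fractional Gaussian noises, simulated exactly by
#' two-dimensional circulant embedding, then integrated along both axes.
#' Every row profile is (up to a row-dependent scale factor) an exact
#' fractional Brownian motion with Hurst `h_horizontal`, and every column
#' profile one with Hurst `h_vertical` -- which is what makes the sheet the
#' natural ground truth for a directional Hurst estimator.
#'
#' @param rows,cols Field dimensions in pixels.
#' @param h_vertical Hurst exponent governing column profiles (variation
#'   down the image).
#' @param h_horizontal Hurst exponent governing row profiles.
#' @param seed Optional integer seed.
#' @return `rows x cols` numeric matrix, zero on the first row and column.
#' @export
simulate_fbs_field <- function(rows, cols, h_vertical, h_horizontal,
                               seed = NULL) {
  stopifnot(rows >= 2, cols >= 2)
  for (h in c(h_vertical, h_horizontal))
    if (!is.finite(h) || h <= 0 || h >= 1)
      stop("Hurst exponents must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m1 <- as.integer(rows) - 1L
  m2 <- as.integer(cols) - 1L
  lam1 <- fgn_eigenvalues(m1, h_vertical)   # length 2*m1
  lam2 <- fgn_eigenvalues(m2, h_horizontal) # length 2*m2
  lam <- outer(lam1, lam2)                  # separable embedding spectrum
  z <- matrix(stats::rnorm(length(lam)) + 1i * stats::rnorm(length(lam)),
              nrow = nrow(lam))
  w <- stats::fft(sqrt(lam / length(lam)) * z)
  incr <- Re(w)[seq_len(m1), seq_len(m2), drop = FALSE]
  field <- matrix(0, rows, cols)
  field[-1, -1] <- t(apply(apply(incr, 2, cumsum), 1, cumsum))
  field
}
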