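# Exact fractional Gaussian noise synthesis.
#
# Increments of fractional Brownian motion with Hurst index H are stationary
# Gaussian with autocovariance
#   gamma(k) = 0.5 * (|k+1|^{2H} - 2 |k|^{2H} + |k-1|^{2H})
# (unit-variance single step). Sampling the full covariance matrix through
# its Cholesky factor is exact for any H in (0, 1); track lengths used here
# (<= 4096 steps) keep that factorization cheap, and exactness matters
# because the generator doubles as ground truth for the MSD fitters.

fgn_autocov <- function(k, H) {
  k <- abs(k)
  0.5 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

# n_steps x n_series matrix of unit-variance fGn increments.
fgn_increments <- function(n_steps, H, n_series = 1L) {
  if (H <= 0 || H >= 1) stop("Hurst index must lie in (0, 1)", call. = FALSE)
  if (n_steps > 4096L)
    stop("exact fGn synthesis supported up to 4096 steps per track", call. = FALSE)
  z <- matrix(rnorm(n_steps * n_series), nrow = n_steps)
  if (abs(H - 0.5) < 1e-12) return(z)  # ordinary white noise
  g <- fgn_autocov(0:(n_steps - 1L), H)
  C <- stats::toeplitz(g)
  U <- chol(C)  # C = t(U) %*% U
  crossprod(U, z)
}
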