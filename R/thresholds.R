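# Histogram-based automatic thresholds in the ImageJ dialect: intensities
# are min-max scaled onto 256 levels, the threshold index k separates levels
# {0..k} (background) from {k+1..255} (foreground), and the returned value is
# the intensity at the lower edge of level k+1 so that `image > threshold`
# reproduces the level-domain split.

img_hist256 <- function(image) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: no threshold exists", call. = FALSE)
  lev <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  counts <- tabulate(lev + 1L, nbins = 256L)
  list(counts = counts, lo = lo, hi = hi, width = (hi - lo) / 256)
}

level_to_value <- function(k, h) h$lo + (k + 1) * h$width

#' Otsu threshold (256-level ImageJ dialect)
#'
#' Maximizes the between-class variance over all 256 candidate split levels
#' of the min-max-scaled histogram, and returns the threshold as an intensity
#' value: pixels strictly above it are foreground.
#'
#' @param image Numeric matrix/array of intensities.
#' @return Threshold intensity (scalar); attribute `level` carries the
#'   0-based histogram level.
#' @examples
#' img <- matrix(c(rnorm(500, 10, 1), rnorm(500, 30, 2)), 100)
#' thr <- otsu_threshold(img)
#' mean(img > thr)
#' @export
otsu_threshold <- function(image) {
  h <- img_hist256(image)
  p <- h$counts / sum(h$counts)
  mu <- (0:255) * p
  w0 <- cumsum(p)
  m0 <- cumsum(mu)
  mT <- m0[256]
  # between-class variance at split after level k (0-based k = 0..254)
  w0k <- w0[1:255]; m0k <- m0[1:255]
  valid <- w0k > 0 & w0k < 1
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mT * w0k[valid] - m0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  k <- which.max(bcv) - 1L
  structure(level_to_value(k, h), level = k)
}

#' Renyi-entropy threshold (256-level ImageJ dialect)
#'
#' Entropy-based threshold following the Sahoo three-order formulation used
#' by ImageJ's "RenyiEntropy" method: maximum-entropy split points are found
#' for Renyi orders 1/2, 1 (Shannon/Kapur limit) and 2, then combined with
#' the order-dependent weighting rule into a single level.
#'
#' @param image Numeric matrix/array of intensities.
#' @return Threshold intensity; attributes `level` (combined 0-based level)
#'   and `t_stars` (the three per-order argmax levels).
#' @export
renyi_threshold <- function(image) {
  h <- img_hist256(image)
  p <- h$counts / sum(h$counts)
  P1 <- cumsum(p)
  first <- which(p > 0)[1] - 1L            # 0-based first/last nonzero level
  last <- utils::tail(which(p > 0), 1) - 1L
  if (first >= last) stop("degenerate histogram: no threshold exists",
                          call. = FALSE)
  t1 <- renyi_argmax(p, P1, first, last, rho = 0.5)
  t2 <- renyi_argmax(p, P1, first, last, rho = 1)
  t3 <- renyi_argmax(p, P1, first, last, rho = 2)
  ts <- sort(c(t1, t2, t3))
  b <- renyi_betas(ts[1], ts[2], ts[3])
  omega <- P1[ts[3] + 1L] - P1[ts[1] + 1L]
  k <- floor(ts[1] * (P1[ts[1] + 1L] + 0.25 * omega * b[1]) +
               0.25 * ts[2] * omega * b[2] +
               ts[3] * (1 - P1[ts[3] + 1L] + 0.25 * omega * b[3]))
  structure(level_to_value(k, h), level = as.integer(k),
            t_stars = c(t1, t2, t3))
}

# argmax over split level t (0-based) of the two-class Renyi entropy sum.
renyi_argmax <- function(p, P1, first, last, rho) {
  best <- -Inf; argt <- first
  for (t in first:(last - 1L)) {
    w1 <- P1[t + 1L]; w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    p1 <- p[1:(t + 1L)] / w1
    p2 <- p[(t + 2L):256] / w2
    p1 <- p1[p1 > 0]; p2 <- p2[p2 > 0]
    ent <- if (abs(rho - 1) < 1e-12) {
      -sum(p1 * log(p1)) - sum(p2 * log(p2))
    } else {
      (log(sum(p1^rho)) + log(sum(p2^rho))) / (1 - rho)
    }
    if (ent > best) { best <- ent; argt <- t }
  }
  argt
}

# ImageJ's weighting of the three per-order split points: orders that agree
# (within 5 levels) share the weight, a lone outlier is down-weighted.
renyi_betas <- function(t1, t2, t3) {
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
}
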