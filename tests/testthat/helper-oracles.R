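# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# -- histogram oracles -------------------------------------------------------

# 256-bin histogram exactly as the package builds it (min-max scaled levels).
oracle_hist256 <- function(v) {
  lo <- min(v); hi <- max(v)
  lev <- pmin(floor((as.numeric(v) - lo) / (hi - lo) * 256), 255)
  tabulate(lev + 1L, nbins = 256L)
}

# Exhaustive Otsu: minimize total within-class variance over all split
# levels (equivalent to maximizing between-class variance, but computed the
# "other way" from per-class second moments).
oracle_otsu_level <- function(counts) {
  best <- Inf; argk <- 0L
  lev <- 0:255
  for (k in 0:254) {
    lo <- counts[1:(k + 1)]; hi <- counts[(k + 2):256]
    n0 <- sum(lo); n1 <- sum(hi)
    if (n0 == 0 || n1 == 0) next
    l0 <- lev[1:(k + 1)]; l1 <- lev[(k + 2):256]
    m0 <- sum(lo * l0) / n0; m1 <- sum(hi * l1) / n1
    wcv <- sum(lo * (l0 - m0)^2) + sum(hi * (l1 - m1)^2)
    if (wcv < best) { best <- wcv; argk <- k }
  }
  argk
}

# Exhaustive Renyi-entropy argmax at a given order, written directly from
# the two-class entropy definition.
oracle_renyi_level <- function(counts, rho) {
  p <- counts / sum(counts)
  nz <- which(p > 0)
  first <- nz[1] - 1L; last <- nz[length(nz)] - 1L
  best <- -Inf; argk <- first
  for (k in first:(last - 1L)) {
    w1 <- sum(p[1:(k + 1)]); w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    q1 <- p[1:(k + 1)][p[1:(k + 1)] > 0] / w1
    q2 <- p[(k + 2):256][p[(k + 2):256] > 0] / w2
    ent <- if (rho == 1) -sum(q1 * log(q1)) - sum(q2 * log(q2))
    else (log(sum(q1^rho)) + log(sum(q2^rho))) / (1 - rho)
    if (ent > best) { best <- ent; argk <- k }
  }
  argk
}

# -- power-law grid oracle ---------------------------------------------------

# Brute-force search over the exponent minimizing squared log-residuals,
# with the log-prefactor profiled out at its per-exponent optimum
# (la(ex) = mean(log y - ex log x), the SSE minimizer for fixed ex);
# the exponent grid is refined around the best point.
oracle_powerlaw <- function(x, y, expo_range = c(-1, 3)) {
  lx <- log(x); ly <- log(y)
  best_ex <- NA; best_la <- NA
  for (pass in 1:4) {
    exs <- seq(expo_range[1], expo_range[2], length.out = 2001)
    sse <- vapply(exs, function(ex) {
      la <- mean(ly - ex * lx)
      sum((ly - la - ex * lx)^2)
    }, numeric(1))
    i <- which.min(sse)
    best_ex <- exs[i]; best_la <- mean(ly - best_ex * lx)
    step <- diff(expo_range) / 2000
    expo_range <- c(best_ex - 2 * step, best_ex + 2 * step)
  }
  c(prefactor = exp(best_la), exponent = best_ex)
}

# -- geometric fixtures ------------------------------------------------------

disk_mask <- function(n, radius_px, centre = (n + 1) / 2) {
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  (ii - centre)^2 + (jj - centre)^2 <= radius_px^2
}

# Movie of k rendered disks of given radii (px), constant over frames.
disk_movie <- function(n, centres, radii_px, frames = 3, fg = 200, bg = 10) {
  frame <- matrix(bg, n, n)
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  for (q in seq_len(nrow(centres)))
    frame[(ii - centres[q, 1])^2 + (jj - centres[q, 2])^2 <= radii_px[q]^2] <- fg
  array(rep(frame, frames), c(n, n, frames))
}

# Per-track alpha fits of a trajectory set; returns the fitted exponents.
per_track_alphas <- function(set, max_lag_frac = 0.25) {
  dt <- attr(set, "frame_interval")
  trs <- split(as.data.frame(set), set$track_id)
  vapply(trs, function(tr) {
    m <- msd_single(tr, frame_interval = dt, max_lag_frac = max_lag_frac)
    fit_anomalous(m, fit_window = range(m$lag_s))$alpha
  }, numeric(1))
}
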