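#' Mean square displacement curves
#'
#' Constructor for MSD curves: lag times in seconds (strictly increasing),
#' MSD values in um^2, the number of displacement pairs entering each lag and
#' the estimator mode (`single_point`, `ensemble` or `pairwise`).
#'
#' @param lags Lag times, s.
#' @param msd MSD values, um^2.
#' @param n_pairs Number of (possibly overlapping) displacement pairs per lag.
#' @param mode Estimator mode.
#' @return An `msd_curve` data frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs`.
#' @export
msd_curve <- function(lags, msd, n_pairs,
                      mode = c("single_point", "ensemble", "pairwise")) {
  mode <- match.arg(mode)
  keep <- n_pairs >= 1
  lags <- lags[keep]; msd <- msd[keep]; n_pairs <- n_pairs[keep]
  if (is.unsorted(lags, strictly = TRUE))
    stop("lags must be strictly increasing", call. = FALSE)
  if (any(msd < 0)) stop("msd must be >= 0", call. = FALSE)
  structure(data.frame(lag_s = lags, msd_um2 = msd, n_pairs = n_pairs),
            mode = mode, class = c("msd_curve", "data.frame"))
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve (%s): %d lags, %.4g-%.4g s\n",
              attr(x, "mode"), nrow(x), min(x$lag_s), max(x$lag_s)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ..., log = "xy") {
  plot(x$lag_s, x$msd_um2, log = log, xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

# Time-averaged squared displacement of one track at every integer frame lag,
# over all ordered pairs. Returns data.frame(k, msd, n).
tamsd_one <- function(x, y, max_lag_frames = length(x) - 1L) {
  L <- length(x)
  ks <- seq_len(min(max_lag_frames, L - 1L))
  msd <- numeric(length(ks)); n <- integer(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    dx <- x[(k + 1):L] - x[1:(L - k)]
    dy <- y[(k + 1):L] - y[1:(L - k)]
    msd[i] <- mean(dx * dx + dy * dy)
    n[i] <- L - k
  }
  data.frame(k = ks, msd = msd, n = n)
}

#' Single-track and ensemble MSD
#'
#' `msd_single()` computes the time-averaged MSD of one track over all
#' ordered position pairs at each frame lag. `msd_ensemble()` averages the
#' per-track time-averaged MSDs across a set, weighting each track's value at
#' a lag by its number of displacement pairs.
#'
#' @param track One track: a data frame with `frame`, `x_um`, `y_um` (rows
#'   sorted by frame), or a `trajectory_set` containing a single track.
#' @param frame_interval Frame interval in s (taken from the set attribute
#'   when a `trajectory_set` is given).
#' @param max_lag_frac Longest lag used, as a fraction of the track length.
#' @return An [msd_curve()].
#' @examples
#' tr <- data.frame(frame = 0:2, x_um = c(0, 1, 2), y_um = 0)
#' msd_single(tr, frame_interval = 1)  # 1 um^2 at 1 s, 4 um^2 at 2 s
#' @export
msd_single <- function(track, frame_interval = attr(track, "frame_interval"),
                       max_lag_frac = 1) {
  track <- as.data.frame(track)
  if ("track_id" %in% names(track) && length(unique(track$track_id)) > 1L)
    stop("msd_single() expects a single track; use msd_ensemble()",
         call. = FALSE)
  track <- track[order(track$frame), ]
  m <- tamsd_one(track$x_um, track$y_um,
                 max_lag_frames = max(1L, floor(max_lag_frac * nrow(track))))
  msd_curve(m$k * frame_interval, m$msd, m$n, mode = "single_point")
}

#' @rdname msd_single
#' @param set A `trajectory_set`.
#' @param min_track_len Tracks shorter than this many frames are dropped.
#' @export
msd_ensemble <- function(set, min_track_len = 10L, max_lag_frac = 1) {
  dt <- attr(set, "frame_interval")
  trs <- split_tracks(set)
  trs <- trs[vapply(trs, nrow, integer(1)) >= min_track_len]
  if (!length(trs)) stop("no track of length >= min_track_len", call. = FALSE)
  per <- lapply(trs, function(tr) {
    tr <- tr[order(tr$frame), ]
    tamsd_one(tr$x_um, tr$y_um,
              max_lag_frames = max(1L, floor(max_lag_frac * nrow(tr))))
  })
  all <- do.call(rbind, per)
  agg_num <- tapply(all$msd * all$n, all$k, sum)
  agg_den <- tapply(all$n, all$k, sum)
  ks <- as.integer(names(agg_num))
  o <- order(ks)
  msd_curve(ks[o] * dt, (agg_num / agg_den)[o], as.integer(agg_den)[o],
            mode = "ensemble")
}

#' Pairwise (relative) MSD
#'
#' MSD of the relative separation vector between co-imaged track pairs,
#' divided by two so that for independent identical diffusers it matches the
#' single-particle MSD. Any motion common to both particles of a pair --
#' in particular uniform drift -- cancels exactly in the separation vector.
#'
#' @param set A `trajectory_set` with at least two tracks that overlap in
#'   time.
#' @param min_overlap Minimum number of shared frames for a pair to be used.
#' @param max_pairs Random-free cap on the number of pairs (the first
#'   `max_pairs` in id order) to bound cost on dense sets.
#' @param max_lag_frac Longest lag used, as a fraction of each pair's overlap.
#' @return An [msd_curve()] with mode `"pairwise"`.
#' @export
msd_pairwise <- function(set, min_overlap = 10L, max_pairs = 2000L,
                         max_lag_frac = 1) {
  dt <- attr(set, "frame_interval")
  trs <- split_tracks(set)
  ids <- names(trs)
  if (length(ids) < 2L) stop("pairwise MSD needs >= 2 tracks", call. = FALSE)
  per <- list(); np <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- trs[[i]]; b <- trs[[j]]
      common <- intersect(a$frame, b$frame)
      if (length(common) < min_overlap) next
      common <- sort(common)
      ai <- match(common, a$frame); bi <- match(common, b$frame)
      # relative separation; consecutive common frames only (gaps allowed in
      # `common` are handled by using the true frame numbers as lags)
      rx <- a$x_um[ai] - b$x_um[bi]
      ry <- a$y_um[ai] - b$y_um[bi]
      L <- length(common)
      max_k <- max(1L, floor(max_lag_frac * L))
      contiguous <- all(diff(common) == diff(common)[1])
      if (L > 200L && contiguous) {
        # all-pairs evaluation is quadratic in L; on a regular frame grid the
        # single-track routine gives the identical time average
        m <- tamsd_one(rx, ry, max_lag_frames = max_k)
        d <- data.frame(k = m$k * diff(common)[1], msd = m$msd, n = m$n)
      } else {
        kk <- outer(common, common, `-`)
        keep <- which(kk > 0 & kk <= max_k, arr.ind = TRUE)
        dk <- kk[keep]
        d2 <- (rx[keep[, 1]] - rx[keep[, 2]])^2 +
          (ry[keep[, 1]] - ry[keep[, 2]])^2
        agg <- tapply(d2, dk, mean)
        cnt <- tapply(d2, dk, length)
        d <- data.frame(k = as.integer(names(agg)), msd = as.numeric(agg),
                        n = as.integer(cnt))
      }
      np <- np + 1L
      per[[np]] <- d
      if (np >= max_pairs) break
    }
    if (np >= max_pairs) break
  }
  if (!np) stop("no co-existing track pairs with sufficient overlap",
                call. = FALSE)
  all <- do.call(rbind, per)
  num <- tapply(all$msd * all$n, all$k, sum)
  den <- tapply(all$n, all$k, sum)
  ks <- as.integer(names(num)); o <- order(ks)
  msd_curve(ks[o] * dt, (num / den)[o] / 2, as.integer(den)[o],
            mode = "pairwise")
}

#' Fit the anomalous diffusion model MSD = D * t^alpha
#'
#' Ordinary least squares of `log(MSD)` on `log(lag)` inside the fit window:
#' `alpha` is the slope and `D = exp(intercept)` (so lag times must be in
#' seconds and MSD in um^2 for D in um^2/s^alpha). Nonpositive MSD values
#' inside the window are excluded; at least four lags must remain.
#'
#' @param msd An [msd_curve()].
#' @param fit_window Numeric `c(min_lag_s, max_lag_s)`. Default: from the
#'   shortest available lag to 25% of the longest lag, the usual
#'   bias/variance compromise for time-averaged MSDs.
#' @param offset Optional constant (um^2, e.g. a localization-noise floor
#'   `4 * sigma^2`) subtracted from the MSD before fitting. Default 0: the
#'   raw MSD is fitted.
#' @return An `anomalous_fit` with fields `D`, `alpha`, `fit_window`,
#'   `r_squared`, `n_lags`.
#' @examples
#' m <- msd_curve(lags = (1:20) / 10, msd = 0.2 * ((1:20) / 10)^0.75,
#'                n_pairs = rep(100, 20))
#' coef(fit_anomalous(m))
#' @export
fit_anomalous <- function(msd, fit_window = NULL, offset = 0) {
  if (is.null(fit_window))
    fit_window <- c(min(msd$lag_s), 0.25 * max(msd$lag_s))
  sel <- msd$lag_s >= fit_window[1] - 1e-12 & msd$lag_s <= fit_window[2] + 1e-12
  y <- msd$msd_um2[sel] - offset
  x <- msd$lag_s[sel]
  ok <- y > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L)
    stop("fewer than 4 positive MSD values inside the fit window",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log(x)), log(y))
  co <- fit$coefficients
  r2 <- 1 - sum(fit$residuals^2) / sum((log(y) - mean(log(y)))^2)
  if (!is.finite(r2)) r2 <- 1  # zero-variance response: exact power law
  structure(list(D = exp(co[[1]]), alpha = co[[2]], fit_window = fit_window,
                 r_squared = r2, n_lags = length(x)),
            class = "anomalous_fit")
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf("Anomalous diffusion fit: MSD = D * t^alpha\n  D = %.4g um^2/s^alpha, alpha = %.3f  (window %.3g-%.3g s, %d lags, R^2 = %.4f)\n",
              x$D, x$alpha, x$fit_window[1], x$fit_window[2], x$n_lags,
              x$r_squared))
  invisible(x)
}

#' @export
coef.anomalous_fit <- function(object, ...) {
  c(D = object$D, alpha = object$alpha)
}

#' @export
predict.anomalous_fit <- function(object, lags, ...) {
  object$D * lags^object$alpha
}
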