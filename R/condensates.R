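#' Segment condensates in an activation movie
#'
#' Each frame is Gaussian-blurred (1 px kernel) and thresholded with a fixed
#' Renyi-entropy threshold determined once on the reference frame (default:
#' 1 min after activation, when condensate size reaches quasi-equilibrium)
#' and reused for every frame. Connected components of at least `min_px`
#' pixels become droplets; the centroid is the intensity-weighted centre of
#' mass of the component's pixels.
#'
#' @param movie An `image_stack` (3D array, rows x cols x frames) with
#'   `pixel_size` and `frame_interval` attributes, or a plain array plus the
#'   two calibration arguments.
#' @param reference_time Time (s) of the threshold-setting frame.
#' @param blur_sigma_px Blur s.d. in pixels.
#' @param min_px Minimum droplet size in pixels (rejects single-pixel
#'   noise without suppressing nascent condensates).
#' @param pixel_size,frame_interval Calibration overrides.
#' @param threshold Optional frozen threshold; when supplied the reference
#'   frame is not consulted, making re-segmentation idempotent.
#' @return A `droplet_table` data frame: `frame` (0-based), `t_s`,
#'   `droplet_id` (frame-local), `area_um2`, `diameter_um`
#'   (`= 2 * sqrt(area / pi)`), `x_um`, `y_um`; attribute `threshold` holds
#'   the frozen value. An empty segmentation at the reference frame gives a
#'   warning and an all-frames-empty table.
#' @export
segment_droplets <- function(movie, reference_time = 60, blur_sigma_px = 1,
                             min_px = 4L,
                             pixel_size = attr(movie, "pixel_size"),
                             frame_interval = attr(movie, "frame_interval"),
                             threshold = NULL) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  nfr <- dim(movie)[3]
  blur <- function(m) as.matrix(EBImage::gblur(EBImage::Image(m),
                                               sigma = blur_sigma_px))
  empty <- data.frame(frame = integer(0), t_s = numeric(0),
                      droplet_id = integer(0), area_um2 = numeric(0),
                      diameter_um = numeric(0), x_um = numeric(0),
                      y_um = numeric(0))
  if (is.null(threshold)) {
    ref <- round(reference_time / frame_interval) + 1L
    if (ref < 1L || ref > nfr)
      stop("reference frame lies outside the movie", call. = FALSE)
    refsm <- blur(movie[, , ref])
    if (max(refsm) == min(refsm)) {
      warning("reference frame is constant: nothing to segment")
      return(structure(empty, threshold = NA_real_,
                       class = c("droplet_table", "data.frame")))
    }
    threshold <- as.numeric(renyi_threshold(refsm))
    if (!any(refsm > threshold)) {
      warning("reference frame segmentation is empty")
      return(structure(empty, threshold = threshold,
                       class = c("droplet_table", "data.frame")))
    }
  }
  out <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    sm <- blur(movie[, , f])
    fg <- sm > threshold
    if (!any(fg)) next
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(fg * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_px)
    if (!length(keep)) next
    drops <- lapply(seq_along(keep), function(q) {
      idx <- which(lab == keep[q], arr.ind = TRUE)
      w <- movie[, , f][idx]
      area <- nrow(idx) * pixel_size^2
      data.frame(frame = f - 1L, t_s = (f - 1L) * frame_interval,
                 droplet_id = q, area_um2 = area,
                 diameter_um = 2 * sqrt(area / pi),
                 x_um = px_to_um(sum(w * idx[, 2]) / sum(w), pixel_size),
                 y_um = px_to_um(sum(w * idx[, 1]) / sum(w), pixel_size))
    })
    out[[f]] <- do.call(rbind, drops)
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(tab)) tab <- empty
  structure(tab, threshold = threshold,
            class = c("droplet_table", "data.frame"))
}

#' Per-frame droplet count and mean diameter
#'
#' @param table A `droplet_table` (from [segment_droplets()] or a
#'   `coalescence_sim$droplets` slot).
#' @return Data frame `t_s`, `count`, `mean_diameter_um`, one row per frame
#'   present in the table.
#' @export
droplet_timeseries <- function(table) {
  if (!nrow(table)) stop("empty droplet table", call. = FALSE)
  agg <- split(table$diameter_um, table$t_s)
  data.frame(t_s = as.numeric(names(agg)),
             count = vapply(agg, length, integer(1)),
             mean_diameter_um = vapply(agg, mean, numeric(1)),
             row.names = NULL)
}

#' Fit the coarsening exponent of droplet growth
#'
#' Ordinary least squares of `log(mean diameter)` on `log(t)` within the
#' analysis window. The default window starts at 60 s (the early
#' nucleation-dominated minute is discarded) and runs to the end of the
#' series. Frames with no droplets are excluded; at least 5 frames must
#' remain.
#'
#' @param series Output of [droplet_timeseries()].
#' @param window `c(t_min, t_max)` in seconds.
#' @return A `coarsening_fit`: `exponent`, `prefactor` (um at t = 1 s),
#'   `window`, `r_squared`, `n_frames`.
#' @examples
#' s <- data.frame(t_s = 60:180, count = 10,
#'                 mean_diameter_um = 0.5 * (60:180)^0.16)
#' coef(fit_coarsening(s))
#' @export
fit_coarsening <- function(series, window = c(60, Inf)) {
  sel <- series$t_s >= window[1] & series$t_s <= window[2] &
    series$count >= 1 & series$t_s > 0
  d <- series[sel, ]
  if (nrow(d) < 5L)
    stop("fewer than 5 usable frames inside the window", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log(d$t_s)), log(d$mean_diameter_um))
  co <- fit$coefficients
  ss_tot <- sum((log(d$mean_diameter_um) - mean(log(d$mean_diameter_um)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(exponent = co[[2]], prefactor = exp(co[[1]]),
                 window = c(min(d$t_s), max(d$t_s)), r_squared = r2,
                 n_frames = nrow(d)),
            class = "coarsening_fit")
}

#' @export
print.coarsening_fit <- function(x, ...) {
  cat(sprintf("Coarsening fit: d = %.4g * t^%.3f (window %.3g-%.3g s, %d frames, R^2 = %.4f)\n",
              x$prefactor, x$exponent, x$window[1], x$window[2], x$n_frames,
              x$r_squared))
  invisible(x)
}

#' @export
coef.coarsening_fit <- function(object, ...) {
  c(prefactor = object$prefactor, exponent = object$exponent)
}

#' Brownian-coalescence scaling check
#'
#' Ratio of the coarsening exponent (mean-diameter growth) to the diffusive
#' exponent of the droplet trajectories, over matched time windows. For
#' Brownian-motion-driven coalescence with Stokes-like mobility and area
#' conservation, the expected ratio is 1/3.
#'
#' The diffusive exponent is the mean of per-track power-law fits: droplet
#' mobility is size-dependent, so long-lived tracks are systematically the
#' slow large droplets and a pooled ensemble MSD would mix mobilities
#' differently at different lags (biasing its apparent exponent down);
#' per-track fits see stationary mobility by construction. The coarsening
#' fit starts after the initial collision-free transient (5% of the run)
#' and stops once fewer than 10% of the initial droplets remain, where the
#' mean diameter becomes jump-dominated.
#'
#' @param sim A `coalescence_sim` from [gen_coalescence()].
#' @param window Analysis window `c(t_min, t_max)` (s) for the coarsening
#'   fit; default `c(0.05 * t_max, t_max)`.
#' @param min_count_frac Frames with fewer droplets than this fraction of
#'   the initial count are excluded from the coarsening fit.
#' @param min_track_len Minimum droplet-track length (frames) used in the
#'   trajectory MSD fits.
#' @param exponent_mode `"per_track"` (mean of per-track fits, default) or
#'   `"ensemble"` (single fit of the pooled ensemble MSD).
#' @return List `ratio`, `coarsening` (the [fit_coarsening()] object),
#'   `alpha` (diffusive exponent used), `n_tracks`.
#' @export
coalescence_scaling_check <- function(sim, window = NULL,
                                      min_count_frac = 0.1,
                                      min_track_len = 20L,
                                      exponent_mode = c("per_track",
                                                        "ensemble")) {
  exponent_mode <- match.arg(exponent_mode)
  tmax <- max(sim$droplets$t_s)
  if (is.null(window)) window <- c(0.05 * tmax, tmax)
  series <- droplet_timeseries(sim$droplets)
  n_init <- series$count[series$t_s == min(series$t_s)]
  series <- series[series$count >= min_count_frac * n_init, ]
  cf <- fit_coarsening(series, window = window)
  tracks <- coalescence_tracks(sim)
  if (exponent_mode == "ensemble") {
    m <- msd_ensemble(tracks, min_track_len = min_track_len,
                      max_lag_frac = 0.25)
    alpha <- fit_anomalous(m)$alpha
    n_tracks <- NA_integer_
  } else {
    trs <- split_tracks(tracks)
    trs <- trs[vapply(trs, nrow, integer(1)) >= min_track_len]
    al <- vapply(trs, function(tr) {
      m <- msd_single(tr, frame_interval = sim$frame_interval,
                      max_lag_frac = 0.25)
      tryCatch(fit_anomalous(m, fit_window = range(m$lag_s))$alpha,
               error = function(e) NA_real_)
    }, numeric(1))
    alpha <- mean(al, na.rm = TRUE)
    n_tracks <- sum(is.finite(al))
  }
  list(ratio = cf$exponent / alpha, coarsening = cf, alpha = alpha,
       n_tracks = n_tracks)
}
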