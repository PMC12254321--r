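#' Per-track MSD amplitude distribution and bimodality call
#'
#' Computes each qualifying track's time-averaged MSD at a given lag and
#' decides whether the distribution of log10 amplitudes is unimodal or
#' bimodal by comparing 1- against 2-component Gaussian mixtures with BIC:
#' the distribution is called bimodal when BIC improves by more than
#' `delta_bic` for two components. A mixed particle environment (e.g. probes
#' sampling dense and sparse chromatin) shows up as bimodal; a homogenized
#' one as unimodal.
#'
#' @param set A `trajectory_set`.
#' @param lag Requested lag in seconds; the nearest available integer frame
#'   lag is used and must lie within half a frame interval of the request.
#' @param min_track_len Tracks must span at least this many frames.
#' @param delta_bic BIC margin required to call two components.
#' @return An `amplitude_distribution`: list with `lag_s`, `values` (um^2,
#'   one per track), `modality` (`"unimodal"`, `"bimodal"` or
#'   `"undetermined"` when < 20 tracks qualify), `component_means` (um^2,
#'   log-domain means back-transformed), `mixing_fractions`, `delta_bic`.
#' @importFrom mclust Mclust mclustBIC
#' @export
amplitude_distribution <- function(set, lag = 0.1, min_track_len = 10L,
                                   delta_bic = 6) {
  dt <- attr(set, "frame_interval")
  k <- round(lag / dt)
  if (k < 1 || abs(k * dt - lag) > dt / 2 + 1e-9)
    stop("requested lag is not resolvable at this frame interval",
         call. = FALSE)
  trs <- split_tracks(set)
  vals <- vapply(trs, function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < max(min_track_len, k + 1L)) return(NA_real_)
    dx <- tr$x_um[(k + 1):nrow(tr)] - tr$x_um[1:(nrow(tr) - k)]
    dy <- tr$y_um[(k + 1):nrow(tr)] - tr$y_um[1:(nrow(tr) - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  vals <- vals[is.finite(vals) & vals > 0]
  out <- list(lag_s = k * dt, values = as.numeric(vals),
              modality = "undetermined", component_means = NA_real_,
              mixing_fractions = NA_real_, delta_bic = NA_real_)
  if (length(vals) < 20L) {
    class(out) <- "amplitude_distribution"
    return(out)
  }
  lv <- log10(vals)
  # model "V": univariate, unequal variances
  m1 <- Mclust(lv, G = 1, modelNames = "V", verbose = FALSE)
  m2 <- Mclust(lv, G = 2, modelNames = "V", verbose = FALSE)
  # mclust BIC is 2*loglik - penalty: larger is better
  dbic <- m2$bic - m1$bic
  if (is.finite(dbic) && dbic > delta_bic) {
    out$modality <- "bimodal"
    out$component_means <- 10^as.numeric(m2$parameters$mean)
    out$mixing_fractions <- as.numeric(m2$parameters$pro)
  } else {
    out$modality <- "unimodal"
    out$component_means <- 10^as.numeric(m1$parameters$mean)
    out$mixing_fractions <- 1
  }
  out$delta_bic <- dbic
  class(out) <- "amplitude_distribution"
  out
}

#' @export
print.amplitude_distribution <- function(x, ...) {
  cat(sprintf("MSD amplitude distribution at lag %.3g s: %d tracks, %s",
              x$lag_s, length(x$values), x$modality))
  if (x$modality == "bimodal")
    cat(sprintf(" (means %.3g / %.3g um^2, fractions %.2f / %.2f, dBIC %.1f)",
                x$component_means[1], x$component_means[2],
                x$mixing_fractions[1], x$mixing_fractions[2], x$delta_bic))
  cat("\n")
  invisible(x)
}

#' Classify tracks as nuclear interior vs periphery
#'
#' Builds the interior mask by binary erosion of the nucleus mask (see
#' [interior_periphery()]), assigns each track to the region containing the
#' majority of its positions, and drops tracks that mostly lie outside the
#' nucleus (their number is reported in the `dropped` attribute).
#'
#' @param set A `trajectory_set` in um, sharing the calibration of `mask`.
#' @param nucleus_mask Logical matrix (nucleus = TRUE).
#' @param erosion_radius_px Erosion radius in pixels (default 3 px, ~0.4 um
#'   at 0.133 um/px).
#' @param pixel_size Pixel size, um/px.
#' @return Data frame `track_id`, `region` (`"interior"` / `"periphery"`),
#'   with attribute `dropped` (number of tracks outside the nucleus).
#' @export
classify_region <- function(set, nucleus_mask, erosion_radius_px = 3L,
                            pixel_size = 0.133) {
  masks <- interior_periphery(nucleus_mask, erosion_radius_px)
  trs <- split_tracks(set)
  nr <- nrow(nucleus_mask); nc <- ncol(nucleus_mask)
  lab <- vapply(trs, function(tr) {
    i <- pmin(pmax(round(um_to_px(tr$y_um, pixel_size)), 1), nr)
    j <- pmin(pmax(round(um_to_px(tr$x_um, pixel_size)), 1), nc)
    lin <- cbind(i, j)
    n_int <- sum(masks$interior[lin])
    n_per <- sum(masks$periphery[lin])
    n_out <- nrow(tr) - n_int - n_per
    if (n_out >= max(n_int, n_per)) return(NA_character_)
    if (n_int >= n_per) "interior" else "periphery"
  }, character(1))
  dropped <- sum(is.na(lab))
  out <- data.frame(track_id = names(trs)[!is.na(lab)],
                    region = lab[!is.na(lab)], row.names = NULL)
  attr(out, "dropped") <- dropped
  out
}
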