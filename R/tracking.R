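#' Detect diffraction-limited spots in a single frame
#'
#' Gaussian-blurs the frame, keeps local maxima above an intensity
#' percentile, and refines each to a sub-pixel position with an
#' intensity-weighted centroid over a small window (local minimum
#' subtracted). Detections closer than `min_sep` pixels are de-duplicated,
#' the brightest winning.
#'
#' @param frame_image Numeric matrix (single 2D frame; rows = y, cols = x).
#' @param blur_sigma Gaussian blur s.d. in pixels applied before the maximum
#'   search.
#' @param intensity_percentile Detections must exceed this percentile of the
#'   blurred image (0-1).
#' @param window Half-width in pixels of the centroid refinement window.
#' @param min_sep Minimum separation between detections, pixels.
#' @param pixel_size Pixel size in um/px used to report physical positions.
#' @return Data frame with one row per detection: `x_px`, `y_px` (0-based
#'   pixel coordinates of the centroid), `x_um`, `y_um`, `intensity`.
#'   An empty image yields an empty data frame, not an error.
#' @export
detect_spots <- function(frame_image, blur_sigma = 1,
                         intensity_percentile = 0.995, window = 3L,
                         min_sep = 3, pixel_size = 1) {
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0))
  if (!length(frame_image) || max(frame_image) == min(frame_image))
    return(empty)
  img <- as.matrix(frame_image)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  thr <- stats::quantile(sm, intensity_percentile)
  nr <- nrow(sm); nc <- ncol(sm)
  # local maxima: strictly greater than the max of the 8-neighbourhood
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  nb <- array(-Inf, c(nr, nc, 8))
  k <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    k <- k + 1
    nb[, , k] <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  ismax <- sm > apply(nb, c(1, 2), max) & sm > thr
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  w <- as.integer(window)
  res <- lapply(seq_len(nrow(idx)), function(q) {
    i <- idx[q, 1]; j <- idx[q, 2]
    ii <- max(1, i - w):min(nr, i + w)
    jj <- max(1, j - w):min(nc, j + w)
    patch <- img[ii, jj, drop = FALSE] - min(img[ii, jj])
    tot <- sum(patch)
    if (tot <= 0) return(c(i, j, img[i, j]))
    ci <- sum(outer(ii, rep(1, length(jj))) * patch) / tot
    cj <- sum(outer(rep(1, length(ii)), jj) * patch) / tot
    c(ci, cj, sum(img[ii, jj]))
  })
  res <- do.call(rbind, res)
  det <- data.frame(row = res[, 1], col = res[, 2], intensity = res[, 3])
  det <- det[order(-det$intensity), ]
  # greedy suppression of duplicates within min_sep px (brightest wins)
  keep <- logical(nrow(det))
  for (q in seq_len(nrow(det))) {
    if (!any(keep)) { keep[q] <- TRUE; next }
    d2 <- (det$row[keep] - det$row[q])^2 + (det$col[keep] - det$col[q])^2
    if (min(d2) >= min_sep^2) keep[q] <- TRUE
  }
  det <- det[keep, ]
  data.frame(x_px = det$col - 1, y_px = det$row - 1,
             x_um = px_to_um(det$col, pixel_size),
             y_um = px_to_um(det$row, pixel_size),
             intensity = det$intensity)
}

#' Link detections into trajectories
#'
#' Frame-to-frame linking by ascending squared displacement: candidate
#' (track, detection) pairs within `max_disp` are assigned greedily from the
#' closest pair upward, which coincides with the global least-squares
#' assignment whenever particles are separated by more than twice their
#' displacements. Ties in cost are broken by detection order. Tracks missing
#' for up to `memory` frames may be bridged. Crossing particles closer than
#' `max_disp` can swap identity; the QC counts report how many links competed
#' for the same detection rather than hiding it.
#'
#' @param detections_per_frame List of detection data frames (as from
#'   [detect_spots()]), one per frame, each with `x_um`, `y_um`.
#' @param max_disp Maximum link displacement, um.
#' @param memory Number of frames a track may go undetected and still be
#'   continued.
#' @param frame_interval Frame interval, s.
#' @return A [as_trajectory_set()]; attribute `qc` holds
#'   `c(contested_links, new_tracks)`.
#' @export
link <- function(detections_per_frame, max_disp, memory = 0L,
                 frame_interval = 1) {
  stopifnot_scalar_pos(max_disp, "max_disp")
  active <- list()  # each: list(id, x, y, last_frame, rows)
  rows <- list(); next_id <- 1L; contested <- 0L
  for (f in seq_along(detections_per_frame)) {
    det <- detections_per_frame[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    assigned_det <- rep(FALSE, max(nd, 0L))
    assigned_trk <- rep(FALSE, length(active))
    if (nd > 0 && length(active) > 0) {
      cand <- expand.grid(trk = seq_along(active), d = seq_len(nd))
      cand$cost <- (vapply(active[cand$trk], `[[`, numeric(1), "x") -
                      det$x_um[cand$d])^2 +
                   (vapply(active[cand$trk], `[[`, numeric(1), "y") -
                      det$y_um[cand$d])^2
      cand <- cand[cand$cost <= max_disp^2, ]
      cand <- cand[order(cand$cost, cand$d), ]
      for (q in seq_len(nrow(cand))) {
        tr <- cand$trk[q]; dd <- cand$d[q]
        if (assigned_trk[tr] && !assigned_det[dd]) contested <- contested + 1L
        if (assigned_trk[tr] || assigned_det[dd]) next
        assigned_trk[tr] <- TRUE; assigned_det[dd] <- TRUE
        active[[tr]]$x <- det$x_um[dd]; active[[tr]]$y <- det$y_um[dd]
        active[[tr]]$last_frame <- f
        rows[[length(rows) + 1L]] <- data.frame(
          track_id = active[[tr]]$id, frame = f - 1L,
          x_um = det$x_um[dd], y_um = det$y_um[dd])
      }
    }
    # unmatched detections start new tracks
    if (nd > 0) for (dd in which(!assigned_det)) {
      active[[length(active) + 1L]] <- list(id = next_id, x = det$x_um[dd],
                                            y = det$y_um[dd], last_frame = f)
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = next_id, frame = f - 1L,
        x_um = det$x_um[dd], y_um = det$y_um[dd])
      next_id <- next_id + 1L
    }
    # retire tracks beyond the memory horizon
    if (length(active))
      active <- Filter(function(a) f - a$last_frame <= memory, active)
  }
  if (!length(rows)) stop("no detections to link", call. = FALSE)
  set <- as_trajectory_set(do.call(rbind, rows), frame_interval)
  attr(set, "qc") <- c(contested_links = contested,
                       new_tracks = next_id - 1L)
  set
}
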