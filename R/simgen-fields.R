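#' Synthetic heterogeneous chromatin field
#'
#' Renders an elliptical nucleus whose intra-nuclear intensity is a low-pass
#' filtered Gaussian random field, exponentiated (to give blob-like bright
#' clusters) and affinely rescaled so the within-mask coefficient of
#' variation, measured against the returned background level, equals
#' `cov_target`. Outside the mask, pixels are Poisson draws around
#' `background_level`; inside, the field is noiseless so the ground-truth
#' COV is exact.
#'
#' @param cov_target Target COV (>= 0; 0 gives a uniform nucleus). Targets
#'   much above ~1.8 exceed what the lognormal-like texture can reach and
#'   raise an error.
#' @param geometry Ellipse semi-axes in um, `c(a, b)`; must fit in the field
#'   of view.
#' @param config A [sim_config()].
#' @param mean_level Mean intra-nuclear intensity above background (a.u.).
#' @param background_level Background intensity (a.u., >= 0).
#' @param corr_length_um Correlation length of the chromatin texture, um.
#' @return A `chromatin_ground_truth`: list with `intensity_field` (matrix),
#'   `nucleus_mask` (logical matrix), `true_cov`, `background_level`.
#' @examples
#' g <- gen_chromatin_field(0.4, geometry = c(5, 4), config = sim_config(1))
#' compute_cov(g$intensity_field, g$nucleus_mask, g$background_level)$cov
#' @export
gen_chromatin_field <- function(cov_target, geometry = c(6, 4.5),
                                config = sim_config(), mean_level = 1000,
                                background_level = 100,
                                corr_length_um = 0.8) {
  if (cov_target < 0) stop("`cov_target` must be >= 0", call. = FALSE)
  if (background_level < 0) stop("`background_level` must be >= 0",
                                 call. = FALSE)
  shape <- config$image_shape
  px <- config$pixel_size
  if (2 * geometry[1] > shape[2] * px || 2 * geometry[2] > shape[1] * px)
    stop("nucleus geometry does not fit in the field of view", call. = FALSE)
  with_stream(child_seed(config$seed, "chromatin"), {
    ci <- shape[1] / 2; cj <- shape[2] / 2
    ii <- matrix(seq_len(shape[1]), shape[1], shape[2])
    jj <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    mask <- ((jj - cj) * px / geometry[1])^2 +
      ((ii - ci) * px / geometry[2])^2 <= 1
    field <- matrix(rpois(prod(shape), background_level), shape[1], shape[2])
    if (any(mask)) {
      g <- matrix(rnorm(prod(shape)), shape[1], shape[2])
      g <- as.matrix(EBImage::gblur(EBImage::Image(g),
                                    sigma = corr_length_um / px))
      g <- (g - mean(g[mask])) / sd(g[mask])
      h <- exp(1.3 * g)  # intrinsic COV ~ 2, enough headroom to rescale down
      m_h <- mean(h[mask]); s_h <- sqrt(mean((h[mask] - m_h)^2))
      if (cov_target == 0) {
        inside <- rep(mean_level, sum(mask))
      } else {
        if (s_h / m_h <= cov_target)
          stop("cov_target exceeds the reachable texture contrast",
               call. = FALSE)
        # intensity = a + b*h with COV = b*s_h / (a + b*m_h) = cov_target
        # and mean fixed at mean_level
        b <- cov_target * mean_level / s_h
        a <- mean_level - b * m_h
        inside <- a + b * h[mask]
        if (min(inside) + background_level < 0)
          stop("cov_target too large for a non-negative field", call. = FALSE)
      }
      field[mask] <- background_level + inside
    }
    structure(list(intensity_field = field, nucleus_mask = mask,
                   true_cov = cov_target, background_level = background_level),
              class = "chromatin_ground_truth")
  })
}

#' Render a trajectory set as a synthetic fluorescence movie
#'
#' Each particle becomes a Gaussian spot of width `psf_sigma` on a Poisson
#' background; photon shot noise applies to spot and background alike. The
#' peak spot amplitude is `snr * sqrt(background)`, the conventional
#' peak-to-noise definition. Ground-truth positions are stored alongside.
#'
#' @param tracks A `trajectory_set`; all positions must lie in the field of
#'   view.
#' @param psf_sigma PSF s.d. in um.
#' @param snr Peak signal-to-noise ratio (> 0).
#' @param config A [sim_config()].
#' @param background Mean background level, photons/pixel.
#' @return An `image_stack`: 3D array (rows, cols, frames) with attributes
#'   `pixel_size`, `frame_interval`, `ground_truth` (the input tracks).
#' @export
render_movie <- function(tracks, psf_sigma = 0.15, snr = 10,
                         config = sim_config(), background = 100) {
  if (snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  shape <- config$image_shape; px <- config$pixel_size
  fov <- shape * px
  if (nrow(tracks) &&
      (min(tracks$x_um) < 0 || max(tracks$x_um) > fov[2] ||
       min(tracks$y_um) < 0 || max(tracks$y_um) > fov[1]))
    stop("track positions fall outside the field of view", call. = FALSE)
  frames <- if (nrow(tracks)) 0:max(tracks$frame) else 0L
  amp <- snr * sqrt(background)
  s_px <- psf_sigma / px
  with_stream(child_seed(config$seed, "movie"), {
    stack <- array(0, c(shape[1], shape[2], length(frames)))
    for (f in seq_along(frames)) {
      lambda <- matrix(background, shape[1], shape[2])
      sub <- tracks[tracks$frame == frames[f], , drop = FALSE]
      for (q in seq_len(nrow(sub))) {
        ci <- um_to_px(sub$y_um[q], px); cj <- um_to_px(sub$x_um[q], px)
        ii <- max(1, floor(ci - 5 * s_px)):min(shape[1], ceiling(ci + 5 * s_px))
        jj <- max(1, floor(cj - 5 * s_px)):min(shape[2], ceiling(cj + 5 * s_px))
        if (!length(ii) || !length(jj)) next
        g <- amp * exp(-(outer((ii - ci)^2, (jj - cj)^2, `+`)) /
                         (2 * s_px^2))
        lambda[ii, jj] <- lambda[ii, jj] + g
      }
      stack[, , f] <- matrix(rpois(length(lambda), lambda), shape[1])
    }
    structure(stack, pixel_size = px,
              frame_interval = config$frame_interval,
              ground_truth = tracks, class = "image_stack")
  })
}

#' Write an image stack as a multi-page TIFF
#'
#' Frames (XYT) or slices (XYZ) are written as 32-bit float pages; the
#' calibration travels in a JSON sidecar.
#'
#' @param stack An `image_stack` (3D array) or list of matrices.
#' @param path Output TIFF path.
#' @param sidecar Write `<path>.json` with pixel size and frame interval.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  pages <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  mx <- max(1, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                  bits.per.sample = 32L)
  if (sidecar)
    jsonlite::write_json(list(pixel_size = attr(stack, "pixel_size"),
                              frame_interval = attr(stack, "frame_interval"),
                              intensity_scale = mx),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- paste0(path, ".json")
  meta <- if (file.exists(sc)) jsonlite::read_json(sc) else list()
  scale <- meta$intensity_scale %||% 1
  stack <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]] * scale
  structure(stack, pixel_size = meta$pixel_size,
            frame_interval = meta$frame_interval, class = "image_stack")
}
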