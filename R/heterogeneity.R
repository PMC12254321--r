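#' Segment nuclei in a fluorescence image
#'
#' Gaussian-blurs the image (1 px kernel by default), thresholds it with the
#' 256-level Otsu rule, labels connected components, and discards components
#' below a minimum physical area. One mask is returned per surviving nucleus.
#' Blur is used for mask generation only; downstream intensity statistics
#' (e.g. [compute_cov()]) are taken on the raw image.
#'
#' @param image Numeric matrix (single channel, 2D frame or z-slice).
#' @param blur_sigma_px Blur s.d. in pixels.
#' @param min_size_um2 Minimum nucleus area in um^2.
#' @param pixel_size Pixel size, um/px.
#' @return List of `nucleus_mask` objects: logical matrices with attributes
#'   `area_um2` and `label`. A constant image yields an empty list with a
#'   warning.
#' @export
segment_nucleus <- function(image, blur_sigma_px = 1, min_size_um2 = 10,
                            pixel_size = 0.133) {
  if (max(image) == min(image)) {
    warning("constant image: no threshold exists, returning no masks")
    return(list())
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = blur_sigma_px))
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- as.matrix(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * pixel_size^2 >= min_size_um2)
  lapply(seq_along(keep), function(q) {
    m <- lab == keep[q]
    structure(m, area_um2 = sizes[keep[q]] * pixel_size^2, label = q,
              class = c("nucleus_mask", class(m)))
  })
}

#' Background intensity from a cell-free region
#'
#' The background level is the median intensity over a region containing no
#' cells; the region must not overlap any nucleus mask.
#'
#' @param image Numeric matrix.
#' @param cellfree_region Logical matrix marking cell-free pixels.
#' @param masks Optional list of nucleus masks checked for overlap.
#' @return Median background intensity (scalar).
#' @export
estimate_background <- function(image, cellfree_region, masks = list()) {
  if (!any(cellfree_region))
    stop("cell-free region is empty", call. = FALSE)
  for (m in masks)
    if (any(cellfree_region & m))
      stop("cell-free region overlaps a nucleus mask", call. = FALSE)
  median(image[cellfree_region])
}

#' Chromatin heterogeneity: intensity coefficient of variation
#'
#' The heterogeneity statistic is the standard deviation of the (raw,
#' unblurred) fluorescence intensity within the nucleus mask divided by its
#' background-subtracted mean:
#' `COV = sd(I) / (mean(I) - background)`.
#' It is invariant under a multiplicative gain applied to both intensities
#' and background, but not under additive offsets unless the background is
#' shifted along.
#'
#' @param image Numeric matrix (2D mid-plane) or 3D array (z-stack) of raw
#'   intensities.
#' @param mask Logical matrix/array of matching dimensionality.
#' @param background Background intensity (see [estimate_background()]).
#' @param dimensionality `"2d"` (mid-plane) or `"3d"` (all voxels).
#' @return A `heterogeneity_result`: list with `cov`, `mean_intensity`,
#'   `std_intensity`, `background`, `n_pixels`, `dimensionality`.
#' @examples
#' img <- matrix(10, 20, 20); img[1:10, ] <- 30
#' m <- matrix(TRUE, 20, 20)
#' compute_cov(img, m, background = 0)$cov  # two-level field: COV = 0.5
#' @export
compute_cov <- function(image, mask, background = 0,
                        dimensionality = c("2d", "3d")) {
  dimensionality <- match.arg(dimensionality)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- image[mask]
  mu <- mean(v)
  if (mu <= background)
    stop("mean intensity <= background: check the background region",
         call. = FALSE)
  # population s.d.: COV of a deterministic two-level field is exact
  s <- sqrt(mean((v - mu)^2))
  structure(list(cov = s / (mu - background), mean_intensity = mu,
                 std_intensity = s, background = background,
                 n_pixels = length(v), dimensionality = dimensionality),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Chromatin heterogeneity (%s): COV = %.4f (mean %.4g, sd %.4g, background %.4g, %d px)\n",
              x$dimensionality, x$cov, x$mean_intensity, x$std_intensity,
              x$background, x$n_pixels))
  invisible(x)
}

#' Interior and periphery masks of a nucleus
#'
#' The interior mask is the binary erosion of the nucleus mask with a disc
#' of the given radius (3 px, ~0.4 um at 0.133 um/px, by default); the
#' periphery is the set difference. The two masks partition the nucleus
#' exactly.
#'
#' @param mask Logical nucleus mask.
#' @param erosion_radius_px Erosion radius in pixels.
#' @return List `interior`, `periphery` of logical matrices.
#' @export
interior_periphery <- function(mask, erosion_radius_px = 3L) {
  r <- as.integer(erosion_radius_px)
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  interior <- as.matrix(EBImage::erode(EBImage::Image(mask * 1), kern)) > 0.5
  if (!any(interior))
    stop("erosion annihilates the mask: nucleus smaller than the kernel",
         call. = FALSE)
  list(interior = interior, periphery = mask & !interior)
}

#' Nuclear volume from a segmented z-stack
#'
#' Volume is the per-slice mask area summed over slices times the z-step:
#' `V = sum(area_i) * z_step = voxel_count * pixel_size^2 * z_step`.
#'
#' @param slice_masks List of logical matrices, one per z-slice (e.g. from
#'   [segment_nucleus()] applied per slice), or a 3D logical array.
#' @param pixel_size Pixel size, um/px.
#' @param z_step Axial slice spacing, um.
#' @return A `volume_result`: list with `volume_um3`, `n_slices`, `z_step`.
#' @export
nuclear_volume <- function(slice_masks, pixel_size, z_step = 0.3) {
  if (is.array(slice_masks) && length(dim(slice_masks)) == 3)
    slice_masks <- lapply(seq_len(dim(slice_masks)[3]),
                          function(k) slice_masks[, , k])
  if (length(slice_masks) < 2L)
    stop("volume needs at least two z-slices", call. = FALSE)
  voxels <- sum(vapply(slice_masks, function(m) sum(m != 0), numeric(1)))
  structure(list(volume_um3 = voxels * pixel_size^2 * z_step,
                 n_slices = length(slice_masks), z_step = z_step),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("Nuclear volume: %.4g um^3 (%d slices at %.3g um)\n",
              x$volume_um3, x$n_slices, x$z_step))
  invisible(x)
}

#' Correlation of condensate size with prior chromatin density
#'
#' For each droplet, local chromatin density is the mean pre-activation
#' intensity within a disc centred on the droplet centroid (radius = twice
#' the droplet radius by default); the result is the Pearson correlation of
#' (size, density) pairs with its two-sided p-value. Condensates growing
#' preferentially in sparse chromatin give a negative correlation.
#'
#' @param droplets A droplet table (see [segment_droplets()]) restricted to
#'   one frame, with columns `x_um`, `y_um`, `diameter_um`.
#' @param pre_activation_chromatin Numeric matrix: chromatin channel before
#'   activation.
#' @param mask Logical nucleus mask; droplet centroids must fall inside.
#' @param pixel_size Pixel size, um/px.
#' @param density_radius_factor Disc radius as a multiple of droplet radius.
#' @return List `r`, `p_value`, `n`, `degenerate` (TRUE when sizes or
#'   densities are constant so r is undefined).
#' @export
size_density_correlation <- function(droplets, pre_activation_chromatin, mask,
                                     pixel_size = 0.133,
                                     density_radius_factor = 2) {
  if (nrow(droplets) < 5L)
    stop("need at least 5 droplets", call. = FALSE)
  nr <- nrow(pre_activation_chromatin); nc <- ncol(pre_activation_chromatin)
  dens <- vapply(seq_len(nrow(droplets)), function(q) {
    ci <- um_to_px(droplets$y_um[q], pixel_size)
    cj <- um_to_px(droplets$x_um[q], pixel_size)
    if (!mask[pmin(pmax(round(ci), 1), nr), pmin(pmax(round(cj), 1), nc)])
      stop("droplet centroid outside the nucleus mask", call. = FALSE)
    rad <- density_radius_factor * droplets$diameter_um[q] / 2 / pixel_size
    ii <- max(1, floor(ci - rad)):min(nr, ceiling(ci + rad))
    jj <- max(1, floor(cj - rad)):min(nc, ceiling(cj + rad))
    sub <- expand.grid(i = ii, j = jj)
    sub <- sub[(sub$i - ci)^2 + (sub$j - cj)^2 <= rad^2, ]
    mean(pre_activation_chromatin[cbind(sub$i, sub$j)])
  }, numeric(1))
  sizes <- droplets$diameter_um
  if (sd(sizes) == 0 || sd(dens) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(dens),
                degenerate = TRUE))
  ct <- stats::cor.test(sizes, dens)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(dens),
       degenerate = FALSE)
}
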