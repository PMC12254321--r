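#' Synthetic cell ensemble in the (Core concentration, Core-to-IDR) plane
#'
#' Samples cells log-uniformly over the concentration and ratio ranges and
#' labels each phase-separated (PS) when its Core concentration exceeds the
#' ground-truth saturation boundary `c_sat(ratio)`, flipping labels with a
#' small probability to emulate classification noise. The default boundary
#' is a power law through `c_sat = 0.10 uM` at ratio 1/16.
#'
#' @param n_cells Number of cells (ensembles of ~800 cells per condition
#'   match typical high-throughput phase-mapping scales).
#' @param conc_range Core concentration sampling bounds, uM (log-uniform).
#' @param ratio_range Core-to-IDR ratio bounds (log-uniform).
#' @param boundary_params List `c_sat_ref` (uM), `ratio_ref`, `gamma`:
#'   `c_sat(r) = c_sat_ref * (r / ratio_ref)^gamma`.
#' @param label_flip_prob Probability of flipping a label (in [0, 0.5)).
#' @param config A [sim_config()].
#' @return A `cell_ensemble` data frame: `cell_id`, `core_conc_uM`,
#'   `core_to_idr_ratio`, `ps_label` (factor PS/nonPS), `true_label`;
#'   attributes `boundary_params` and `c_sat_fun`.
#' @export
gen_phase_ensemble <- function(n_cells = 800,
                               conc_range = c(0.01, 10),
                               ratio_range = c(1 / 128, 1),
                               boundary_params = list(c_sat_ref = 0.10,
                                                      ratio_ref = 1 / 16,
                                                      gamma = 0.5),
                               label_flip_prob = 0.05,
                               config = sim_config()) {
  if (label_flip_prob < 0 || label_flip_prob >= 0.5)
    stop("`label_flip_prob` must lie in [0, 0.5)", call. = FALSE)
  if (any(conc_range <= 0) || any(ratio_range <= 0) ||
      diff(conc_range) <= 0 || diff(ratio_range) <= 0)
    stop("ranges must be positive and increasing", call. = FALSE)
  bp <- boundary_params
  c_sat <- function(r) bp$c_sat_ref * (r / bp$ratio_ref)^bp$gamma
  if (any(!is.finite(c_sat(ratio_range))) || any(c_sat(ratio_range) <= 0))
    stop("boundary must be positive over the ratio range", call. = FALSE)
  with_stream(child_seed(config$seed, "phase"), {
    conc <- exp(runif(n_cells, log(conc_range[1]), log(conc_range[2])))
    ratio <- exp(runif(n_cells, log(ratio_range[1]), log(ratio_range[2])))
    truth <- conc > c_sat(ratio)
    flip <- runif(n_cells) < label_flip_prob
    lab <- xor(truth, flip)
    out <- data.frame(cell_id = seq_len(n_cells), core_conc_uM = conc,
                      core_to_idr_ratio = ratio,
                      ps_label = factor(ifelse(lab, "PS", "nonPS"),
                                        levels = c("nonPS", "PS")),
                      true_label = factor(ifelse(truth, "PS", "nonPS"),
                                          levels = c("nonPS", "PS")))
    structure(out, boundary_params = bp, c_sat_fun = c_sat,
              class = c("cell_ensemble", "data.frame"))
  })
}

#' Intensity-to-concentration calibration
#'
#' Least-squares line mapping fluorescence intensity (a.u.) to protein
#' concentration (uM), as used to transfer an FCS-calibrated concentration
#' scale onto a second microscope. For the equimolar-tag construct, a second
#' channel's concentration equals the first times the measured intensity
#' ratio.
#'
#' @param intensity Fluorescence intensities, a.u.
#' @param conc_uM Matched concentrations, uM.
#' @return A `calibration_model`: list with `slope` (uM per a.u.),
#'   `intercept` (uM), `r_squared`, `residuals`.
#' @export
fit_calibration <- function(intensity, conc_uM) {
  if (length(intensity) < 3L)
    stop("need at least 3 calibration pairs", call. = FALSE)
  if (max(intensity) < 2 * min(intensity[intensity > 0]) ||
      sd(intensity) == 0)
    stop("calibration intensities must span more than a 2-fold range",
         call. = FALSE)
  fit <- stats::lm(conc_uM ~ intensity)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((conc_uM - mean(conc_uM))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1,
                 residuals = res),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: conc = %.4g + %.4g * intensity (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
predict.calibration_model <- function(object, intensity, ...) {
  object$intercept + object$slope * intensity
}

#' Classify a cell as phase-separated from its post-activation image
#'
#' A cell is PS when at least `min_droplets` condensates are detected in the
#' post-activation frame with a per-cell Renyi threshold; components must
#' additionally stand out from the nucleoplasmic signal by `min_contrast`
#' robust standard deviations, so a flat noisy nucleus is nonPS rather than
#' segmentation noise. Unsegmentable input (constant image) yields label
#' `"undetermined"`.
#'
#' @param post_activation_image Numeric matrix, one cell.
#' @param min_droplets Minimum droplet count for a PS call.
#' @param min_px Minimum droplet size, pixels.
#' @param min_contrast Required component contrast over the image median, in
#'   units of the median absolute deviation.
#' @param blur_sigma_px Blur before thresholding.
#' @return List `ps_label` (`"PS"`, `"nonPS"` or `"undetermined"`),
#'   `droplet_count`.
#' @export
classify_ps <- function(post_activation_image, min_droplets = 1L,
                        min_px = 4L, min_contrast = 5, blur_sigma_px = 1) {
  img <- post_activation_image
  if (max(img) == min(img))
    return(list(ps_label = "undetermined", droplet_count = NA_integer_))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma_px))
  thr <- tryCatch(as.numeric(renyi_threshold(sm)), error = function(e) NA)
  if (!is.finite(thr))
    return(list(ps_label = "undetermined", droplet_count = NA_integer_))
  fg <- sm > thr
  cnt <- 0L
  if (any(fg)) {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(fg * 1)))
    med <- median(sm); s <- mad(sm)
    if (s == 0) s <- sd(sm)
    for (q in seq_len(max(lab))) {
      idx <- lab == q
      if (sum(idx) >= min_px && mean(sm[idx]) > med + min_contrast * s)
        cnt <- cnt + 1L
    }
  }
  list(ps_label = if (cnt >= min_droplets) "PS" else "nonPS",
       droplet_count = cnt)
}

#' Fit the binodal phase boundary with an SVM
#'
#' Soft-margin support vector machine on the standardized log10 axes
#' (radial-basis kernel, cost 1, inverse-frequency class weights; a linear
#' kernel is available by flag). The boundary polyline is the zero level set
#' of the decision function on a `grid_n` x `grid_n` grid spanning the data:
#' for each ratio grid line, the crossing concentration is found by sign
#' change and linear interpolation, scanning upward from low concentration.
#'
#' @param cells Data frame with `core_conc_uM`, `core_to_idr_ratio` and
#'   `ps_label` (both classes with >= 20 cells).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost Soft-margin cost C.
#' @param grid_n Grid resolution per axis.
#' @return A `phase_boundary`: list with `model` (the svm fit), `boundary`
#'   (data frame `ratio`, `conc_uM` of the zero level set), `decision_fun`
#'   (vectorized function of (conc, ratio) returning the signed decision
#'   value, positive on the PS side), `training_summary`, `kernel`.
#' @export
fit_boundary <- function(cells, kernel = c("radial", "linear"), cost = 1,
                         grid_n = 200L) {
  kernel <- match.arg(kernel)
  lab <- factor(cells$ps_label, levels = c("nonPS", "PS"))
  if (any(table(lab) < 20L))
    stop("both classes need at least 20 cells", call. = FALSE)
  dat <- data.frame(lc = log10(cells$core_conc_uM),
                    lr = log10(cells$core_to_idr_ratio),
                    y = lab)
  wts <- rev(as.numeric(table(lab)))
  wts <- setNames(wts / sum(wts) * 2, levels(lab))
  model <- e1071::svm(y ~ lc + lr, data = dat, kernel = kernel, cost = cost,
                      scale = TRUE, class.weights = wts)
  decision_raw <- function(lc, lr) {
    dv <- attr(predict(model, data.frame(lc = lc, lr = lr),
                       decision.values = TRUE), "decision.values")
    as.numeric(dv)
  }
  # orient the decision values so positive = PS side (compare the mean
  # decision value over each training class; a probe far outside the data
  # would be meaningless under the radial kernel)
  dv_train <- decision_raw(dat$lc, dat$lr)
  sgn <- if (mean(dv_train[dat$y == "PS"]) >=
               mean(dv_train[dat$y == "nonPS"])) 1 else -1
  decision_fun <- function(conc_uM, ratio)
    sgn * decision_raw(log10(conc_uM), log10(ratio))
  lr_grid <- seq(min(dat$lr), max(dat$lr), length.out = grid_n)
  lc_grid <- seq(min(dat$lc), max(dat$lc), length.out = grid_n)
  dv <- matrix(sgn * decision_raw(rep(lc_grid, times = grid_n),
                                  rep(lr_grid, each = grid_n)),
               nrow = grid_n)  # rows: conc, cols: ratio
  cross <- vapply(seq_len(grid_n), function(j) {
    col <- dv[, j]
    s <- which(col[-grid_n] < 0 & col[-1] >= 0)
    if (!length(s)) return(NA_real_)
    i <- s[1]
    frac <- -col[i] / (col[i + 1] - col[i])
    lc_grid[i] + frac * (lc_grid[i + 1] - lc_grid[i])
  }, numeric(1))
  boundary <- data.frame(ratio = 10^lr_grid, conc_uM = 10^cross)
  boundary <- boundary[is.finite(boundary$conc_uM), ]
  structure(list(model = model, boundary = boundary,
                 decision_fun = decision_fun,
                 training_summary = table(lab), kernel = kernel,
                 conc_range = range(cells$core_conc_uM),
                 ratio_range = range(cells$core_to_idr_ratio)),
            class = "phase_boundary")
}

#' @export
print.phase_boundary <- function(x, ...) {
  cat(sprintf("Phase boundary (SVM, %s kernel): %d nonPS / %d PS cells, %d boundary points over ratio %.3g-%.3g\n",
              x$kernel, x$training_summary[["nonPS"]],
              x$training_summary[["PS"]], nrow(x$boundary),
              min(x$boundary$ratio), max(x$boundary$ratio)))
  invisible(x)
}

#' @export
plot.phase_boundary <- function(x, cells = NULL, ...) {
  if (!is.null(cells))
    plot(cells$core_to_idr_ratio, cells$core_conc_uM, log = "xy",
         col = ifelse(cells$ps_label == "PS", "#1b9e77", "#7570b3"),
         pch = 16, cex = 0.4, xlab = "Core-to-IDR ratio",
         ylab = "Core concentration (uM)", ...)
  else
    plot(x$boundary$ratio, x$boundary$conc_uM, log = "xy", type = "n",
         xlab = "Core-to-IDR ratio", ylab = "Core concentration (uM)", ...)
  lines(x$boundary$ratio, x$boundary$conc_uM, lwd = 2)
  invisible(x)
}

#' Saturation concentration at a fixed Core-to-IDR ratio
#'
#' Interpolates the fitted boundary polyline (linearly in log10-log10 space)
#' at the requested ratio; no extrapolation outside the sampled ratio range.
#'
#' @param boundary A `phase_boundary`.
#' @param at_ratio Core-to-IDR ratio at which to read off the boundary
#'   (default 1/16).
#' @return A `saturation_result`: list `c_sat_uM`, `at_ratio`.
#' @export
saturation_conc <- function(boundary, at_ratio = 1 / 16) {
  b <- boundary$boundary
  if (at_ratio < min(b$ratio) || at_ratio > max(b$ratio))
    stop("`at_ratio` outside the fitted boundary's ratio range",
         call. = FALSE)
  lc <- stats::approx(log10(b$ratio), log10(b$conc_uM),
                      xout = log10(at_ratio))$y
  structure(list(c_sat_uM = 10^lc, at_ratio = at_ratio),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("Saturation concentration: %.3g uM at Core-to-IDR ratio %.4g\n",
              x$c_sat_uM, x$at_ratio))
  invisible(x)
}
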