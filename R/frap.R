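#' Synthetic FRAP recovery curve
#'
#' Generates a normalized fluorescence-recovery curve from the
#' single-exponential model `y(t) = b * (1 - exp(-k * (t - t0)))` for
#' `t >= t0` (0 before), plus i.i.d. Gaussian noise. `b` is the mobile
#' fraction: a fully chromatin-incorporated probe has `b` near 0, an
#' unbound one near 1.
#'
#' @param b Mobile fraction, in [0, 1].
#' @param k Recovery rate, 1/s (> 0).
#' @param t0 Bleach time, s (must be among `times`).
#' @param noise_sigma Gaussian noise s.d. on the normalized signal.
#' @param times Sorted sampling times, s.
#' @param config A [sim_config()] (seed source).
#' @return A `frap_curve`: data frame `t_s`, `y` with attributes
#'   `bleach_frame` (index of t0) and `ground_truth`.
#' @examples
#' g <- gen_frap(b = 0.5, k = 0.1, times = seq(0, 60, 1),
#'               config = sim_config(1))
#' head(g)
#' @export
gen_frap <- function(b, k, t0 = 0, noise_sigma = 0.02,
                     times = seq(0, 60, by = 1), config = sim_config()) {
  if (b < 0 || b > 1) stop("`b` must lie in [0, 1]", call. = FALSE)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  bf <- which(abs(times - t0) < 1e-9)
  if (!length(bf)) stop("`t0` must be one of the sampling times",
                        call. = FALSE)
  with_stream(child_seed(config$seed, "frap"), {
    y <- ifelse(times >= t0, b * (1 - exp(-k * (times - t0))), 0)
    if (noise_sigma > 0) y <- y + rnorm(length(times), 0, noise_sigma)
    structure(data.frame(t_s = times, y = y), bleach_frame = bf[1],
              ground_truth = list(b = b, k = k, t0 = t0,
                                  noise_sigma = noise_sigma),
              class = c("frap_curve", "data.frame"))
  })
}

#' Normalize a raw FRAP trace
#'
#' Background-subtracts the bleached-ROI trace, optionally corrects
#' acquisition drift by the reference ROI (dividing by the reference's
#' background-subtracted intensity relative to its pre-bleach mean), and
#' min-max normalizes so the lowest intensity maps to 0 and the highest to
#' 1.
#'
#' @param t_s Times, s.
#' @param I_roi Bleached-ROI intensities, a.u.
#' @param bleach_frame Index of the bleach frame (pre-bleach frames must
#'   exist before it).
#' @param I_bg Background intensities (scalar or per-frame), a.u.
#' @param I_ref Optional unbleached reference-ROI intensities, a.u.
#' @return A `frap_curve` data frame `t_s`, `y` with attribute
#'   `bleach_frame`.
#' @export
normalize_frap <- function(t_s, I_roi, bleach_frame, I_bg = 0, I_ref = NULL) {
  if (bleach_frame < 2 || bleach_frame > length(t_s))
    stop("`bleach_frame` must lie within the series with pre-bleach frames",
         call. = FALSE)
  v <- I_roi - I_bg
  if (!is.null(I_ref)) {
    ref <- I_ref - I_bg
    pre <- mean(ref[seq_len(bleach_frame - 1L)])
    v <- v / (ref / pre)
  }
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("flat trace: max equals min, nothing to normalize",
                     call. = FALSE)
  structure(data.frame(t_s = t_s, y = (v - lo) / (hi - lo)),
            bleach_frame = bleach_frame,
            class = c("frap_curve", "data.frame"))
}

#' Fit the single-exponential FRAP recovery model
#'
#' Nonlinear least squares of `y = b * (1 - exp(-k * (t - t0)))` on the
#' post-bleach points, with `t0` fixed at the bleach time (it is the start
#' of bleaching, not a free parameter; set `fit_t0 = TRUE` to relax this).
#' Multistart over `k` in {0.01, 0.1, 1, 10} 1/s guards against local
#' minima; the best-RSS fit is returned.
#'
#' @param curve A `frap_curve` (from [gen_frap()] or [normalize_frap()]).
#' @param t0 Bleach time, s; default taken from the curve's `bleach_frame`.
#' @param fit_t0 Also fit `t0` (flagged alternative).
#' @param k_starts Multistart grid for `k`, 1/s.
#' @return A `frap_fit`: list `b` (mobile fraction), `k` (1/s), `t0`, `rss`,
#'   `n_points`.
#' @examples
#' g <- gen_frap(b = 0.5, k = 0.1, noise_sigma = 0, config = sim_config(1))
#' coef(fit_frap(g))
#' @export
fit_frap <- function(curve, t0 = NULL, fit_t0 = FALSE,
                     k_starts = c(0.01, 0.1, 1, 10)) {
  bf <- attr(curve, "bleach_frame") %||% 1L
  if (is.null(t0)) t0 <- curve$t_s[bf]
  post <- curve[curve$t_s >= t0 - 1e-9, ]
  if (nrow(post) < 8L)
    stop("need at least 8 post-bleach points", call. = FALSE)
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch({
      if (fit_t0) {
        minpack.lm::nlsLM(y ~ b * (1 - exp(-k * pmax(t_s - tt0, 0))),
                          data = post,
                          start = list(b = max(0.1, max(post$y)),
                                       k = k0, tt0 = t0),
                          lower = c(0, 1e-8, t0 - 10),
                          upper = c(1.05, Inf, t0 + 10),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ b * (1 - exp(-k * (t_s - t0))), data = post,
                          start = list(b = max(0.1, max(post$y)), k = k0),
                          lower = c(0, 1e-8), upper = c(1.05, Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co <- coef(fit)
      best <- list(b = unname(co[["b"]]), k = unname(co[["k"]]),
                   t0 = if (fit_t0) unname(co[["tt0"]]) else t0,
                   rss = rss, n_points = nrow(post))
    }
  }
  if (is.null(best))
    stop("FRAP fit failed to converge from all starts", call. = FALSE)
  structure(best, class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: y = b (1 - exp(-k (t - t0)))\n  mobile fraction b = %.3f, k = %.4g 1/s, t0 = %.3g s (RSS %.4g over %d points)\n",
              x$b, x$k, x$t0, x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(b = object$b, k = object$k, t0 = object$t0)
}

#' @export
predict.frap_fit <- function(object, t_s, ...) {
  ifelse(t_s >= object$t0,
         object$b * (1 - exp(-object$k * (t_s - object$t0))), 0)
}
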