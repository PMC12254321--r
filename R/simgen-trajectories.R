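#' Particle population specification
#'
#' Describes one homogeneous population of simulated particles moving as
#' fractional Brownian motion with ensemble mean square displacement
#' `MSD(tau) = D * tau^alpha` (2D, in um^2), plus optional static
#' localization noise and uniform drift.
#'
#' @param n_tracks Number of tracks (>= 1).
#' @param n_steps Number of positions per track (>= 2).
#' @param D MSD amplitude in um^2/s^alpha (>= 0; 0 means stationary
#'   particles whose apparent motion is pure localization noise).
#' @param alpha Anomalous exponent, in (0, 2).
#' @param loc_noise_sigma Localization noise s.d. in um, added i.i.d. to each
#'   coordinate (static error; contributes `2 * sigma^2` per axis pair to the
#'   apparent MSD at all lags).
#' @param drift Uniform drift velocity, um/s, length-2 vector.
#' @param fraction Nominal mixing fraction (used for bookkeeping when several
#'   populations are combined; fractions must sum to 1).
#' @return A `population_spec`.
#' @export
population_spec <- function(n_tracks, n_steps, D, alpha,
                            loc_noise_sigma = 0, drift = c(0, 0),
                            fraction = 1) {
  if (alpha <= 0 || alpha >= 2)
    stop("`alpha` must lie in (0, 2)", call. = FALSE)
  if (n_tracks < 1 || n_steps < 2)
    stop("need `n_tracks` >= 1 and `n_steps` >= 2", call. = FALSE)
  if (D < 0) stop("`D` must be >= 0", call. = FALSE)
  if (loc_noise_sigma < 0) stop("`loc_noise_sigma` must be >= 0", call. = FALSE)
  if (length(drift) != 2) stop("`drift` must have length 2", call. = FALSE)
  structure(list(n_tracks = as.integer(n_tracks), n_steps = as.integer(n_steps),
                 D = D, alpha = alpha, loc_noise_sigma = loc_noise_sigma,
                 drift = as.numeric(drift), fraction = fraction),
            class = "population_spec")
}

#' Simulate anomalous-diffusion trajectories
#'
#' Generates fractional-Brownian-motion tracks for one or several particle
#' populations. Per-axis increments are exact stationary Gaussian fGn with
#' Hurst index `H = alpha / 2`, scaled so the ensemble 2D MSD is
#' `D * tau^alpha`; apparent positions add i.i.d. Gaussian localization noise
#' and any uniform drift, giving an apparent ensemble MSD of
#' `D * tau^alpha + 4 * sigma_loc^2 + |v|^2 * tau^2`.
#'
#' @param populations A `population_spec` or list of them. When several are
#'   given their `fraction` fields must sum to 1.
#' @param config A [sim_config()]; supplies the frame interval, field of view
#'   (for start positions) and the seed.
#' @return A [as_trajectory_set()] with a `population` column holding the
#'   ground-truth population index, and a `ground_truth` attribute listing
#'   the population parameters.
#' @examples
#' cfg <- sim_config(seed = 7, frame_interval = 0.1)
#' ts <- gen_trajectories(population_spec(20, 100, D = 0.1, alpha = 1), cfg)
#' print(ts)
#' @export
gen_trajectories <- function(populations, config = sim_config()) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("population fractions must sum to 1", call. = FALSE)
  dt <- config$frame_interval
  fov <- config$image_shape * config$pixel_size  # um extent (rows, cols)
  with_stream(child_seed(config$seed, "tracks"), {
    out <- vector("list", length(populations))
    id0 <- 0L
    for (p in seq_along(populations)) {
      pp <- populations[[p]]
      n <- pp$n_tracks; L <- pp$n_steps
      # per-axis increment scale: unit fGn summed over k steps has variance
      # k^alpha; scale so the per-axis MSD is (D/2) * (k*dt)^alpha
      s <- sqrt(pp$D / 2) * dt^(pp$alpha / 2)
      if (pp$D > 0) {
        dx <- s * fgn_increments(L - 1L, pp$alpha / 2, n)
        dy <- s * fgn_increments(L - 1L, pp$alpha / 2, n)
      } else {
        dx <- dy <- matrix(0, L - 1L, n)
      }
      x0 <- runif(n, 0.05 * fov[2], 0.95 * fov[2])
      y0 <- runif(n, 0.05 * fov[1], 0.95 * fov[1])
      t_s <- (0:(L - 1L)) * dt
      x <- rbind(rep(0, n), apply(dx, 2, cumsum)) +
        matrix(x0, L, n, byrow = TRUE) + pp$drift[1] * t_s
      y <- rbind(rep(0, n), apply(dy, 2, cumsum)) +
        matrix(y0, L, n, byrow = TRUE) + pp$drift[2] * t_s
      if (pp$loc_noise_sigma > 0) {
        x <- x + rnorm(length(x), 0, pp$loc_noise_sigma)
        y <- y + rnorm(length(y), 0, pp$loc_noise_sigma)
      }
      out[[p]] <- data.frame(
        track_id = rep(id0 + seq_len(n), each = L),
        frame = rep(0:(L - 1L), n),
        t_s = rep(t_s, n),
        x_um = as.vector(x), y_um = as.vector(y),
        population = p)
      id0 <- id0 + n
    }
    set <- as_trajectory_set(do.call(rbind, out), dt)
    attr(set, "ground_truth") <- lapply(populations, unclass)
    set
  })
}
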