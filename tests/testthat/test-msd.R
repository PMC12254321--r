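test_that("time-averaged MSD matches hand-enumerated pairs", {
  tr <- data.frame(frame = 0:2, x_um = c(0, 1, 2), y_um = c(0, 0, 0))
  m <- msd_single(tr, frame_interval = 1)
  expect_equal(m$msd_um2, c(1, 4))
  expect_equal(m$lag_s, c(1, 2))
  expect_equal(m$n_pairs, c(2L, 1L))
  # stationary track: identically zero
  st <- data.frame(frame = 0:9, x_um = 1.5, y_um = -2)
  expect_true(all(msd_single(st, frame_interval = 0.5)$msd_um2 == 0))
})

test_that("anomalous fit is exact on a pure power law and matches the grid oracle", {
  lags <- (1:40) / 10
  m <- msd_curve(lags, 0.2 * lags^0.75, rep(50L, 40))
  f <- fit_anomalous(m, fit_window = range(lags))
  expect_equal(f$alpha, 0.75, tolerance = 1e-12)
  expect_equal(f$D, 0.2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # 20 random noisy curves: OLS in log space equals brute-force grid search
  set.seed(77)
  for (i in 1:20) {
    a <- runif(1, 0.3, 1.5); D <- exp(runif(1, -3, 0))
    y <- D * lags^a * exp(rnorm(40, 0, 0.1))
    mc <- msd_curve(lags, y, rep(30L, 40))
    fit <- fit_anomalous(mc, fit_window = range(lags))
    orc <- oracle_powerlaw(lags, y, expo_range = c(0, 2))
    sse_fit <- sum((log(y) - log(fit$D) - fit$alpha * log(lags))^2)
    sse_orc <- sum((log(y) - log(orc["prefactor"]) -
                      orc["exponent"] * log(lags))^2)
    expect_lt(abs(sse_fit - sse_orc), 1e-6)
  }
  expect_error(fit_anomalous(msd_curve(1:3, c(1, 2, 3), rep(5L, 3)),
                             fit_window = c(1, 3)), "4")
})

test_that("pairwise MSD cancels common motion exactly", {
  # two tracks translating with the same constant velocity: separation fixed
  tt <- 0:49
  a <- data.frame(track_id = 1, frame = tt, x_um = 0.05 * tt, y_um = 0.02 * tt)
  b <- data.frame(track_id = 2, frame = tt, x_um = 3 + 0.05 * tt,
                  y_um = 1 + 0.02 * tt)
  set <- as_trajectory_set(rbind(a, b), 1)
  m <- msd_pairwise(set)
  expect_true(all(m$msd_um2 < 1e-24))
  # deterministic identity: adding uniform drift to every track leaves the
  # pairwise MSD bit-identical
  cfg <- sim_config(seed = 21, frame_interval = 0.1)
  ts <- gen_trajectories(population_spec(8, 60, D = 0.1, alpha = 1), cfg)
  drifted <- ts
  drifted$x_um <- drifted$x_um + 0.05 * drifted$t_s
  m0 <- msd_pairwise(ts)
  m1 <- msd_pairwise(drifted)
  # cancellation is analytic; only last-ulp float noise may remain
  expect_equal(m0$msd_um2, m1$msd_um2, tolerance = 1e-13)
  expect_error(msd_pairwise(ts[ts$track_id == 1, ]), "2 tracks")
})

test_that("pairwise and single-point MSD agree for independent diffusers; only pairwise shrugs off drift", {
  cfg <- sim_config(seed = 31, frame_interval = 0.1)
  ts <- gen_trajectories(population_spec(60, 80, D = 0.1, alpha = 1), cfg)
  drifted <- ts
  drifted$x_um <- drifted$x_um + 0.05 * drifted$t_s
  me <- msd_ensemble(ts, max_lag_frac = 0.25)
  mp <- msd_pairwise(drifted, max_lag_frac = 0.25)
  common <- intersect(me$lag_s, mp$lag_s)
  common <- common[common <= 0.25 * 80 * 0.1]
  # SE of the ensemble value from per-track spread
  trs <- split(as.data.frame(ts), ts$track_id)
  for (lag in common[c(1, floor(length(common) / 2), length(common))]) {
    k <- round(lag / 0.1)
    vals <- vapply(trs, function(tr) {
      n <- nrow(tr)
      dx <- tr$x_um[(k + 1):n] - tr$x_um[1:(n - k)]
      dy <- tr$y_um[(k + 1):n] - tr$y_um[1:(n - k)]
      mean(dx^2 + dy^2)
    }, numeric(1))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mp$msd_um2[mp$lag_s == lag] - me$msd_um2[me$lag_s == lag]),
              3 * se)
  }
  # the drifted single-point MSD is inflated at long lags by (v tau)^2
  med <- msd_ensemble(drifted, max_lag_frac = 0.25)
  long <- max(common)
  expect_gt(med$msd_um2[med$lag_s == long],
            me$msd_um2[me$lag_s == long])
})

test_that("amplitude distribution flags mixtures as bimodal and recovers fractions", {
  cfg <- sim_config(seed = 13, frame_interval = 0.1 / 3)
  mix <- gen_trajectories(list(
    population_spec(80, 120, D = 0.01, alpha = 0.5, fraction = 0.5),
    population_spec(80, 120, D = 0.32, alpha = 1.0, fraction = 0.5)), cfg)
  ad <- amplitude_distribution(mix, lag = 0.1)
  expect_identical(ad$modality, "bimodal")
  expect_lt(max(abs(sort(ad$mixing_fractions) - c(0.5, 0.5))), 0.1)
  uni <- gen_trajectories(population_spec(160, 120, D = 0.1, alpha = 0.75),
                          cfg)
  au <- amplitude_distribution(uni, lag = 0.1)
  expect_identical(au$modality, "unimodal")
  # identical tracks: unimodal with one component
  few <- amplitude_distribution(mix[mix$track_id %in% 1:5, ], lag = 0.1)
  expect_identical(few$modality, "undetermined")
})

test_that("region classification uses the eroded-mask partition", {
  mask <- disk_mask(64, 20)
  px <- 0.133
  # track sitting at the disk centre: interior
  centre_um <- (64 / 2) * px
  inner <- data.frame(track_id = 1, frame = 0:9,
                      x_um = centre_um + rnorm(10, 0, 0.01),
                      y_um = centre_um + rnorm(10, 0, 0.01))
  # track hugging the rim: periphery
  rim_um <- centre_um + 18.5 * px
  outer <- data.frame(track_id = 2, frame = 0:9, x_um = rim_um,
                      y_um = centre_um)
  # track outside the nucleus: dropped
  out <- data.frame(track_id = 3, frame = 0:9, x_um = 60 * px, y_um = 5 * px)
  set <- as_trajectory_set(rbind(inner, outer, out), 0.1)
  lab <- classify_region(set, mask, erosion_radius_px = 3, pixel_size = px)
  expect_identical(lab$region[lab$track_id == "1"], "interior")
  expect_identical(lab$region[lab$track_id == "2"], "periphery")
  expect_identical(attr(lab, "dropped"), 1L)
})
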