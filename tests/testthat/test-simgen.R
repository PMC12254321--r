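test_that("generators are deterministic in the seed", {
  cfg <- sim_config(seed = 42, frame_interval = 0.1)
  a <- gen_trajectories(population_spec(5, 40, D = 0.1, alpha = 0.8), cfg)
  b <- gen_trajectories(population_spec(5, 40, D = 0.1, alpha = 0.8), cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  g1 <- gen_chromatin_field(0.3, geometry = c(5, 4), config = cfg)
  g2 <- gen_chromatin_field(0.3, geometry = c(5, 4), config = cfg)
  expect_identical(g1$intensity_field, g2$intensity_field)
  s1 <- gen_coalescence(10, 0.5, 20, config = cfg)
  s2 <- gen_coalescence(10, 0.5, 20, config = cfg)
  expect_identical(s1$droplets, s2$droplets)
  e1 <- gen_phase_ensemble(50, config = cfg)
  e2 <- gen_phase_ensemble(50, config = cfg)
  expect_identical(e1$core_conc_uM, e2$core_conc_uM)
  f1 <- gen_frap(0.5, 0.1, config = cfg)
  f2 <- gen_frap(0.5, 0.1, config = cfg)
  expect_identical(f1$y, f2$y)
  # different seed, different draw
  c2 <- sim_config(seed = 43, frame_interval = 0.1)
  expect_false(identical(
    gen_trajectories(population_spec(5, 40, D = 0.1, alpha = 0.8), c2)$x_um,
    a$x_um))
})

test_that("chromatin field hits the target COV and validates input", {
  cfg <- sim_config(seed = 3)
  g0 <- gen_chromatin_field(0, geometry = c(5, 4), config = cfg)
  r0 <- compute_cov(g0$intensity_field, g0$nucleus_mask, g0$background_level)
  expect_lt(r0$cov, 0.02)  # homogeneous limit
  for (cv in c(0.05, 0.4, 1.0)) {
    g <- gen_chromatin_field(cv, geometry = c(5, 4), config = cfg)
    r <- compute_cov(g$intensity_field, g$nucleus_mask, g$background_level)
    expect_lt(abs(r$cov - cv) / cv, 0.02)
    expect_true(any(g$nucleus_mask))
  }
  expect_error(gen_chromatin_field(-0.1, config = cfg), "cov_target")
  expect_error(gen_chromatin_field(0.3, geometry = c(100, 100), config = cfg),
               "fit")
})

test_that("a decreasing cov_target series emulates progressive homogenization", {
  cfg <- sim_config(seed = 9)
  targets <- c(0.55, 0.45, 0.35, 0.25)  # drug-treatment-like decline
  measured <- vapply(targets, function(cv) {
    g <- gen_chromatin_field(cv, geometry = c(5, 4), config = cfg)
    compute_cov(g$intensity_field, g$nucleus_mask, g$background_level)$cov
  }, numeric(1))
  expect_true(all(diff(measured) < 0))
})

test_that("trajectory generator matches its analytic MSD", {
  cfg <- sim_config(seed = 5, frame_interval = 0.1)
  # zero-D population: apparent MSD is the localization-noise floor 4 sigma^2
  ts0 <- gen_trajectories(
    population_spec(300, 20, D = 0, alpha = 1, loc_noise_sigma = 0.03), cfg)
  m0 <- msd_ensemble(ts0, min_track_len = 10)
  expect_true(all(abs(m0$msd_um2 - 4 * 0.03^2) < 0.2 * 4 * 0.03^2))
  # direct averaging of >= 1e4 squared displacements at one lag, alpha = 1
  ts1 <- gen_trajectories(population_spec(100, 120, D = 0.1, alpha = 1), cfg)
  trs <- split(as.data.frame(ts1), ts1$track_id)
  d2 <- unlist(lapply(trs, function(tr) {
    dx <- diff(tr$x_um); dy <- diff(tr$y_um); dx^2 + dy^2
  }))
  expect_gt(length(d2), 1e4)
  se <- sd(d2) / sqrt(length(d2))  # displacements at lag dt are independent
  expect_lt(abs(mean(d2) - 0.1 * 0.1), 3 * se)
  expect_error(gen_trajectories(population_spec(5, 10, D = 1, alpha = 2.5),
                                cfg))
})

test_that("ensemble MSD tracks D * tau^alpha within 3 SE at every tested lag", {
  cfg <- sim_config(seed = 7, frame_interval = 0.1)
  for (a in c(0.5, 0.75, 1.0)) {
    set <- gen_trajectories(population_spec(150, 100, D = 0.1, alpha = a), cfg)
    dt <- 0.1
    trs <- split(as.data.frame(set), set$track_id)
    for (k in c(1L, 5L, 12L, 25L)) {  # lags up to 25% of track length
      vals <- vapply(trs, function(tr) {
        n <- nrow(tr)
        dx <- tr$x_um[(k + 1):n] - tr$x_um[1:(n - k)]
        dy <- tr$y_um[(k + 1):n] - tr$y_um[1:(n - k)]
        mean(dx^2 + dy^2)
      }, numeric(1))
      se <- sd(vals) / sqrt(length(vals))
      expect_lt(abs(mean(vals) - 0.1 * (k * dt)^a), 3 * se)
    }
  }
})

test_that("coalescence conserves area/volume and merges on contact", {
  cfg <- sim_config(seed = 2, frame_interval = 1)
  # two droplets placed in contact: conservation forces a sqrt(2) radius
  sim <- gen_coalescence(2, init_radius = 1, n_steps = 1,
                         config = cfg, box_size = 20, D_ref = 1e-8,
                         init_positions = cbind(c(5, 7), c(5, 5)))
  last <- sim$droplets[sim$droplets$frame == 1, ]
  expect_equal(nrow(last), 1L)
  expect_equal(last$radius_um, sqrt(2), tolerance = 1e-12)
  # volume mode merges to cube-root sum
  simv <- gen_coalescence(2, init_radius = 1, n_steps = 1,
                          config = cfg, box_size = 20, D_ref = 1e-8,
                          conserve = "volume",
                          init_positions = cbind(c(5, 7), c(5, 5)))
  lastv <- simv$droplets[simv$droplets$frame == 1, ]
  expect_equal(lastv$radius_um, 2^(1 / 3), tolerance = 1e-12)
  # counts never increase; conserved quantity constant to 1e-9 relative
  sim2 <- gen_coalescence(60, 0.5, 150, config = cfg)
  counts <- droplet_timeseries(sim2$droplets)$count
  expect_true(all(diff(counts) <= 0))
  drift <- abs(sim2$conserved_quantity - sim2$conserved_quantity[1]) /
    sim2$conserved_quantity[1]
  expect_lt(max(drift), 1e-9)
  expect_error(gen_coalescence(1, config = cfg), "two")
})

test_that("phase ensemble labels follow the ground-truth binodal", {
  cfg <- sim_config(seed = 6)
  ens <- gen_phase_ensemble(400, label_flip_prob = 0, config = cfg)
  bp <- attr(ens, "boundary_params")
  c_sat <- attr(ens, "c_sat_fun")
  # a cell at twice the boundary concentration is PS
  expect_true(all(ens$ps_label[ens$core_conc_uM >
                                 2 * c_sat(ens$core_to_idr_ratio)] == "PS"))
  expect_identical(ens$ps_label, ens$true_label)
  # PS fraction matches the analytic measure of the super-boundary region
  # (Monte-Carlo integration with independent uniform draws in log space)
  set.seed(123)
  n_mc <- 1e6
  lc <- runif(n_mc, log(0.01), log(10))
  lr <- runif(n_mc, log(1 / 128), log(1))
  p_ps <- mean(exp(lc) > c_sat(exp(lr)))
  big <- gen_phase_ensemble(5000, label_flip_prob = 0,
                            config = sim_config(seed = 8))
  frac <- mean(big$ps_label == "PS")
  expect_lt(abs(frac - p_ps), 3 * sqrt(p_ps * (1 - p_ps) / 5000))
  expect_error(gen_phase_ensemble(10, label_flip_prob = 0.7, config = cfg),
               "flip")
})

test_that("FRAP curves follow the recovery model", {
  cfg <- sim_config(seed = 4)
  g <- gen_frap(b = 0.5, k = 0.1, t0 = 0, noise_sigma = 0,
                times = seq(0, 60, 1), config = cfg)
  expect_equal(g$y[g$t_s == 10], 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(g$y[g$t_s == 10], 4), 0.3161)
  # b = 1 with very fast recovery: y ~ 1 for all t > t0
  gfast <- gen_frap(b = 1, k = 1e4, noise_sigma = 0, config = cfg)
  expect_true(all(abs(gfast$y[gfast$t_s > 0] - 1) < 1e-6))
  # near-complete chromatin incorporation: mobile fraction ~ 0.03
  gim <- gen_frap(b = 0.03, k = 0.1, noise_sigma = 0.005, config = cfg)
  expect_lt(max(gim$y), 0.1)
  expect_error(gen_frap(b = 1.2, k = 0.1, config = cfg), "b")
})

test_that("trajectory CSV round-trips through the sidecar", {
  cfg <- sim_config(seed = 11, frame_interval = 0.25)
  ts <- gen_trajectories(population_spec(3, 15, D = 0.05, alpha = 1), cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_trajectories(ts, path)
  back <- read_trajectories(path)
  expect_equal(attr(back, "frame_interval"), 0.25)
  expect_equal(back$x_um, ts$x_um, tolerance = 1e-12)
})
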