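test_that("Otsu threshold equals the exhaustive within-class-variance oracle", {
  set.seed(50)
  for (i in 1:50) {
    v <- c(rnorm(500, runif(1, 10, 40), runif(1, 1, 8)),
           rnorm(500, runif(1, 60, 120), runif(1, 2, 12)))
    thr <- otsu_threshold(v)
    expect_identical(attr(thr, "level"),
                     oracle_otsu_level(oracle_hist256(v)))
  }
})

test_that("nucleus segmentation finds bright disks and applies the size filter", {
  px <- 0.5  # um/px so a radius-8 disk is ~50 um^2
  img <- matrix(10, 80, 80)
  img[disk_mask(80, 8, centre = 30)] <- 100
  masks <- segment_nucleus(img, pixel_size = px)
  expect_length(masks, 1L)
  expect_gt(attr(masks[[1]], "area_um2"), 45)
  inside <- which(disk_mask(80, 6, centre = 30))
  expect_true(all(masks[[1]][inside]))
  # a 5 um^2 disk (radius ~2.5 px) falls below the 10 um^2 floor
  img2 <- matrix(10, 80, 80)
  img2[disk_mask(80, 2.5, centre = 40)] <- 100
  expect_length(segment_nucleus(img2, pixel_size = px), 0L)
  expect_warning(out <- segment_nucleus(matrix(7, 40, 40), pixel_size = px),
                 "constant")
  expect_length(out, 0L)
})

test_that("background estimation is the cell-free median and guards overlap", {
  img <- matrix(3, 50, 50)
  img[1:10, 1:10] <- 200
  region <- matrix(FALSE, 50, 50); region[30:45, 30:45] <- TRUE
  expect_equal(estimate_background(img, region), 3)
  set.seed(1)
  imgp <- matrix(rpois(2500, 100), 50, 50)
  expect_lt(abs(estimate_background(imgp, region) - 100), 1.5)
  mask <- matrix(FALSE, 50, 50); mask[35:40, 35:40] <- TRUE
  expect_error(estimate_background(img, region, masks = list(mask)),
               "overlap")
  expect_error(estimate_background(img, matrix(FALSE, 50, 50)), "empty")
})

test_that("COV matches the two-level closed form and its invariances", {
  # fraction f at 2a, rest at 0, zero background: COV = sqrt(f(1-f))|d|/mean
  img <- matrix(0, 40, 40)
  img[1:20, ] <- 2  # f = 0.5 at intensity 2a with a = 1
  mask <- matrix(TRUE, 40, 40)
  r <- compute_cov(img, mask, background = 0)
  expect_equal(r$cov, 1, tolerance = 1e-12)
  # brute-force pixel statistics agree with the stored fields
  v <- img[mask]
  expect_equal(r$cov, sqrt(mean((v - mean(v))^2)) / mean(v))
  # gain invariance: scaling intensities and background together
  set.seed(2)
  img2 <- matrix(rpois(1600, 50) + 20, 40, 40)
  r1 <- compute_cov(img2, mask, background = 20)
  r2 <- compute_cov(3.7 * img2, mask, background = 3.7 * 20)
  expect_equal(r1$cov, r2$cov, tolerance = 1e-12)
  # additive offsets change COV unless the background is co-shifted
  r3 <- compute_cov(img2 + 40, mask, background = 20)
  expect_false(isTRUE(all.equal(r1$cov, r3$cov)))
  r4 <- compute_cov(img2 + 40, mask, background = 60)
  expect_equal(r1$cov, r4$cov, tolerance = 1e-12)
  # uniform field: COV 0; mean below background errors
  expect_equal(compute_cov(matrix(5, 10, 10), matrix(TRUE, 10, 10), 0)$cov, 0)
  expect_error(compute_cov(matrix(5, 10, 10), matrix(TRUE, 10, 10), 9),
               "background")
})

test_that("2D mid-plane and 3D COV agree on a z-uniform nucleus", {
  set.seed(3)
  plane <- matrix(rpois(900, 80), 30, 30)
  stack <- array(rep(plane, 4), c(30, 30, 4))
  mask2 <- matrix(TRUE, 30, 30)
  mask3 <- array(TRUE, c(30, 30, 4))
  expect_equal(compute_cov(plane, mask2, 10)$cov,
               compute_cov(stack, mask3, 10, dimensionality = "3d")$cov,
               tolerance = 1e-12)
})

test_that("interior/periphery partition the nucleus exactly", {
  mask <- disk_mask(64, 20)
  ip <- interior_periphery(mask, erosion_radius_px = 3)
  expect_identical(ip$interior | ip$periphery, mask)
  expect_false(any(ip$interior & ip$periphery))
  # disk radius 20 eroded by 3: periphery area fraction ~ 1 - (17/20)^2
  frac <- sum(ip$periphery) / sum(mask)
  expect_lt(abs(frac - (1 - (17 / 20)^2)), 0.03)  # discretization tolerance
  expect_error(interior_periphery(disk_mask(16, 2), erosion_radius_px = 3),
               "annihilates")
})

test_that("nuclear volume matches the closed-form sphere and scales with z-step", {
  px <- 0.13; zs <- 0.3; R <- 5
  zvals <- seq(-R + zs / 2, R - zs / 2, by = zs)
  masks <- lapply(zvals, function(z) {
    r2 <- R^2 - z^2
    n <- 100
    ii <- matrix(seq_len(n), n, n); jj <- t(ii)
    ((ii - 50.5) * px)^2 + ((jj - 50.5) * px)^2 <= r2
  })
  v <- nuclear_volume(masks, px, zs)
  expect_lt(abs(v$volume_um3 - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3), 0.03)
  v2 <- nuclear_volume(masks, px, 2 * zs)
  expect_equal(v2$volume_um3, 2 * v$volume_um3)
  expect_error(nuclear_volume(masks[1], px, zs), "two")
})

test_that("size-density correlation recovers an anticorrelated construction", {
  set.seed(8)
  px <- 0.2
  n <- 100
  mask <- matrix(TRUE, n, n)
  # droplets on a grid; chromatin density high where droplets are small
  centres <- expand.grid(i = seq(15, 85, by = 14), j = seq(15, 85, by = 14))
  dens_true <- runif(nrow(centres), 50, 150)
  sizes <- (160 - dens_true) / 100 + rnorm(nrow(centres), 0, 0.05)
  img <- matrix(0, n, n)
  for (q in seq_len(nrow(centres))) {
    ii <- (centres$i[q] - 6):(centres$i[q] + 6)
    jj <- (centres$j[q] - 6):(centres$j[q] + 6)
    img[ii, jj] <- dens_true[q]
  }
  drops <- data.frame(x_um = (centres$j - 0.5) * px,
                      y_um = (centres$i - 0.5) * px,
                      diameter_um = sizes)
  res <- size_density_correlation(drops, img, mask, pixel_size = px)
  expect_false(res$degenerate)
  expect_lt(res$r, -0.5)
  # direct textbook Pearson on the constructed pairs
  local_dens <- vapply(seq_len(nrow(centres)), function(q)
    img[centres$i[q], centres$j[q]], numeric(1))
  r_direct <- sum((sizes - mean(sizes)) * (local_dens - mean(local_dens))) /
    sqrt(sum((sizes - mean(sizes))^2) * sum((local_dens - mean(local_dens))^2))
  expect_equal(sign(res$r), sign(r_direct))
  expect_lt(abs(res$r - r_direct), 0.15)  # disc-averaged vs point density
  # constant sizes: degenerate flag, not an error
  drops$diameter_um <- 1
  expect_true(size_density_correlation(drops, img, mask,
                                       pixel_size = px)$degenerate)
  expect_error(size_density_correlation(drops[1:3, ], img, mask), "5")
})
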