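# Common-filter covariance, LCMV weights, source projection and the
# differential band-power map.

make_epochs <- function(arr, sfreq = 400, t0 = 0) {
  meg_epochs(arr, sfreq, t0 + (seq_len(dim(arr)[3]) - 1) / sfreq)
}

test_that("covariance approaches identity for i.i.d. noise and rank 1 for a fixed pattern", {
  set.seed(1)
  n_ch <- 8
  arr_b <- array(rnorm(50 * n_ch * 1000), c(50, n_ch, 1000))
  arr_a <- array(rnorm(50 * n_ch * 1000), c(50, n_ch, 1000))
  cov <- common_covariance(make_epochs(arr_b), make_epochs(arr_a))
  expect_equal(cov$n_samples_used, 1e5)
  expect_true(all(abs(diag(cov$matrix) - 1) < 0.05))
  off <- cov$matrix[row(cov$matrix) != col(cov$matrix)]
  expect_lt(max(abs(off)), 0.05)

  a <- rnorm(n_ch)
  s <- rnorm(2000)
  arr1 <- array(0, c(2, n_ch, 1000))
  arr1[1, , ] <- a %o% s[1:1000]; arr1[2, , ] <- a %o% s[1001:2000]
  cov1 <- common_covariance(make_epochs(arr1), make_epochs(arr1))
  ev <- eigen(cov1$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1], 1e-10)
  expect_lt(abs(ev[2]) / ev[1], 1e-10)
})

test_that("pooled covariance equals the weighted combination of window covariances", {
  set.seed(2)
  arr_b <- array(rnorm(10 * 4 * 60), c(10, 4, 60))
  arr_a <- array(rnorm(10 * 4 * 60) * 2 + 1, c(10, 4, 60))
  cov <- common_covariance(make_epochs(arr_b), make_epochs(arr_a))
  # direct algebraic oracle: per-window demeaned scatter, pooled
  flat_ref <- function(arr) {
    m <- matrix(aperm(arr, c(2, 3, 1)), dim(arr)[2])
    m - rowMeans(m)
  }
  zb <- flat_ref(arr_b); za <- flat_ref(arr_a)
  n_tot <- ncol(zb) + ncol(za)
  want <- (tcrossprod(zb) + tcrossprod(za)) / (n_tot - 2)
  expect_equal(cov$matrix, want, tolerance = 1e-12)
  expect_lt(max(abs(cov$matrix - t(cov$matrix))), 1e-12)
  ev <- eigen(cov$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
})

test_that("identity covariance gives a matched filter with unit gain", {
  geom <- desk_geometry()
  nc <- nrow(geom$sensors$positions)
  cov <- structure(list(matrix = diag(nc), n_samples_used = nc,
                        window_spec = "identity"), class = "meg_covariance")
  w <- lcmv_weights(geom$leadfield, cov, lambda = 0)
  for (v in c(3, 50, 120)) {
    l <- drop(geom$leadfield$gain[, v, ] %*% w$orientation[v, ])
    expect_equal(sum(w$weights[v, ] * l), 1, tolerance = 1e-9)
    # w proportional to l under identity covariance
    expect_equal(w$weights[v, ], l / sum(l^2), tolerance = 1e-9)
  }
})

test_that("unit gain holds at every non-silent voxel and weights grow with depth", {
  geom <- desk_geometry()
  set.seed(5)
  nc <- nrow(geom$sensors$positions)
  arr <- array(rnorm(10 * nc * 200) * 1e-13, c(10, nc, 200))
  cov <- common_covariance(make_epochs(arr), make_epochs(arr))
  w <- lcmv_weights(geom$leadfield, cov)
  ok <- which(!w$silent)
  gains <- vapply(ok, function(v)
    sum(w$weights[v, ] * drop(geom$leadfield$gain[, v, ] %*% w$orientation[v, ])),
    numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-9)
  # depth bias: deeper voxels need larger weights (near-identity covariance)
  depth <- geom$head$radius - sqrt(rowSums(geom$grid$points^2))
  wn <- rowSums(w$weights^2)
  expect_gt(cor(depth[ok], wn[ok], method = "spearman"), 0)
})

single_source_epochs <- function(geom, v, ori, snr = 30, n_trials = 20,
                                 sfreq = 400, seed = 1) {
  set.seed(seed)
  n_vox <- nrow(geom$grid$points)
  arr <- array(0, c(n_trials, n_vox, 200))
  for (tr in seq_len(n_trials))
    arr[tr, v, ] <- narrowband_sig(200, sfreq) * 1e-8
  src <- as_sources(arr, sfreq)
  gscale <- max(abs(geom$leadfield$gain[, v, ]))
  project_and_add_noise(src, geom$leadfield, ori,
                        noise_sd = 1e-8 * gscale / snr, seed = seed + 1)
}

test_that("a strong single source is localized to within one grid spacing", {
  geom <- desk_geometry()
  ori <- draw_tangential_orientations(geom$grid, geom$head, seed = 8)
  errs <- vapply(1:5, function(s) {
    v <- select_scenario_voxels(geom$grid, geom$head, 1,
                                min_radius_frac = 0.4, seed = 40 + s)
    ep <- single_source_epochs(geom, v, ori, snr = 30, seed = 50 + s)
    cov <- common_covariance(ep, ep)
    w <- lcmv_weights(geom$leadfield, cov)
    pv <- rowSums((w$weights %*% cov$matrix) * w$weights)
    est <- which.max(pv)
    sqrt(sum((geom$grid$points[est, ] - geom$grid$points[v, ])^2))
  }, numeric(1))
  expect_lte(stats::median(errs), geom$grid$spacing)
})

test_that("beamformer weights are invariant to covariance scaling", {
  geom <- desk_geometry()
  set.seed(6)
  nc <- nrow(geom$sensors$positions)
  arr <- array(rnorm(10 * nc * 100) * 1e-13, c(10, nc, 100))
  ep <- make_epochs(arr)
  cov <- common_covariance(ep, ep)
  cov10 <- cov; cov10$matrix <- 10 * cov$matrix
  w1 <- lcmv_weights(geom$leadfield, cov)
  w2 <- lcmv_weights(geom$leadfield, cov10)
  s1 <- project_sources(w1, ep); s2 <- project_sources(w2, ep)
  expect_equal(s1$data, s2$data, tolerance = 1e-9)
})

test_that("source projection is linear and recovers a noiseless source", {
  geom <- desk_geometry()
  ori <- draw_tangential_orientations(geom$grid, geom$head, seed = 8)
  v <- select_scenario_voxels(geom$grid, geom$head, 1,
                              min_radius_frac = 0.5, seed = 77)
  ep <- single_source_epochs(geom, v, ori, snr = 1e4, n_trials = 10, seed = 3)
  cov <- common_covariance(ep, ep)
  w <- lcmv_weights(geom$leadfield, cov)
  src <- project_sources(w, ep)
  truth <- array(0, c(10, nrow(geom$grid$points), 200))
  set.seed(3)  # reproduce the ground-truth time courses
  for (tr in 1:10) truth[tr, v, ] <- narrowband_sig(200, 400) * 1e-8
  expect_gt(abs(cor(src$data[1, v, ], truth[1, v, ])), 0.99)

  z <- ep; z$data[] <- 0
  expect_true(all(project_sources(w, z)$data == 0))
  s2 <- ep; s2$data <- 2 * ep$data
  expect_equal(project_sources(w, s2)$data, 2 * src$data, tolerance = 1e-12)
})

test_that("the differential power map reflects the planted ERD depth", {
  geom <- desk_geometry()
  erd_vox <- select_scenario_voxels(geom$grid, geom$head, 3, seed = 12)
  sc <- meg_scenario(n_trials = 100, sfreq = 400, erd_voxels = erd_vox,
                     erd_depth = 0.5, noise_sd = 0, seed = 21)
  src <- simulate_trial_sources(sc, geom$grid)
  sb <- window_sources(src, sc$baseline_window)
  sa <- window_sources(src, sc$active_window)
  erd <- differential_band_power(sb, sa, c(13, 23))
  m <- mean(erd$rel_power_change[erd_vox])
  expect_gt(m, -0.6); expect_lt(m, -0.4)

  sc0 <- meg_scenario(n_trials = 100, sfreq = 400, erd_voxels = erd_vox,
                      erd_depth = 0, noise_sd = 0, seed = 22)
  src0 <- simulate_trial_sources(sc0, geom$grid)
  erd0 <- differential_band_power(window_sources(src0, sc0$baseline_window),
                                  window_sources(src0, sc0$active_window),
                                  c(13, 23))
  expect_lt(max(abs(erd0$rel_power_change[erd_vox])), 0.1)
})

test_that("out-of-band sources leave near-zero band power", {
  sfreq <- 400
  t <- (0:199) / sfreq
  arr <- array(0, c(5, 2, 200))
  for (tr in 1:5) arr[tr, 1, ] <- sin(2 * pi * 30 * t)   # exactly at 30 Hz
  src <- as_sources(arr, sfreq)
  pw <- trial_band_power(src, c(13, 23))
  pw_own <- trial_band_power(src, c(28, 32))
  expect_lt(mean(pw[, 1]), 1e-3 * mean(pw_own[, 1]))
})
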