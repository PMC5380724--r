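# Ground-truth generator: geometry, analytic forward model, planted source
# dynamics and the mirrored atlas.

test_that("sensor arrays sit on the shell, are deterministic, and quasi-uniform", {
  hs <- build_head_and_sensors(275, 0.09, 0.12, seed = 7)
  expect_equal(nrow(hs$sensors$positions), 275)
  r <- sqrt(rowSums(hs$sensors$positions^2))
  expect_true(all(abs(r - 0.12) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(hs$sensors$orientations^2)) - 1) < 1e-9))

  hs2 <- build_head_and_sensors(32, 0.09, 0.12, seed = 7)
  hs3 <- build_head_and_sensors(32, 0.09, 0.12, seed = 7)
  expect_identical(hs2$sensors$positions, hs3$sensors$positions)

  # min pairwise distance within 2x of a brute-force repulsion layout
  hs64 <- build_head_and_sensors(64, 0.09, 0.12, seed = 1)
  mindist <- function(p) min(dist(p))
  repulsion_layout <- function(n, R, iters = 200) {
    set.seed(42)
    p <- matrix(rnorm(n * 3), n, 3)
    p[, 3] <- abs(p[, 3])
    p <- p / sqrt(rowSums(p^2))
    for (it in seq_len(iters)) {
      f <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        d <- sweep(p, 2, p[i, ], `-`)
        dn <- sqrt(rowSums(d^2)); dn[i] <- Inf
        f[i, ] <- -colSums(d / dn^3)
      }
      p <- p + 0.002 * f
      p[, 3] <- pmax(p[, 3], 0)
      p <- p / sqrt(rowSums(p^2))
    }
    p * R
  }
  oracle <- repulsion_layout(64, 0.12)
  expect_gt(mindist(hs64$sensors$positions), mindist(oracle) / 2)

  expect_error(build_head_and_sensors(64, -0.1, 0.12), "geometry")
  expect_error(build_head_and_sensors(64, 0.12, 0.09), "geometry")
})

test_that("source grids are clipped inside the sphere and scale as a lattice", {
  head <- build_head_and_sensors(32, 0.09, 0.12)$head
  g1 <- build_source_grid(head, 0.01)
  expect_true(all(sqrt(rowSums(g1$points^2)) < 0.95 * 0.09))
  g2 <- build_source_grid(head, 0.02)
  ratio <- nrow(g1$points) / nrow(g2$points)
  expect_gt(ratio, 8 * 0.7)
  expect_lt(ratio, 8 * 1.3)
  expect_error(build_source_grid(head, 0.2), "empty grid")
})

test_that("leadfield matches an independent transcription of the conducting-sphere formula", {
  geom <- desk_geometry()
  # scalar, per-sensor reference implementation
  sarvas_ref <- function(r0, q, rs, ns) {
    a_vec <- rs - r0
    a <- sqrt(sum(a_vec^2)); r <- sqrt(sum(rs^2))
    FF <- a * (r * a + r^2 - sum(r0 * rs))
    gF <- (a^2 / r + sum(a_vec * rs) / a + 2 * a + 2 * r) * rs -
      (a + 2 * r + sum(a_vec * rs) / a) * r0
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    B <- 1e-7 / FF^2 * (FF * qxr0 - sum(qxr0 * rs) * gF)
    sum(B * ns)
  }
  v <- which.min(abs(sqrt(rowSums(geom$grid$points^2)) - 0.06))
  for (q in list(c(1, 0, 0), c(0, 1, 0), c(0.3, -0.5, 0.8))) {
    got <- drop(geom$leadfield$gain[, v, ] %*% q)
    want <- vapply(seq_len(64), function(s)
      sarvas_ref(geom$grid$points[v, ], q, geom$sensors$positions[s, ],
                 geom$sensors$orientations[s, ]), numeric(1))
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-12)
  }
})

test_that("radial dipoles are silent and the forward model is linear", {
  geom <- desk_geometry()
  gain <- geom$leadfield$gain
  n_vox <- nrow(geom$grid$points)
  tang_scale <- max(abs(gain))
  for (v in seq(1, n_vox, by = 17)) {
    rdir <- geom$grid$points[v, ] / sqrt(sum(geom$grid$points[v, ]^2))
    radial_field <- drop(gain[, v, ] %*% rdir)
    expect_lt(max(abs(radial_field)), 1e-15 * tang_scale)
  }
  # q and -q negate; superposition of moments is exact
  v <- 10
  q <- c(0.2, 0.9, -0.1)
  expect_equal(drop(gain[, v, ] %*% q), -drop(gain[, v, ] %*% (-q)))
  q2 <- c(-0.5, 0.1, 0.4)
  expect_equal(drop(gain[, v, ] %*% (q + q2)),
               drop(gain[, v, ] %*% q) + drop(gain[, v, ] %*% q2),
               tolerance = 1e-12)
  # sensors inside the sphere are rejected
  bad <- geom$sensors
  bad$positions[1, ] <- c(0, 0, 0.03)
  expect_error(compute_leadfield(geom$grid, bad, geom$head), "outside")
})

test_that("planted ERD produces the designed active/baseline band-power ratio", {
  geom <- desk_geometry()
  erd_vox <- select_scenario_voxels(geom$grid, geom$head, 3, seed = 9)
  ratio_for_depth <- function(depth) {
    sc <- meg_scenario(n_trials = 100, sfreq = 400, erd_voxels = erd_vox,
                       erd_depth = depth, noise_sd = 0, seed = 31)
    src <- simulate_trial_sources(sc, geom$grid)
    pb <- trial_band_power(window_sources(src, sc$baseline_window), c(13, 23))
    pa <- trial_band_power(window_sources(src, sc$active_window), c(13, 23))
    mean(colMeans(pa)[erd_vox] / colMeans(pb)[erd_vox])
  }
  expect_equal(ratio_for_depth(0), 1, tolerance = 0.1)
  r <- ratio_for_depth(0.5)
  expect_gt(r, 0.4); expect_lt(r, 0.6)
  expect_error(meg_scenario(sfreq = 100, erd_band = c(13, 60)), "Nyquist")
})

test_that("full coupling yields near-perfect sample PLV from the generated phases", {
  geom <- desk_geometry()
  vox <- select_scenario_voxels(geom$grid, geom$head, 2, seed = 3)
  sc <- meg_scenario(n_trials = 100, sfreq = 400,
                     coupled_pairs = cbind(vox[1], vox[2], 1),
                     noise_sd = 0, seed = 17)
  src <- simulate_trial_sources(sc, geom$grid)
  truth <- attr(src, "coupling_truth")
  i <- match(vox, truth$voxels)
  ph <- structure(list(phases = truth$phases[, i, , drop = FALSE],
                       freqs = truth$freqs), class = "meg_phases")
  plv <- plv_matrix(ph)
  expect_gte(plv[1, 2], 0.95)
})

test_that("planted couplings beat uncoupled pairs across scenario draws", {
  geom <- desk_geometry()
  hits <- 0L
  for (s in 1:20) {
    vox <- select_scenario_voxels(geom$grid, geom$head, 2, seed = 100 + s)
    sc <- meg_scenario(n_trials = 40, sfreq = 400,
                       coupled_pairs = cbind(vox[1], vox[2], 0.9),
                       noise_sd = 0, seed = 200 + s)
    src <- simulate_trial_sources(sc, geom$grid)
    ph <- trial_spectral_phases(window_sources(src, sc$active_window))
    plv <- plv_matrix(ph)
    null_vals <- plv[upper.tri(plv)]
    null_vals <- null_vals[-which(upper.tri(plv))[
      which(upper.tri(plv), arr.ind = TRUE)[, 1] == min(vox) &
        which(upper.tri(plv), arr.ind = TRUE)[, 2] == max(vox)]]
    if (plv[vox[1], vox[2]] > stats::quantile(null_vals, 0.95)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("sensor projection is linear and noise is calibrated", {
  geom <- desk_geometry()
  n_vox <- nrow(geom$grid$points)
  ori <- draw_tangential_orientations(geom$grid, geom$head, seed = 5)
  arr <- array(0, c(1, n_vox, 50))
  arr[1, 7, ] <- sin(2 * pi * 11 * (0:49) / 400)
  src <- as_sources(arr, 400)
  ep <- project_and_add_noise(src, geom$leadfield, ori, noise_sd = 0, seed = 1)
  gcol <- drop(geom$leadfield$gain[, 7, ] %*% ori[7, ])
  expect_equal(ep$data[1, , ], gcol %o% arr[1, 7, ], tolerance = 1e-12)

  src2 <- as_sources(2 * arr, 400)
  ep2 <- project_and_add_noise(src2, geom$leadfield, ori, noise_sd = 0, seed = 1)
  expect_equal(ep2$data, 2 * ep$data, tolerance = 1e-12)

  # noise-only data: per-channel SD within 5% of the target at 1e4 samples
  arr0 <- array(0, c(1, n_vox, 10000))
  epn <- project_and_add_noise(as_sources(arr0, 400), geom$leadfield, ori,
                               noise_sd = 3e-14, seed = 2)
  sds <- apply(epn$data[1, , ], 1, sd)
  expect_true(all(abs(sds - 3e-14) / 3e-14 < 0.05))

  bad_ori <- ori; bad_ori[3, ] <- c(2, 0, 0)
  expect_error(project_and_add_noise(src, geom$leadfield, bad_ori, 0, 1),
               "unit norm")
})

test_that("simulation is bitwise deterministic per seed", {
  geom <- desk_geometry()
  atlas <- build_synthetic_atlas(geom$grid, 4, seed = 5L)
  sc <- hub_network_scenario(geom$grid, geom$head, atlas, seed = 55)
  ori <- draw_tangential_orientations(geom$grid, geom$head, seed = 6)
  e1 <- project_and_add_noise(simulate_trial_sources(sc, geom$grid),
                              geom$leadfield, ori, sc$noise_sd, seed = 9)
  e2 <- project_and_add_noise(simulate_trial_sources(sc, geom$grid),
                              geom$leadfield, ori, sc$noise_sd, seed = 9)
  expect_identical(e1$data, e2$data)
})

test_that("the synthetic atlas is a mirrored partition of contiguous parcels", {
  geom <- desk_geometry()
  atlas <- build_synthetic_atlas(geom$grid, 4, seed = 3)
  expect_equal(nrow(atlas$parcels), 8)
  expect_false(anyNA(atlas$labels))            # every voxel exactly one label
  counts <- table(atlas$labels)
  expect_equal(length(counts), 8L)
  nl <- sum(atlas$labels <= 4); nr <- sum(atlas$labels > 4)
  expect_lte(abs(nl - nr), 1)

  # each parcel is one connected component under 6-neighbor adjacency
  ijk <- round(sweep(geom$grid$points, 2,
                     apply(geom$grid$points, 2, min)) / geom$grid$spacing)
  for (lab in seq_len(8)) {
    vox <- which(atlas$labels == lab)
    keys <- paste(ijk[vox, 1], ijk[vox, 2], ijk[vox, 3])
    seen <- logical(length(vox)); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (s in 1:6) {
        step <- matrix(c(1,0,0, -1,0,0, 0,1,0, 0,-1,0, 0,0,1, 0,0,-1),
                       ncol = 3, byrow = TRUE)[s, ]
        nb <- paste(ijk[vox[cur], 1] + step[1], ijk[vox[cur], 2] + step[2],
                    ijk[vox[cur], 3] + step[3])
        j <- match(nb, keys)
        if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    expect_true(all(seen), label = sprintf("parcel %d connected", lab))
  }
  expect_error(build_synthetic_atlas(geom$grid, 100), "fewer voxels")
})

test_that("atlas TSV round-trips", {
  geom <- desk_geometry()
  atlas <- build_synthetic_atlas(geom$grid, 3, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_identical(back$labels, atlas$labels)
  expect_equal(as.data.frame(back$parcels), as.data.frame(atlas$parcels))
})
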