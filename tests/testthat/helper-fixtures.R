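# Shared fixtures, built once per test run. Desk-scale geometry: 64 sensors
# on a 10 cm shell around a 7 cm conductor sphere, 2 cm grid (~160 voxels).

fixture_env <- new.env()

desk_geometry <- function() {
  if (is.null(fixture_env$geom)) {
    hs <- build_head_and_sensors(n_chan = 64, head_radius = 0.07,
                                 sensor_shell_radius = 0.1, seed = 2L)
    grid <- build_source_grid(hs$head, 0.02)
    lf <- compute_leadfield(grid, hs$sensors, hs$head)
    fixture_env$geom <- list(head = hs$head, sensors = hs$sensors,
                             grid = grid, leadfield = lf)
  }
  fixture_env$geom
}

# wrap a trials x voxels x samples array as sources
as_sources <- function(arr, sfreq, t0 = 0) {
  meg_sources(arr, sfreq, t0 + (seq_len(dim(arr)[3]) - 1) / sfreq)
}

# sources restricted to the scenario analysis windows
window_sources <- function(src, window) {
  ii <- which(src$times >= window[1] & src$times < window[2] - 1e-12)
  meg_sources(src$data[, , ii, drop = FALSE], src$sfreq, src$times[ii],
              grid = src$grid)
}

# unit-RMS band-limited (8-25 Hz) test signal
narrowband_sig <- function(n, sfreq) {
  x <- rnorm(n)
  X <- stats::fft(x)
  f <- pmin((0:(n - 1)) * sfreq / n, sfreq - (0:(n - 1)) * sfreq / n)
  X[f < 8 | f > 25] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sd(x)
}

# geometry for the end-to-end hub scenarios: denser helmet, coarser grid
# (so voxel estimates are spatially distinct at this channel count)
hub_geometry <- function() {
  if (is.null(fixture_env$hub_geom)) {
    hs <- build_head_and_sensors(n_chan = 128, head_radius = 0.07,
                                 sensor_shell_radius = 0.1, seed = 2L)
    grid <- build_source_grid(hs$head, 0.025)
    lf <- compute_leadfield(grid, hs$sensors, hs$head)
    fixture_env$hub_geom <- list(head = hs$head, sensors = hs$sensors,
                                 grid = grid, leadfield = lf)
  }
  fixture_env$hub_geom
}

run_hub_subject <- function(geom, seed, hemisphere = "any", n_trials = 71, ...) {
  atlas <- build_synthetic_atlas(geom$grid, 4, seed = 5L)
  sc <- hub_network_scenario(geom$grid, geom$head, atlas, seed = seed,
                             hemisphere = hemisphere, n_trials = n_trials)
  ori <- draw_tangential_orientations(geom$grid, geom$head,
                                      seed = derive_seed(seed, "ori"))
  src <- simulate_trial_sources(sc, geom$grid)
  ep <- project_and_add_noise(src, geom$leadfield, ori, sc$noise_sd,
                              seed = derive_seed(seed, "noise"))
  ds <- structure(list(epochs = ep, head = geom$head, sensors = geom$sensors,
                       grid = geom$grid, leadfield = geom$leadfield,
                       atlas = atlas, orientations = ori, scenario = sc),
                  class = "meg_dataset")
  cfg <- default_config(n_rand = 200L, seed = derive_seed(seed, "cfg"), ...)
  list(bundle = suppressMessages(run_subject(ds, cfg)), dataset = ds,
       scenario = sc, hub = sc$coupled_pairs[1, 1])
}
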