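# Synthetic MEG generation: spherical head, helmet sensor array, analytic
# forward model, ground-truth source dynamics (band-limited desynchrony and
# planted phase coupling) and a mirrored parcel atlas. Coordinates: x grows
# to the right, y to anterior, z to superior; SI units throughout.

MU0_OVER_4PI <- 1e-7  # T m / A

#' Build a spherical conductor head model and a helmet sensor array
#'
#' Sensors are placed quasi-uniformly on the upper hemisphere of a shell
#' surrounding the conducting sphere (a golden-angle spiral, rotated by a
#' seed-derived azimuth), with magnetometer axes pointing radially inward.
#'
#' @param n_chan number of channels (>= 16); 275 mimics a whole-head
#'   axial-gradiometer system.
#' @param head_radius conductor sphere radius in meters.
#' @param sensor_shell_radius radius of the sensor shell (m); must exceed
#'   `head_radius`.
#' @param center 3-vector, sphere center (m).
#' @param seed integer; the layout is deterministic for a fixed seed.
#' @return A list with elements `head` (class `meg_head`: `center`, `radius`)
#'   and `sensors` (class `meg_sensors`: `positions`, `orientations`).
#' @export
build_head_and_sensors <- function(n_chan = 275, head_radius = 0.09,
                                   sensor_shell_radius = 0.12,
                                   center = c(0, 0, 0), seed = 1L) {
  if (!is.numeric(head_radius) || head_radius <= 0 ||
      !is.numeric(sensor_shell_radius) || sensor_shell_radius <= head_radius)
    stop_meg("geometry error: need sensor_shell_radius > head_radius > 0")
  if (n_chan < 16L) stop_meg("need at least 16 channels")

  # golden-angle spiral on the upper hemisphere; deterministic in the seed
  i <- seq_len(n_chan)
  cos_theta <- 1 - (i - 0.5) / n_chan        # 1 (vertex) .. ~0 (rim)
  sin_theta <- sqrt(pmax(0, 1 - cos_theta^2))
  golden <- pi * (3 - sqrt(5))
  phi0 <- 2 * pi * (derive_seed(seed, "sensor-azimuth") %% 1000L) / 1000
  phi <- i * golden + phi0
  pos <- cbind(sin_theta * cos(phi), sin_theta * sin(phi), cos_theta)
  positions <- sweep(pos * sensor_shell_radius, 2, center, `+`)
  orientations <- -pos  # radially inward unit vectors

  head <- structure(list(center = as.numeric(center), radius = head_radius),
                    class = "meg_head")
  sensors <- structure(list(positions = positions, orientations = orientations),
                       class = "meg_sensors")
  list(head = head, sensors = sensors)
}

#' Build a regular dipole grid inside the head
#'
#' An axis-aligned lattice at the requested spacing, staggered by half a
#' spacing so no point lies exactly on the midline plane or at the sphere
#' center, clipped to points with `||p - center|| < 0.95 * radius`.
#'
#' @param head a `meg_head`.
#' @param spacing lattice spacing in meters (10 mm mirrors common practice).
#' @return An object of class `meg_grid`: `points` (n_vox x 3), `spacing`,
#'   `inside_mask`.
#' @export
build_source_grid <- function(head, spacing = 0.01) {
  if (spacing <= 0 || spacing >= head$radius)
    stop_meg("empty grid: spacing must lie in (0, head radius)")
  rmax <- 0.95 * head$radius
  k <- floor(rmax / spacing - 0.5)
  if (k < 0) stop_meg("empty grid: spacing too coarse for this head")
  offs <- (seq(-k - 1L, k) + 0.5) * spacing
  pts <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  dimnames(pts) <- NULL
  keep <- sqrt(rowSums(pts^2)) < rmax
  if (!any(keep)) stop_meg("empty grid: no lattice point inside the sphere")
  pts <- sweep(pts[keep, , drop = FALSE], 2, head$center, `+`)
  structure(list(points = pts, spacing = spacing,
                 inside_mask = rep(TRUE, nrow(pts))),
            class = "meg_grid")
}

# analytic field of a current dipole in a homogeneous conducting sphere,
# evaluated at all sensors for one source location and the three unit moments
sphere_dipole_gain <- function(r0, positions, orientations, center) {
  r0 <- r0 - center
  R  <- sweep(positions, 2, center)
  a_vec <- sweep(R, 2, r0)
  a  <- sqrt(rowSums(a_vec^2))
  rn <- sqrt(rowSums(R^2))
  rr0 <- drop(R %*% r0)
  ar  <- rowSums(a_vec * R)
  FF  <- a * (rn * a + rn^2 - rr0)
  c1  <- a^2 / rn + ar / a + 2 * a + 2 * rn
  c2  <- a + 2 * rn + ar / a
  gradF <- c1 * R - outer(c2, r0)
  g <- matrix(0, nrow(positions), 3L)
  for (ax in 1:3) {
    q <- c(0, 0, 0); q[ax] <- 1
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    if (all(qxr0 == 0)) next  # radial/central moment: silent by symmetry
    B <- (outer(FF, qxr0) - drop(R %*% qxr0) * gradF) * (MU0_OVER_4PI / FF^2)
    g[, ax] <- rowSums(B * orientations)
  }
  g
}

#' Compute the forward leadfield for a grid of dipoles
#'
#' Uses the closed-form magnetic field of a current dipole inside a
#' homogeneous conducting sphere. The field of a radially oriented dipole is
#' identically zero outside the conductor, the property MEG beamforming
#' relies on; the gain is linear in the dipole moment.
#'
#' @param grid a `meg_grid`; all points must lie inside the sphere.
#' @param sensors a `meg_sensors`; all positions must lie outside the sphere.
#' @param head a `meg_head`.
#' @return An object of class `meg_leadfield` with `gain`
#'   (n_chan x n_vox x 3, tesla per A*m), plus the `sensors`, `grid` and
#'   `head` used.
#' @export
compute_leadfield <- function(grid, sensors, head) {
  dp <- sqrt(rowSums(sweep(grid$points, 2, head$center)^2))
  if (any(dp >= head$radius))
    stop_meg("all grid points must lie strictly inside the conductor sphere")
  ds <- sqrt(rowSums(sweep(sensors$positions, 2, head$center)^2))
  if (any(ds <= head$radius))
    stop_meg("all sensors must lie outside the conductor sphere")
  if (!unit_rows(sensors$orientations))
    stop_meg("sensor orientations must be unit vectors")
  n_vox <- nrow(grid$points)
  gain <- array(0, c(nrow(sensors$positions), n_vox, 3L))
  for (v in seq_len(n_vox)) {
    gain[, v, ] <- sphere_dipole_gain(grid$points[v, ], sensors$positions,
                                      sensors$orientations, head$center)
  }
  structure(list(gain = gain, sensors = sensors, grid = grid, head = head),
            class = "meg_leadfield")
}

#' Describe a simulation scenario
#'
#' Encodes the ground truth of one synthetic subject: trial structure,
#' which voxels carry a band-limited power decrease (event-related
#' desynchrony, ERD) in the active window, and which voxel pairs are phase
#' coupled there. Defaults mirror a covert verb-generation recording:
#' 71 target trials at 1200 Hz, epochs of -0.9 to 1.8 s, a 13-23 Hz ERD of
#' depth 0.5 between 0.6 and 1.0 s relative to a -0.4 to 0 s baseline, and
#' broadband (3-30 Hz) coupling.
#'
#' @param n_trials number of trials.
#' @param sfreq sampling rate (Hz).
#' @param epoch_window c(t0, t1) seconds, t0 < 0 < t1.
#' @param erd_voxels integer voxel indices carrying the ERD.
#' @param erd_band c(f_lo, f_hi) Hz of the ERD oscillation.
#' @param erd_depth fractional power reduction in the active window, in
#'   `[0, 1]`; 0.5 halves band power.
#' @param coupled_pairs 3-column matrix (voxel_i, voxel_j, strength) or list
#'   of such triples; strength in `[0, 1]` maps monotonically to expected PLV.
#' @param noise_sd sensor noise SD in tesla (10 fT default).
#' @param seed integer; the whole simulation is deterministic per seed.
#' @param baseline_window,active_window analysis windows (s) the ERD contrast
#'   is defined over.
#' @param coupling_band band (Hz) over which coupled pairs share phases.
#' @param source_amp RMS dipole moment of the 1/f background sources
#'   (A*m; 10 nA*m).
#' @param erd_amp amplitude of the ERD oscillation relative to the
#'   background (task-active sources are stronger than resting background;
#'   3x default).
#' @param coupling_amp amplitude of the coupled sources relative to the
#'   background. A scalar applies to both voxels of every pair; a length-2
#'   vector gives the first-column ("hub") and second-column ("partner")
#'   voxels different amplitudes, e.g. `c(5, 2)` for a strongly active hub
#'   with moderately active partners.
#' @param split_bins when several pairs share a hub voxel, divide the
#'   retained bins round-robin between them (`TRUE`, default) so partners
#'   share no locked bins and the planted star is exact at the generator
#'   level; with `FALSE` every pair locks on the whole band and partners
#'   inherit transitive locking at the squared strength.
#' @param background_frac relative amplitude of the 1/f background added to
#'   ERD voxels.
#' @param jitter SD (s) of trial-wise latency jitter of the active-window
#'   dynamics; 0 reproduces perfectly stimulus-locked responses.
#' @return A validated list of class `meg_scenario`.
#' @export
meg_scenario <- function(n_trials = 71, sfreq = 1200,
                         epoch_window = c(-0.9, 1.8),
                         erd_voxels = integer(), erd_band = c(13, 23),
                         erd_depth = 0.5, coupled_pairs = NULL,
                         noise_sd = 1e-14, seed = 1L,
                         baseline_window = c(-0.4, 0),
                         active_window = c(0.6, 1.0),
                         coupling_band = c(3, 30),
                         source_amp = 1e-8, erd_amp = 3, coupling_amp = 3,
                         split_bins = TRUE, background_frac = 0.05,
                         jitter = 0) {
  if (!(epoch_window[1] < 0 && 0 < epoch_window[2]))
    stop_meg("epoch_window must straddle stimulus onset (t0 < 0 < t1)")
  if (erd_depth < 0 || erd_depth > 1) stop_meg("erd_depth must lie in [0, 1]")
  if (erd_band[1] <= 0 || erd_band[2] >= sfreq / 2 || diff(erd_band) <= 0)
    stop_meg("Nyquist error: erd_band must lie inside (0, sfreq/2)")
  if (is.list(coupled_pairs)) coupled_pairs <- do.call(rbind, coupled_pairs)
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- matrix(as.numeric(coupled_pairs), ncol = 3L)
    if (any(coupled_pairs[, 3] < 0 | coupled_pairs[, 3] > 1))
      stop_meg("coupling_strength must lie in [0, 1]")
    if (any(coupled_pairs[, 1] == coupled_pairs[, 2]))
      stop_meg("coupled pairs must involve two distinct voxels")
  }
  stopifnot(n_trials >= 1, noise_sd >= 0, jitter >= 0,
            length(coupling_amp) %in% 1:2, all(coupling_amp > 0))
  if (length(coupling_amp) == 1L) coupling_amp <- rep(coupling_amp, 2L)
  structure(list(n_trials = as.integer(n_trials), sfreq = sfreq,
                 epoch_window = epoch_window, erd_voxels = as.integer(erd_voxels),
                 erd_band = erd_band, erd_depth = erd_depth,
                 coupled_pairs = coupled_pairs, noise_sd = noise_sd,
                 seed = as.integer(seed), baseline_window = baseline_window,
                 active_window = active_window, coupling_band = coupling_band,
                 source_amp = source_amp, erd_amp = erd_amp,
                 coupling_amp = coupling_amp, split_bins = split_bins,
                 background_frac = background_frac, jitter = jitter),
            class = "meg_scenario")
}

# 1/f-shaped noise, one column per series, unit RMS
one_over_f_noise <- function(n, n_series, sfreq) {
  w <- matrix(rnorm(n * n_series), n, n_series)
  W <- stats::mvfft(w)
  f <- c(0, seq_len(n - 1)) * sfreq / n
  f <- pmin(f, sfreq - f)                       # two-sided frequency axis
  sc <- 1 / sqrt(pmax(f, 1))                    # 1 Hz knee, zeroed DC below
  sc[1] <- 0
  x <- Re(stats::mvfft(W * sc, inverse = TRUE)) / n
  sweep(x, 2, sqrt(colMeans(x^2)), `/`)
}

# band-limited Gaussian noise, unit RMS per column
narrowband_noise <- function(n, n_series, sfreq, band) {
  w <- matrix(rnorm(n * n_series), n, n_series)
  W <- stats::mvfft(w)
  f <- c(0, seq_len(n - 1)) * sfreq / n
  f <- pmin(f, sfreq - f)
  keep <- f >= band[1] & f <= band[2]
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  sweep(x, 2, sqrt(colMeans(x^2)), `/`)
}

# amplitude envelope realizing the ERD: level 1 outside, sqrt(1 - depth)
# across the active window, cosine ramps clear of both analysis windows
erd_envelope <- function(times, depth, active_window) {
  lo <- sqrt(1 - depth)
  ramp <- min(0.1, active_window[1] / 2)
  env <- rep(1, length(times))
  a0 <- active_window[1]; a1 <- active_window[2]
  down <- times >= a0 - ramp & times < a0
  up   <- times >= a1 & times < a1 + ramp
  env[times >= a0 & times < a1] <- lo
  env[down] <- lo + (1 - lo) * 0.5 * (1 + cos(pi * (times[down] - a0 + ramp) / ramp))
  env[up]   <- lo + (1 - lo) * 0.5 * (1 - cos(pi * (times[up] - a1) / ramp))
  env
}

#' Simulate ground-truth source time courses for one subject
#'
#' All voxels carry independent 1/f-like background activity. ERD voxels
#' additionally carry a band-limited stochastic oscillation whose envelope
#' drops so that active-window band power is `(1 - erd_depth)` times baseline
#' band power. Coupled voxel pairs share, in the active window, a common
#' per-bin spectral phase with independent trial-wise jitter scaled by
#' `(1 - coupling_strength)`, so expected phase-locking grows monotonically
#' with the planted strength.
#'
#' @param scenario a `meg_scenario`.
#' @param grid a `meg_grid`; scenario voxel indices must be valid for it.
#' @return A `meg_sources` object (trials x voxels x samples, A*m). When
#'   couplings are planted, the drawn per-trial spectral phases of the
#'   coupled voxels are attached as attribute `coupling_truth`
#'   (`voxels`, `phases` (trials x voxels x bins), `freqs`) so tests can
#'   evaluate phase locking against the generator's own ground truth.
#' @export
simulate_trial_sources <- function(scenario, grid) {
  stopifnot(inherits(scenario, "meg_scenario"), inherits(grid, "meg_grid"))
  n_vox <- nrow(grid$points)
  idx_all <- c(scenario$erd_voxels, as.integer(scenario$coupled_pairs[, 1:2]))
  if (length(idx_all) && (min(idx_all) < 1 || max(idx_all) > n_vox))
    stop_meg("scenario voxel indices out of range for this grid")

  sf <- scenario$sfreq
  times <- seq(scenario$epoch_window[1], scenario$epoch_window[2], by = 1 / sf)
  n <- length(times)
  amp <- scenario$source_amp

  env <- erd_envelope(times, scenario$erd_depth, scenario$active_window)
  ia <- window_index(times, scenario$active_window)
  ib <- window_index(times, scenario$baseline_window)[seq_along(ia)]
  n_act <- length(ia)
  # active-window DFT bins carrying the planted coupling
  f_act <- seq_len(floor(n_act / 2)) * sf / n_act
  kbin <- which(f_act >= scenario$coupling_band[1] &
                f_act <= scenario$coupling_band[2])
  f_cpl <- f_act[kbin]
  t_rel <- (seq_len(n_act) - 1) / sf

  pairs <- scenario$coupled_pairs
  set.seed(scenario$seed)
  # constant per-voxel, per-bin phase lags, fixed across trials: PLV is
  # invariant to a constant lag, but lagged waveforms are decorrelated in
  # time, which keeps the minimum-variance inversion from cancelling
  # coherent sources
  lag <- NULL
  pair_bins <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    vox_cpl <- sort(unique(as.integer(pairs[, 1:2])))
    lag <- matrix(runif(length(kbin) * length(vox_cpl), -pi, pi),
                  length(kbin), length(vox_cpl),
                  dimnames = list(NULL, vox_cpl))
    # pairs sharing a first (hub) voxel divide the retained bins between
    # them, round-robin; a lone pair keeps the whole band
    pair_bins <- vector("list", nrow(pairs))
    for (grp in split(seq_len(nrow(pairs)), pairs[, 1])) {
      k <- if (scenario$split_bins) length(grp) else 1L
      for (r in seq_along(grp))
        pair_bins[[grp[r]]] <- seq(min(r, k), length(kbin), by = k)
    }
  }
  out <- array(0, c(scenario$n_trials, n_vox, n))
  gen_phases <- if (!is.null(lag))
    array(NA_real_, c(scenario$n_trials, ncol(lag), length(kbin))) else NULL
  for (tr in seq_len(scenario$n_trials)) {
    x <- one_over_f_noise(n, n_vox, sf)               # samples x voxels
    if (length(scenario$erd_voxels)) {
      nb <- narrowband_noise(n, length(scenario$erd_voxels), sf,
                             scenario$erd_band)
      shift <- if (scenario$jitter > 0)
        round(rnorm(1, 0, scenario$jitter) * sf) else 0L
      e <- env
      if (shift != 0) {
        e <- env[pmin(pmax(seq_len(n) - shift, 1L), n)]
      }
      x[, scenario$erd_voxels] <-
        nb * e * scenario$erd_amp +
        x[, scenario$erd_voxels] * scenario$background_frac
    }
    if (!is.null(pairs) && nrow(pairs)) {
      spectra <- vector("list", n_vox)
      draw_spec <- function() list(A = sqrt(rnorm(length(kbin))^2 +
                                              rnorm(length(kbin))^2),
                                   phi = runif(length(kbin), -pi, pi))
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]; cs <- pairs[p, 3]
        if (is.null(spectra[[i]])) spectra[[i]] <- draw_spec()
        if (is.null(spectra[[j]])) spectra[[j]] <- draw_spec()
        # each pair locks on its own interleaved bin subset (pair_bins), so
        # two partners of the same hub share no locked bins: planted
        # couplings stay a star, not a clique (phase locking is transitive)
        bsel <- pair_bins[[p]]
        spectra[[j]]$A[bsel] <- spectra[[i]]$A[bsel]
        spectra[[j]]$phi[bsel] <- spectra[[i]]$phi[bsel] +
          (1 - cs) * pi * runif(length(bsel), -1, 1)
      }
      wave <- function(A, phi) {
        # sum of exact-bin cosines, normalized to unit RMS
        drop(cos(outer(t_rel, 2 * pi * f_cpl) +
                   matrix(phi, n_act, length(kbin), byrow = TRUE)) %*% A) /
          sqrt(sum(A^2) / 2)
      }
      for (v in which(!vapply(spectra, is.null, logical(1)))) {
        amp_v <- if (v %in% pairs[, 1]) scenario$coupling_amp[1]
                 else scenario$coupling_amp[2]
        phi_v <- spectra[[v]]$phi + lag[, as.character(v)]
        gen_phases[tr, match(v, as.integer(colnames(lag))), ] <- phi_v
        # coupled voxels are equally active in both windows: independent
        # phases at baseline, locked phases in the active window, so the
        # task contrast is a pure phase reorganization with no power change
        # (and window-symmetric leakage cancels in the PLV difference)
        base_spec <- draw_spec()
        x[ib, v] <- amp_v * wave(base_spec$A, base_spec$phi)
        x[ia, v] <- amp_v * wave(spectra[[v]]$A, phi_v)
      }
    }
    out[tr, , ] <- t(x) * amp
  }
  src <- meg_sources(out, sf, times, grid = grid)
  if (!is.null(gen_phases))
    attr(src, "coupling_truth") <- list(voxels = as.integer(colnames(lag)),
                                        phases = gen_phases, freqs = f_cpl)
  src
}

#' Select well-separated superficial voxels for scenario design
#'
#' Picks `n` voxels from the outer radial shell of the grid (where cortex
#' sits and where MEG sensitivity is adequate), optionally restricted to one
#' hemisphere, spread out by greedy max-min-distance selection. Deterministic
#' per seed.
#'
#' @param grid a `meg_grid`.
#' @param head a `meg_head`.
#' @param n number of voxels.
#' @param hemisphere `"any"`, `"L"` (x < 0) or `"R"` (x > 0).
#' @param min_radius_frac keep voxels with `||p - center||` at least this
#'   fraction of the head radius.
#' @param seed integer seed.
#' @return Integer vector of voxel indices.
#' @export
select_scenario_voxels <- function(grid, head, n, hemisphere = "any",
                                   min_radius_frac = 0.6, seed = 1L) {
  p <- sweep(grid$points, 2, head$center)
  r <- sqrt(rowSums(p^2)) / head$radius
  cand <- which(r >= min_radius_frac &
                  switch(hemisphere,
                         any = TRUE, L = p[, 1] < 0, R = p[, 1] > 0))
  if (length(cand) < n) stop_meg("not enough candidate voxels in that shell")
  set.seed(seed)
  sel <- cand[sample.int(length(cand), 1L)]
  while (length(sel) < n) {
    d2 <- sapply(cand, function(v)
      min(colSums((t(grid$points[sel, , drop = FALSE]) - grid$points[v, ])^2)))
    sel <- c(sel, cand[which.max(d2)])
  }
  sel
}

#' Scenario preset: a network hub with distributed partners
#'
#' Builds a `meg_scenario` in which one superficial "hub" voxel is phase
#' coupled to several distant partner voxels, at most one per atlas parcel.
#' The hub is the most parcel-interior of a spread of superficial
#' candidates, so its leakage neighborhood stays within one parcel. All
#' coupled sources are strong relative to the background: the
#' minimum-variance inversion then adaptively suppresses each source in its
#' neighbors' estimates, so the recovered graph is the planted star rather
#' than a blur of leakage halos. Full-band locking at moderate strength
#' keeps the transitive partner-partner locking (squared jitter spread)
#' below a proportional edge threshold of 0.7.
#'
#' @param grid a `meg_grid`.
#' @param head a `meg_head`.
#' @param atlas a `meg_atlas` over the grid.
#' @param seed integer seed (drives voxel selection and the simulation).
#' @param hemisphere `"any"`, `"L"` or `"R"` — where the network lives.
#' @param n_trials,sfreq trial count and sampling rate.
#' @param coupling_strength planted strength for every hub-partner pair.
#' @param max_partners cap on the number of partners.
#' @return A `meg_scenario`; the hub voxel is `coupled_pairs[1, 1]`.
#' @export
hub_network_scenario <- function(grid, head, atlas, seed = 1L,
                                 hemisphere = "any", n_trials = 71,
                                 sfreq = 400, coupling_strength = 0.5,
                                 max_partners = 8L) {
  stopifnot(inherits(atlas, "meg_atlas"))
  vox <- select_scenario_voxels(grid, head, 9, hemisphere = hemisphere,
                                min_radius_frac = 0.55, seed = seed)
  interior <- vapply(vox, function(v) {
    d <- sqrt(colSums((t(grid$points) - grid$points[v, ])^2))
    nb <- which(d > 0 & d < 1.01 * grid$spacing)
    sum(atlas$labels[nb] == atlas$labels[v])
  }, numeric(1))
  hub <- vox[which.max(interior)]
  partners <- setdiff(vox, hub)
  # at most one partner per parcel (the one farthest from the hub), so no
  # single parcel can accumulate several star leaves
  d_hub <- sqrt(colSums((t(grid$points[partners, , drop = FALSE]) -
                           grid$points[hub, ])^2))
  keep <- unlist(lapply(split(seq_along(partners), atlas$labels[partners]),
                        function(ii) ii[which.max(d_hub[ii])]))
  partners <- partners[sort(keep)]
  if (length(partners) > max_partners)
    partners <- partners[seq_len(max_partners)]
  meg_scenario(n_trials = n_trials, sfreq = sfreq,
               coupled_pairs = cbind(hub, partners, coupling_strength),
               noise_sd = 1e-14, seed = seed, coupling_amp = 5,
               split_bins = FALSE)
}

#' Draw fixed tangential source orientations
#'
#' One tangential unit vector per voxel (orthogonal to the radial direction),
#' drawn once per scenario so every source is visible to the sensors in a
#' spherical conductor.
#'
#' @param grid a `meg_grid`.
#' @param head a `meg_head`.
#' @param seed integer seed.
#' @return An n_vox x 3 matrix of unit vectors.
#' @export
draw_tangential_orientations <- function(grid, head, seed = 1L) {
  set.seed(seed)
  p <- sweep(grid$points, 2, head$center)
  r <- p / sqrt(rowSums(p^2))
  ang <- runif(nrow(p), 0, 2 * pi)
  # tangential frame per voxel via a reference axis least aligned with r
  ref <- cbind(as.numeric(abs(r[, 1]) < 0.9), 0,
               as.numeric(abs(r[, 1]) >= 0.9))
  t1 <- cbind(ref[, 2] * r[, 3] - ref[, 3] * r[, 2],
              ref[, 3] * r[, 1] - ref[, 1] * r[, 3],
              ref[, 1] * r[, 2] - ref[, 2] * r[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(r[, 2] * t1[, 3] - r[, 3] * t1[, 2],
              r[, 3] * t1[, 1] - r[, 1] * t1[, 3],
              r[, 1] * t1[, 2] - r[, 2] * t1[, 1])
  cos(ang) * t1 + sin(ang) * t2
}

#' Project source time courses to the sensors and add noise
#'
#' Sensor data are the superposition of every voxel's gain (for its fixed
#' orientation) times its time course, plus i.i.d. Gaussian sensor noise.
#'
#' @param sources a `meg_sources` from [simulate_trial_sources()].
#' @param leadfield a `meg_leadfield`.
#' @param orientations n_vox x 3 unit dipole orientations.
#' @param noise_sd sensor noise SD (tesla).
#' @param seed integer seed for the noise.
#' @return A `meg_epochs` object.
#' @export
project_and_add_noise <- function(sources, leadfield, orientations,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(sources, "meg_sources"),
            inherits(leadfield, "meg_leadfield"))
  d <- dim(sources$data)
  if (dim(leadfield$gain)[2] != d[2] || nrow(orientations) != d[2])
    stop_meg("leadfield/orientations voxel count must match the sources")
  if (!unit_rows(orientations))
    stop_meg("orientation rows must have unit norm")
  G <- leadfield$gain[, , 1] * rep(orientations[, 1], each = dim(leadfield$gain)[1]) +
       leadfield$gain[, , 2] * rep(orientations[, 2], each = dim(leadfield$gain)[1]) +
       leadfield$gain[, , 3] * rep(orientations[, 3], each = dim(leadfield$gain)[1])
  set.seed(seed)
  nchan <- nrow(G)
  out <- array(0, c(d[1], nchan, d[3]))
  for (tr in seq_len(d[1])) {
    out[tr, , ] <- G %*% matrix(sources$data[tr, , ], nrow = d[2]) +
      matrix(rnorm(nchan * d[3], 0, noise_sd), nchan, d[3])
  }
  meg_epochs(out, sources$sfreq, sources$times,
             chan_pos = leadfield$sensors$positions,
             chan_ori = leadfield$sensors$orientations)
}
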