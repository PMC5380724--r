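# LCMV beamforming: a "common filter" covariance pooled over baseline and
# active windows, scalar spatial filters with per-voxel optimal tangential
# orientation, per-trial source projection, and the differential band-power
# (ERD) map.

#' Common-filter covariance from pooled baseline and active windows
#'
#' The channel covariance of the concatenation of both analysis windows
#' across all kept trials, each window demeaned separately per channel.
#' Pooling both windows into one ("common") filter means baseline and active
#' source estimates share identical weights, so their power difference
#' reflects the sources, not filter differences.
#'
#' @param baseline_epochs,active_epochs `meg_epochs` with equal channel sets.
#' @return An object of class `meg_covariance`: `matrix` (channels x
#'   channels, tesla^2), `n_samples_used`, `window_spec`.
#' @export
common_covariance <- function(baseline_epochs, active_epochs) {
  stopifnot(inherits(baseline_epochs, "meg_epochs"),
            inherits(active_epochs, "meg_epochs"))
  if (n_chan(baseline_epochs) != n_chan(active_epochs))
    stop_meg("baseline and active windows must share the channel set")
  if (n_trials(baseline_epochs) < 2L)
    stop_meg("covariance needs at least 2 trials")
  flat <- function(e) {
    d <- dim(e$data)
    m <- matrix(aperm(e$data, c(2, 3, 1)), d[2], d[1] * d[3])
    m - rowMeans(m)
  }
  xb <- flat(baseline_epochs)
  xa <- flat(active_epochs)
  n_tot <- ncol(xb) + ncol(xa)
  C <- (tcrossprod(xb) + tcrossprod(xa)) / (n_tot - 2L)
  C <- (C + t(C)) / 2
  structure(list(matrix = C, n_samples_used = n_tot,
                 window_spec = "baseline+active (per-window demeaned)"),
            class = "meg_covariance")
}

#' LCMV beamformer weights with diagonal-loading regularization
#'
#' For each grid point the leadfield is restricted to the tangential plane
#' (the radial column is silent in a spherical conductor) and the scalar
#' orientation is the tangential direction maximizing estimated output
#' power, i.e. the eigenvector of the smallest eigenvalue of
#' `t(L) %*% solve(C_reg) %*% L`. Weights are the classical minimum-variance
#' solution `solve(C_reg, l) / (t(l) %*% solve(C_reg) %*% l)`, so the filter
#' has unit gain at its own voxel. Regularization follows the percent
#' convention: `C_reg = C + lambda * mean(diag(C)) * I` with `lambda = 0.001`
#' for 0.1%.
#'
#' @param leadfield a `meg_leadfield`.
#' @param cov a `meg_covariance`.
#' @param lambda fractional diagonal loading (0.001 = 0.1%).
#' @return An object of class `meg_beamformer`: `weights` (n_vox x channels),
#'   `orientation` (n_vox x 3 unit vectors), `regularization_lambda`,
#'   `silent` (logical; voxels with a numerically zero leadfield get
#'   all-zero weights).
#' @export
lcmv_weights <- function(leadfield, cov, lambda = 0.001) {
  stopifnot(inherits(leadfield, "meg_leadfield"),
            inherits(cov, "meg_covariance"))
  nc <- dim(leadfield$gain)[1]
  if (nrow(cov$matrix) != nc)
    stop_meg("leadfield and covariance disagree on the channel count")
  Creg <- cov$matrix + lambda * mean(diag(cov$matrix)) * diag(nc)
  Cinv <- tryCatch(chol2inv(chol(Creg)),
                   error = function(e)
                     stop_meg("regularized covariance is singular: ", conditionMessage(e)))
  n_vox <- dim(leadfield$gain)[2]
  ctr <- leadfield$head$center
  W <- matrix(0, n_vox, nc)
  ori <- matrix(0, n_vox, 3)
  silent <- logical(n_vox)
  gscale <- max(abs(leadfield$gain))
  for (v in seq_len(n_vox)) {
    L <- leadfield$gain[, v, ]
    r <- leadfield$grid$points[v, ] - ctr
    rn <- sqrt(sum(r^2))
    if (rn < .Machine$double.eps) { silent[v] <- TRUE; next }
    r <- r / rn
    ref <- if (abs(r[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    t1 <- c(ref[2] * r[3] - ref[3] * r[2],
            ref[3] * r[1] - ref[1] * r[3],
            ref[1] * r[2] - ref[2] * r[1])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(r[2] * t1[3] - r[3] * t1[2],
            r[3] * t1[1] - r[1] * t1[3],
            r[1] * t1[2] - r[2] * t1[1])
    Tb <- cbind(t1, t2)
    Lt <- L %*% Tb
    if (max(abs(Lt)) < 1e-12 * gscale) { silent[v] <- TRUE; next }
    M <- crossprod(Lt, Cinv %*% Lt)
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- eg$vectors[, 2L]                       # smallest eigenvalue
    o3 <- drop(Tb %*% u)
    # deterministic sign: first sizeable component positive
    s <- o3[which(abs(o3) > 1e-12)[1]]
    if (!is.na(s) && s < 0) o3 <- -o3
    l <- drop(L %*% o3)
    Cl <- Cinv %*% l
    W[v, ] <- Cl / drop(crossprod(l, Cl))
    ori[v, ] <- o3
  }
  structure(list(weights = W, orientation = ori,
                 regularization_lambda = lambda, silent = silent,
                 grid = leadfield$grid),
            class = "meg_beamformer")
}

#' Apply beamformer weights to sensor epochs
#'
#' `source[trial, v, t] = w_v . data[trial, , t]`; linear in the sensor data.
#' Silent voxels yield all-zero time courses.
#'
#' @param weights a `meg_beamformer`.
#' @param epochs a `meg_epochs` with a matching channel count.
#' @return A `meg_sources`.
#' @export
project_sources <- function(weights, epochs) {
  stopifnot(inherits(weights, "meg_beamformer"), inherits(epochs, "meg_epochs"))
  if (ncol(weights$weights) != n_chan(epochs))
    stop_meg("weights and epochs disagree on the channel count")
  d <- dim(epochs$data)
  out <- array(0, c(d[1], nrow(weights$weights), d[3]))
  for (tr in seq_len(d[1]))
    out[tr, , ] <- weights$weights %*% matrix(epochs$data[tr, , ], nrow = d[2])
  meg_sources(out, epochs$sfreq, epochs$times, grid = weights$grid)
}

#' Per-trial band power of source time courses
#'
#' Hann-tapered periodogram per trial and voxel, summed over the DFT bins
#' lying inside the band (inclusive edges).
#'
#' @param sources a `meg_sources`.
#' @param band c(f_lo, f_hi) Hz.
#' @return A trials x n_vox matrix of band power.
#' @export
trial_band_power <- function(sources, band) {
  d <- dim(sources$data)
  n <- d[3]
  h <- hann_window(n)
  f <- (seq_len(floor(n / 2) + 1L) - 1L) * sources$sfreq / n
  keep <- which(f >= band[1] & f <= band[2])
  if (!length(keep)) stop_meg("no DFT bin lies inside the requested band")
  u <- sum(h^2)
  pw <- matrix(0, d[1], d[2])
  for (tr in seq_len(d[1])) {
    X <- stats::mvfft(t(matrix(sources$data[tr, , ], nrow = d[2])) * h)
    pw[tr, ] <- colSums(abs(X[keep, , drop = FALSE])^2) / u
  }
  pw
}

#' Differential band-power (ERD) map
#'
#' Relative task-related power change per voxel:
#' `(P_active - P_baseline) / P_baseline`, with band power averaged over
#' trials. Voxels with zero baseline power get `NA` and are excluded from
#' downstream statistics.
#'
#' @param sources_baseline,sources_active `meg_sources` with equal trial
#'   counts and window lengths.
#' @param band analysis band (Hz); 13-23 Hz targets low-beta desynchrony.
#' @return A tibble of class `erd_map` with columns `voxel`,
#'   `pow_baseline`, `pow_active`, `rel_power_change`; per-trial power
#'   matrices are attached as attributes `power_baseline` / `power_active`
#'   for permutation inference, and `band` records the band.
#' @export
differential_band_power <- function(sources_baseline, sources_active,
                                    band = c(13, 23)) {
  db <- dim(sources_baseline$data); da <- dim(sources_active$data)
  if (db[1] != da[1]) stop_meg("trial counts must match across windows")
  if (db[3] != da[3]) stop_meg("window lengths must match across windows")
  pb <- trial_band_power(sources_baseline, band)
  pa <- trial_band_power(sources_active, band)
  mb <- colMeans(pb); ma <- colMeans(pa)
  rel <- ifelse(mb > 0, (ma - mb) / mb, NA_real_)
  out <- tibble::tibble(voxel = seq_len(db[2]),
                        pow_baseline = mb, pow_active = ma,
                        rel_power_change = rel)
  attr(out, "power_baseline") <- pb
  attr(out, "power_active") <- pa
  attr(out, "band") <- band
  class(out) <- c("erd_map", class(out))
  out
}

#' Add permutation inference to an ERD map
#'
#' Runs the sign-flip permutation test and Benjamini-Hochberg correction on
#' the per-trial power matrices carried by an [differential_band_power()]
#' result.
#'
#' @param erd an `erd_map`.
#' @param n_rand number of randomizations.
#' @param q FDR level.
#' @param seed integer seed.
#' @return The `erd_map` with columns `t_stat`, `p_value`, `significant`.
#' @export
erd_inference <- function(erd, n_rand = 5000, q = 0.05, seed = 1L) {
  stopifnot(inherits(erd, "erd_map"))
  pa <- attr(erd, "power_active"); pb <- attr(erd, "power_baseline")
  pr <- permutation_erd_test(pa, pb, n_rand = n_rand, seed = seed)
  erd$t_stat <- pr$observed_t
  erd$p_value <- pr$p_values
  erd$p_value[is.na(erd$rel_power_change)] <- NA_real_
  erd$significant <- fdr_bh(erd$p_value, q = q)
  erd
}
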