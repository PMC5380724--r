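# Voxel-pair phase-locking-value (PLV) connectivity. Per trial and voxel a
# Hann-tapered DFT yields phases at the retained bins of the broadband
# (3-30 Hz) range; PLV per pair and bin is the modulus of the trial-averaged
# unit phasor of the phase difference, the broadband summary is the
# unweighted mean over bins, and the stored adjacency is active minus
# baseline PLV.

#' Per-trial spectral phases of source time courses
#'
#' Hann-tapered DFT per trial and voxel; phases are the arguments of the
#' complex coefficients at the retained bins. Bins must carry at least
#' `min_cycles` cycles within the window (default 2: at a 400 ms window this
#' retains 5, 7.5, ..., 30 Hz and drops the unreliable 3-5 Hz edge).
#'
#' @param sources a `meg_sources`.
#' @param band c(f_lo, f_hi) Hz.
#' @param min_cycles minimum number of oscillation cycles per window for a
#'   bin to be retained.
#' @return A list of class `meg_phases`: `phases`
#'   (trials x n_vox x n_bins, radians in (-pi, pi]), `freqs` (Hz).
#' @export
trial_spectral_phases <- function(sources, band = c(3, 30), min_cycles = 2) {
  stopifnot(inherits(sources, "meg_sources"))
  d <- dim(sources$data)
  n <- d[3]
  f <- (seq_len(floor(n / 2) + 1L) - 1L) * sources$sfreq / n
  cycles <- f * n / sources$sfreq    # = bin index: cycles in the window
  keep <- which(f >= band[1] & f <= band[2] & cycles >= min_cycles)
  if (!length(keep))
    stop_meg("window too short: no retained bin in the requested band")
  h <- hann_window(n)
  ph <- array(0, c(d[1], d[2], length(keep)))
  for (tr in seq_len(d[1])) {
    X <- stats::mvfft(t(matrix(sources$data[tr, , ], nrow = d[2])) * h)
    ph[tr, , ] <- t(Arg(X[keep, , drop = FALSE]))
  }
  structure(list(phases = ph, freqs = f[keep]), class = "meg_phases")
}

#' Within-window PLV matrix
#'
#' For each pair (a, b) and retained bin,
#' `PLV = | mean over trials of exp(i (phi_a - phi_b)) |`; the returned
#' matrix is the unweighted mean over bins. PLV is 1 for a constant phase
#' lag and approaches `sqrt(pi / (4 N))` for independent phases at N trials.
#'
#' @param phases a `meg_phases` with at least 2 trials.
#' @return A symmetric n_vox x n_vox matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
plv_matrix <- function(phases) {
  stopifnot(inherits(phases, "meg_phases"))
  d <- dim(phases$phases)
  if (d[1] < 2L) stop_meg("PLV is degenerate below 2 trials")
  acc <- matrix(0, d[2], d[2])
  for (k in seq_len(d[3])) {
    Z <- exp(1i * phases$phases[, , k])
    M <- Mod(crossprod(Conj(Z), Z)) / d[1]
    acc <- acc + M
  }
  P <- acc / d[3]
  (P + t(P)) / 2
}

#' Task-related PLV adjacency (active minus baseline)
#'
#' Computes the within-window PLV matrices for both windows and returns
#' their difference, isolating task-related coupling changes.
#'
#' @param phases_active,phases_baseline `meg_phases` over the same trials,
#'   voxels and bins.
#' @return An object of class `meg_adjacency`: `values` (symmetric
#'   n_vox x n_vox, zero diagonal, entries in `[-1, 1]`), `freqs`,
#'   `plv_active`, `plv_baseline`.
#' @export
plv_adjacency <- function(phases_active, phases_baseline) {
  da <- dim(phases_active$phases); db <- dim(phases_baseline$phases)
  if (!all(da == db) ||
      length(phases_active$freqs) != length(phases_baseline$freqs))
    stop_meg("active and baseline phase tensors must match in trials, voxels and bins")
  Pa <- plv_matrix(phases_active)
  Pb <- plv_matrix(phases_baseline)
  stopifnot(all(Pa >= -1e-9 & Pa <= 1 + 1e-9),
            all(Pb >= -1e-9 & Pb <= 1 + 1e-9))
  V <- Pa - Pb
  diag(V) <- 0
  structure(list(values = V, freqs = phases_active$freqs,
                 plv_active = Pa, plv_baseline = Pb),
            class = "meg_adjacency")
}

#' @export
print.meg_adjacency <- function(x, ...) {
  cat(sprintf("<meg_adjacency> %d x %d voxels, %d bins (%.3g..%.3g Hz)\n",
              nrow(x$values), ncol(x$values), length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}
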