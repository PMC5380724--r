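# Sensor-space cleaning chain: epoching with baseline correction, DFT-bin
# line-noise attenuation, zero-phase FIR band-pass, and median-filter
# jump-artifact rejection. All analysis windows use the half-open [t0, t1)
# sample convention so paired windows of equal duration have equal counts.

#' Epoch a continuous recording and baseline-correct each trial
#'
#' Cuts epochs around each event onset (inclusive sample convention:
#' `round(diff(window) * sfreq) + 1` samples) and removes, per trial and
#' channel, the mean over the baseline window.
#'
#' @param continuous channels x samples matrix (tesla).
#' @param event_onsets event times in seconds from recording start.
#' @param sfreq sampling rate (Hz).
#' @param window epoch extent c(t0, t1) seconds relative to onset.
#' @param baseline_window window (s) whose mean is removed per trial/channel.
#' @param chan_pos,chan_ori optional channel geometry carried through.
#' @return A `meg_epochs`. Events whose epoch would exceed the recording are
#'   dropped with a warning.
#' @export
epoch_and_baseline <- function(continuous, event_onsets, sfreq,
                               window = c(-0.9, 1.8),
                               baseline_window = c(-0.9, 0),
                               chan_pos = NULL, chan_ori = NULL) {
  stopifnot(is.matrix(continuous), length(event_onsets) >= 1)
  n_samp_rec <- ncol(continuous)
  rel <- seq(round(window[1] * sfreq), round(window[2] * sfreq))
  times <- rel / sfreq
  onset_idx <- round(event_onsets * sfreq) + 1L
  ok <- onset_idx + min(rel) >= 1L & onset_idx + max(rel) <= n_samp_rec
  if (!all(ok))
    warning(sprintf("dropping %d event(s) whose epoch exceeds the recording: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  if (!any(ok)) stop_meg("no event fits inside the recording")
  onset_idx <- onset_idx[ok]
  dat <- array(0, c(length(onset_idx), nrow(continuous), length(rel)))
  for (tr in seq_along(onset_idx))
    dat[tr, , ] <- continuous[, onset_idx[tr] + rel]
  ib <- window_index(times, baseline_window)
  if (!length(ib)) stop_meg("baseline window contains no samples")
  bl <- apply(dat[, , ib, drop = FALSE], c(1, 2), mean)
  dat <- dat - array(bl, dim(dat))
  meg_epochs(dat, sfreq, times, chan_pos = chan_pos, chan_ori = chan_ori,
             events = event_onsets[ok])
}

#' Attenuate power-line noise by sharp sinusoid projection
#'
#' Per trial and channel, removes the least-squares projection of the epoch
#' onto sine/cosine pairs at each target frequency and at its two
#' neighboring DFT frequencies (spaced 1/epoch-duration apart). A pure tone
#' at a target frequency is removed exactly even when it does not fall on a
#' DFT bin, while amplitudes 2 Hz or more away are left essentially
#' untouched for epochs of a second or longer.
#'
#' @param epochs a `meg_epochs`.
#' @param freqs target frequencies (Hz), all below Nyquist.
#' @return The filtered `meg_epochs`.
#' @export
attenuate_line_noise <- function(epochs, freqs = c(60, 120, 180)) {
  stopifnot(inherits(epochs, "meg_epochs"))
  if (any(freqs >= epochs$sfreq / 2) || any(freqs <= 0))
    stop_meg("line frequencies must lie inside (0, Nyquist)")
  n <- n_samples(epochs)
  df <- epochs$sfreq / n
  tt <- seq_len(n) / epochs$sfreq
  fset <- unique(as.vector(outer(c(-df, 0, df), freqs, `+`)))
  fset <- fset[fset > 0 & fset < epochs$sfreq / 2]
  X <- do.call(cbind, lapply(fset, function(f)
    cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
  Xp <- solve(crossprod(X), t(X))
  dat <- epochs$data
  nc <- dim(dat)[2]
  for (tr in seq_len(dim(dat)[1])) {
    D <- t(matrix(dat[tr, , ], nrow = nc))        # samples x channels
    dat[tr, , ] <- t(D - X %*% (Xp %*% D))
  }
  epochs$data <- dat
  epochs
}

# zero-phase application of a symmetric odd-length FIR kernel: reflection
# padding, linear convolution, group-delay compensation
apply_fir_zerophase <- function(mat, h) {
  nh <- length(h)
  half <- (nh - 1L) %/% 2L
  n <- nrow(mat)
  np <- min(nh, n - 1L)
  pad <- rbind(mat[rev(seq_len(np) + 1L), , drop = FALSE],
               mat,
               mat[n - seq_len(np), , drop = FALSE])
  m <- nrow(pad)
  nfft <- stats::nextn(m + nh - 1L, 2)
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  Y <- stats::mvfft(rbind(pad, matrix(0, nfft - m, ncol(mat))))
  y <- Re(stats::mvfft(Y * H, inverse = TRUE)) / nfft
  y[np + half + seq_len(n), , drop = FALSE]
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR applied with reflection padding and
#' group-delay compensation; the symmetric kernel makes the response exactly
#' zero phase, which downstream phase-locking estimates rely on.
#'
#' @param epochs a `meg_epochs`.
#' @param band c(f_lo, f_hi) Hz inside (0, Nyquist).
#' @param order filter order (number of taps minus one, forced even);
#'   default `round(sfreq / 3)`.
#' @return The filtered `meg_epochs`.
#' @export
bandpass <- function(epochs, band = c(0.1, 100), order = NULL) {
  stopifnot(inherits(epochs, "meg_epochs"))
  ny <- epochs$sfreq / 2
  if (band[1] <= 0 || band[2] >= ny || band[1] >= band[2])
    stop_meg("band edges must satisfy 0 < f_lo < f_hi < Nyquist")
  ord <- order %||% round(epochs$sfreq / 3)
  ord <- max(10L, as.integer(ord) %/% 2L * 2L)
  h <- signal::fir1(ord, band / ny, type = "pass")
  dat <- epochs$data
  nc <- dim(dat)[2]
  for (tr in seq_len(dim(dat)[1]))
    dat[tr, , ] <- t(apply_fir_zerophase(t(matrix(dat[tr, , ], nrow = nc)), h))
  epochs$data <- dat
  epochs
}

#' Reject trials containing jump artifacts
#'
#' Per trial and channel the artifact score is the largest single-sample
#' step of the 9-sample running-median smooth of the signal (the median
#' filter suppresses spikes and noise but follows genuine steps, so its
#' derivative isolates jump discontinuities); a trial
#' is rejected when the robust z-score (median/MAD across trials, per
#' channel) of that score exceeds `z_threshold` on any channel. Clean data
#' are not modified, only `keep` is updated.
#'
#' @param epochs a `meg_epochs` with at least 8 trials.
#' @param z_threshold robust z cutoff; the default 20 only flags gross steps.
#' @param kernel running-median length (odd).
#' @return The `meg_epochs` with an updated `keep` mask; rejected indices are
#'   reported via a message.
#' @export
reject_jump_trials <- function(epochs, z_threshold = 20, kernel = 9L) {
  stopifnot(inherits(epochs, "meg_epochs"))
  nt <- n_trials(epochs)
  if (nt < 8L) stop_meg("jump rejection needs at least 8 trials")
  nc <- n_chan(epochs)
  score <- matrix(0, nt, nc)
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      x <- epochs$data[tr, ch, ]
      score[tr, ch] <- max(abs(diff(stats::runmed(x, kernel))))
    }
  }
  med <- apply(score, 2, stats::median)
  madv <- apply(score, 2, stats::mad)  # mad() includes the 1.4826 constant
  madv[madv == 0] <- .Machine$double.eps
  z <- sweep(sweep(score, 2, med), 2, madv, `/`)
  bad <- apply(z, 1, max) > z_threshold
  if (all(bad | !epochs$keep))
    stop_meg("all trials rejected; review z_threshold")
  if (any(bad))
    message(sprintf("rejecting %d trial(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")))
  epochs$keep <- epochs$keep & !bad
  epochs
}

#' Extract equal-length baseline and active windows
#'
#' Half-open `[t0, t1)` sample selection; only trials with `keep = TRUE` are
#' retained. The two windows must yield the same number of samples, as the
#' paired power comparison requires.
#'
#' @param epochs a `meg_epochs`.
#' @param baseline,active windows in seconds, both inside the epoch extent.
#' @return A list with `meg_epochs` elements `baseline` and `active`.
#' @export
extract_windows <- function(epochs, baseline = c(-0.4, 0),
                            active = c(0.6, 1.0)) {
  stopifnot(inherits(epochs, "meg_epochs"))
  for (w in list(baseline, active))
    if (w[1] < min(epochs$times) - 1e-12 || w[2] > max(epochs$times) + 1 / epochs$sfreq)
      stop_meg("analysis window lies outside the epoch extent")
  ib <- window_index(epochs$times, baseline)
  ia <- window_index(epochs$times, active)
  if (length(ib) != length(ia))
    stop_meg("baseline and active windows must contain equal sample counts")
  tr <- which(epochs$keep)
  mk <- function(ii) meg_epochs(epochs$data[tr, , ii, drop = FALSE],
                                epochs$sfreq, epochs$times[ii],
                                chan_pos = epochs$chan_pos,
                                chan_ori = epochs$chan_ori)
  list(baseline = mk(ib), active = mk(ia))
}
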