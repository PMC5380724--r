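#' Sensor-space MEG epochs
#'
#' Lightweight container for epoched MEG data: a `trials x channels x samples`
#' array in tesla, with channel geometry, the time axis (seconds, t = 0 at
#' stimulus onset) and a per-trial keep mask maintained by artifact rejection.
#'
#' @param data numeric array, trials x channels x samples (tesla).
#' @param sfreq sampling rate in Hz.
#' @param times numeric vector of sample times in seconds; must be uniformly
#'   spaced at `1/sfreq`.
#' @param chan_pos,chan_ori optional `n_chan x 3` matrices of sensor positions
#'   (m) and unit orientations.
#' @param events optional numeric vector of event onsets (s) in the original
#'   recording.
#' @param keep logical vector, one entry per trial; trials flagged `FALSE`
#'   are excluded from analysis windows.
#' @return An object of class `meg_epochs`.
#' @export
meg_epochs <- function(data, sfreq, times, chan_pos = NULL, chan_ori = NULL,
                       events = NULL, keep = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(times) != dim(data)[3])
    stop_meg("length(times) must equal the number of samples")
  dt <- diff(times)
  if (any(abs(dt - 1 / sfreq) > 1e-9 / sfreq) || any(dt <= 0))
    stop_meg("times must be strictly increasing and uniformly spaced at 1/sfreq")
  keep <- keep %||% rep(TRUE, dim(data)[1])
  stopifnot(length(keep) == dim(data)[1])
  structure(
    list(data = data, sfreq = sfreq, times = as.numeric(times),
         chan_pos = chan_pos, chan_ori = chan_ori, events = events,
         keep = as.logical(keep), schema_version = "1.0"),
    class = "meg_epochs")
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<meg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  time %g .. %g s; %d trials kept\n",
              min(x$times), max(x$times), sum(x$keep)))
  invisible(x)
}

n_trials  <- function(x) dim(x$data)[1]
n_chan    <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Per-trial source-space time courses
#'
#' @param data numeric array, trials x voxels x samples (nominal A*m).
#' @param sfreq sampling rate (Hz).
#' @param times time axis (s).
#' @param grid the `meg_grid` the voxels refer to, if available.
#' @return An object of class `meg_sources`.
#' @export
meg_sources <- function(data, sfreq, times, grid = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(times) == dim(data)[3])
  structure(list(data = data, sfreq = sfreq, times = as.numeric(times),
                 grid = grid),
            class = "meg_sources")
}

#' @export
print.meg_sources <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<meg_sources> %d trials x %d voxels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  invisible(x)
}
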