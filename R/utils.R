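#' @importFrom stats fft rnorm runif sd median mad runmed p.adjust t.test
#' @importFrom rlang hash .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_meg <- function(...) stop(..., call. = FALSE)

#' Derive a stage-specific seed from a master seed
#'
#' Stage seeds are derived by hashing the stage name together with the master
#' seed, so that adding or removing a stage never perturbs the random stream
#' of the other stages. The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- rlang::hash(list(as.integer(master), stage))
  # fold the first 8 hex digits of the hash into a positive 31-bit integer
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L) %% .Machine$integer.max)
}

# half-open [t0, t1) sample selection used for every analysis window
window_index <- function(times, window) {
  which(times >= window[1] & times < window[2] - 1e-12)
}

unit_rows <- function(m, tol = 1e-9) {
  all(abs(sqrt(rowSums(m^2)) - 1) <= tol)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}
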