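# Permutation inference for the ERD contrast and reusable
# Benjamini-Hochberg false-discovery-rate control.

#' Paired t statistic per voxel
#'
#' Classical paired t on the per-trial active-minus-baseline differences:
#' `t = mean(d) / (sd(d) / sqrt(n))`, one value per voxel. Zero-variance
#' differences yield `Inf` with the sign of the mean (0 for an all-zero
#' column).
#'
#' @param active_power,baseline_power trials x n_vox matrices.
#' @return Numeric vector of t statistics, length n_vox.
#' @export
paired_t <- function(active_power, baseline_power) {
  stopifnot(is.matrix(active_power), is.matrix(baseline_power),
            all(dim(active_power) == dim(baseline_power)))
  n <- nrow(active_power)
  if (n < 3L) stop_meg("paired t needs at least 3 trials")
  d <- active_power - baseline_power
  m <- colMeans(d)
  s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  zv <- s <= 0 | !is.finite(t)
  t[zv] <- sign(m[zv]) * Inf
  t[zv & m == 0] <- 0
  t
}

#' Sign-flip permutation test for the paired power contrast
#'
#' Each randomization exchanges the active/baseline assignment within a
#' random subset of trials (equivalently, flips the sign of those trials'
#' differences) and recomputes the paired t. Two-sided p-values use the
#' add-one rule `p = (1 + #{|t*| >= |t_obs|}) / (1 + n_rand)`, which keeps
#' p >= 1/(n_rand + 1) and guarantees validity.
#'
#' @param active_power,baseline_power trials x n_vox matrices (same trials).
#' @param n_rand number of randomizations (warning below 100).
#' @param seed integer seed; results are deterministic per seed.
#' @return A list of class `meg_permutation`: `observed_t`, `p_values`,
#'   `n_randomizations`, `seed`.
#' @export
permutation_erd_test <- function(active_power, baseline_power,
                                 n_rand = 5000, seed = 1L) {
  if (n_rand < 100) warning("fewer than 100 randomizations: unstable p floor")
  t_obs <- paired_t(active_power, baseline_power)
  d <- active_power - baseline_power
  n <- nrow(d)
  ss <- colSums(d^2)
  set.seed(seed)
  count <- integer(length(t_obs))
  abs_obs <- abs(t_obs)
  block <- 500L
  done <- 0L
  while (done < n_rand) {
    b <- min(block, n_rand - done)
    S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
    m <- (S %*% d) / n
    v <- sweep(-n * m^2, 2, ss, `+`) / (n - 1)
    tstar <- abs(m / sqrt(v / n))
    tstar[!is.finite(tstar)] <- Inf
    count <- count + colSums(tstar >= rep(abs_obs, each = b) - 1e-12)
    done <- done + b
  }
  structure(list(observed_t = t_obs,
                 p_values = (1 + count) / (1 + n_rand),
                 n_randomizations = as.integer(n_rand),
                 seed = as.integer(seed)),
            class = "meg_permutation")
}

#' @export
print.meg_permutation <- function(x, ...) {
  cat(sprintf("<meg_permutation> %d voxels, %d randomizations (seed %d)\n",
              length(x$p_values), x$n_randomizations, x$seed))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test result
#' @param x a `meg_permutation`.
#' @param ... unused.
#' @return A tibble with columns `voxel`, `t_stat`, `p_value`.
#' @export
tidy.meg_permutation <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$p_values),
                 t_stat = x$observed_t, p_value = x$p_values)
}

#' @rdname tidy.meg_permutation
#' @export
glance.meg_permutation <- function(x, ...) {
  tibble::tibble(n_voxels = length(x$p_values),
                 n_randomizations = x$n_randomizations,
                 min_p = min(x$p_values, na.rm = TRUE), seed = x$seed)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: reject all `p_(i)` with
#' `i <= max{ i : p_(i) <= i * q / m }`. `NA` p-values are never rejected
#' and do not count toward `m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param q FDR level.
#' @return Logical rejection mask, same length as `p_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_meg("p-values must lie in [0, 1]")
  mask <- rep(FALSE, length(p_values))
  mask[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= q
  mask
}
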