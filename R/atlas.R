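# Synthetic parcel atlas: voxels are split by hemisphere (sign of x), the
# left hemisphere is grown into spatially contiguous parcels by multi-source
# breadth-first search on the 6-neighbor lattice graph, and the parcellation
# is mirrored onto the right hemisphere so homologous parcels exist by
# construction (the lattice is staggered off the midline, so mirroring is
# exact). Parcels receive frontal/temporal lobe annotations by the
# anterior-posterior position of their centroid, matched across hemispheres.

#' Build a mirrored synthetic parcel atlas over a source grid
#'
#' @param grid a `meg_grid` from [build_source_grid()].
#' @param n_parcels_per_hemisphere number of parcels per hemisphere (>= 2).
#' @param seed integer seed for the parcel seeds.
#' @return An object of class `meg_atlas`: `labels` (integer per voxel,
#'   1..2P), and `parcels`, a tibble with columns `label`, `name`,
#'   `hemisphere` (L/R) and `lobe` (frontal/temporal).
#' @export
build_synthetic_atlas <- function(grid, n_parcels_per_hemisphere = 4, seed = 1L) {
  P <- as.integer(n_parcels_per_hemisphere)
  if (P < 2L) stop_meg("need at least 2 parcels per hemisphere")
  pts <- grid$points
  left <- which(pts[, 1] < 0)
  right <- which(pts[, 1] > 0)
  if (length(left) < P || length(right) < P)
    stop_meg("fewer voxels than parcels in a hemisphere")

  # integer lattice coordinates of the left-hemisphere voxels
  lp <- pts[left, , drop = FALSE]
  ijk <- round(sweep(lp, 2, apply(lp, 2, min)) / grid$spacing)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  index <- new.env(hash = TRUE, size = length(left))
  kk <- key(ijk)
  for (i in seq_along(kk)) assign(kk[i], i, envir = index)

  set.seed(derive_seed(seed, "atlas-seeds"))
  km <- stats::kmeans(lp, centers = P, nstart = 5, iter.max = 50)
  seeds <- vapply(seq_len(P), function(p) {
    d2 <- rowSums(sweep(lp, 2, km$centers[p, ])^2)
    which.min(d2)
  }, integer(1))
  seeds <- unique(seeds)
  while (length(seeds) < P) seeds <- unique(c(seeds, sample(nrow(lp), 1)))

  # multi-source BFS: each parcel grows one lattice shell at a time, so every
  # parcel is a connected component of the 6-neighbor graph by construction
  lab <- rep(NA_integer_, nrow(lp))
  lab[seeds] <- seq_len(P)
  frontier <- as.list(seeds)
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(frontier) && any(lengths(frontier) > 0)) {
    nxt <- vector("list", P)
    for (p in seq_len(P)) {
      for (v in frontier[[p]]) {
        for (s in seq_len(6)) {
          nb <- ijk[v, ] + steps[s, ]
          j <- mget(paste(nb[1], nb[2], nb[3]), envir = index,
                    ifnotfound = list(NA_integer_))[[1]]
          if (!is.na(j) && is.na(lab[j])) {
            lab[j] <- p
            nxt[[p]] <- c(nxt[[p]], j)
          }
        }
      }
    }
    frontier <- nxt
    if (all(lengths(frontier) == 0)) break
  }
  # isolated stragglers (disconnected left subgraph): nearest labeled voxel
  if (anyNA(lab)) {
    labelled <- which(!is.na(lab))
    for (v in which(is.na(lab))) {
      d2 <- rowSums(sweep(lp[labelled, , drop = FALSE], 2, lp[v, ])^2)
      lab[v] <- lab[labelled[which.min(d2)]]
    }
  }

  # mirror left labels onto the right hemisphere via x -> -x
  labels <- rep(NA_integer_, nrow(pts))
  labels[left] <- lab
  mir <- cbind(-pts[right, 1], pts[right, 2], pts[right, 3])
  nn <- vapply(seq_len(nrow(mir)), function(i) {
    which.min(rowSums(sweep(lp, 2, mir[i, ])^2))
  }, integer(1))
  labels[right] <- lab[nn] + P

  # frontal/temporal by anterior-posterior parcel centroid, mirrored
  cy <- vapply(seq_len(P), function(p) mean(lp[lab == p, 2]), numeric(1))
  lobe_l <- ifelse(rank(cy, ties.method = "first") > P / 2, "frontal", "temporal")
  parcels <- tibble::tibble(
    label = seq_len(2L * P),
    name = c(sprintf("%s_%02d_L", toupper(substr(lobe_l, 1, 1)), seq_len(P)),
             sprintf("%s_%02d_R", toupper(substr(lobe_l, 1, 1)), seq_len(P))),
    hemisphere = rep(c("L", "R"), each = P),
    lobe = rep(lobe_l, 2L))
  structure(list(labels = labels, parcels = parcels),
            class = "meg_atlas")
}

#' @export
print.meg_atlas <- function(x, ...) {
  cat(sprintf("<meg_atlas> %d voxels in %d parcels (%d per hemisphere)\n",
              length(x$labels), nrow(x$parcels), nrow(x$parcels) %/% 2L))
  invisible(x)
}

#' Write / read a parcel atlas as TSV
#'
#' One row per voxel with columns `voxel_index`, `label`, `name`,
#' `hemisphere`, `lobe`.
#'
#' @param atlas a `meg_atlas`.
#' @param path file path.
#' @return `write_atlas` returns `path` invisibly; `read_atlas` returns a
#'   `meg_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  tab <- tibble::tibble(voxel_index = seq_along(atlas$labels),
                        label = atlas$labels)
  tab <- dplyr::left_join(tab, atlas$parcels, by = "label")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parcels <- dplyr::distinct(
    tibble::as_tibble(tab[order(tab$label),
                          c("label", "name", "hemisphere", "lobe")]))
  structure(list(labels = as.integer(tab$label[order(tab$voxel_index)]),
                 parcels = tibble::as_tibble(parcels)),
            class = "meg_atlas")
}
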