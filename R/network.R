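# Graph analysis of the task-related adjacency: proportional binarization,
# hub metrics (degree, eigenvector centrality, betweenness), parcel
# aggregation, the laterality index and the group contrast. Centralities are
# computed with igraph behind this surface.

#' Binarize an adjacency at a fraction of its maximum
#'
#' An edge is present where the (positive) adjacency entry reaches
#' `fraction` times the maximum positive off-diagonal value — the
#' "70% of maximum connectivity strength" rule at the default. Task-related
#' decreases (negative entries) never create edges under the default
#' `edge_sign = "positive"`; `"absolute"` thresholds `|value|` instead.
#'
#' @param adjacency a `meg_adjacency` or symmetric numeric matrix.
#' @param fraction threshold as a fraction of the maximum (0.7 default).
#' @param edge_sign `"positive"` or `"absolute"`.
#' @return An object of class `meg_graph`: `adjacency` (logical, symmetric,
#'   zero diagonal), `threshold_fraction`, `threshold_value`.
#' @export
binarize_by_max_fraction <- function(adjacency, fraction = 0.7,
                                     edge_sign = c("positive", "absolute")) {
  edge_sign <- match.arg(edge_sign)
  V <- if (inherits(adjacency, "meg_adjacency")) adjacency$values else adjacency
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (edge_sign == "absolute") V <- abs(V)
  off <- V[row(V) != col(V)]
  mx <- suppressWarnings(max(off[off > 0]))
  if (!is.finite(mx)) {
    warning("no positive adjacency entry: returning an empty graph")
    A <- matrix(FALSE, nrow(V), ncol(V))
    return(structure(list(adjacency = A, threshold_fraction = fraction,
                          threshold_value = NA_real_),
                     class = "meg_graph"))
  }
  thr <- fraction * mx
  A <- V >= thr
  diag(A) <- FALSE
  A <- A & t(A)
  structure(list(adjacency = A, threshold_fraction = fraction,
                 threshold_value = thr),
            class = "meg_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Node degree
#'
#' Number of suprathreshold connections at each node (row sums of the
#' boolean adjacency).
#'
#' @param g a `meg_graph`.
#' @return Integer vector, one count per node.
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "meg_graph"))
  as.integer(rowSums(g$adjacency))
}

#' Eigenvector centrality
#'
#' Entrywise non-negative leading eigenvector of the binary adjacency,
#' computed on the largest connected component (size ties broken toward the
#' component containing the lowest-index node), zero elsewhere, scaled so
#' the maximum is 1.
#'
#' @param g a `meg_graph`.
#' @return Numeric vector in `[0, 1]`; all zeros (with a warning) for an
#'   edgeless graph.
#' @export
eigenvector_centrality <- function(g) {
  stopifnot(inherits(g, "meg_graph"))
  n <- nrow(g$adjacency)
  if (!any(g$adjacency)) {
    warning("empty graph: eigenvector centrality is all zeros")
    return(numeric(n))
  }
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    first_node <- vapply(big, function(cc) min(which(comp$membership == cc)),
                         integer(1))
    big <- big[which.min(first_node)]
  }
  nodes <- which(comp$membership == big)
  sub <- igraph::induced_subgraph(ig, nodes)
  ev <- igraph::eigen_centrality(sub)$vector   # scaled so max = 1
  out <- numeric(n)
  out[nodes] <- pmax(ev, 0)
  out / max(out)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness (Brandes accumulation); each
#' unordered pair is counted once on undirected graphs.
#'
#' @param g a `meg_graph`.
#' @return Numeric vector of non-negative scores.
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "meg_graph"))
  if (!any(g$adjacency)) return(numeric(nrow(g$adjacency)))
  igraph::betweenness(as_igraph(g), directed = FALSE, normalized = FALSE)
}

#' All three hub metrics as a tibble
#'
#' @param g a `meg_graph`.
#' @return A tibble with columns `voxel`, `degree`, `evc`, `betweenness`.
#' @export
centrality_map <- function(g) {
  tibble::tibble(voxel = seq_len(nrow(g$adjacency)),
                 degree = degree_centrality(g),
                 evc = suppressWarnings(eigenvector_centrality(g)),
                 betweenness = as.numeric(betweenness_centrality(g)))
}

#' Aggregate voxel metrics into parcels and rescale
#'
#' Per-parcel arithmetic mean of each member-voxel metric; with
#' `rescale = TRUE` each metric column is then scaled to `[0, 1]` by its
#' maximum (the group-map convention). Parcels without member voxels keep
#' `NA`.
#'
#' @param metrics a tibble from [centrality_map()] (columns `voxel`,
#'   `degree`, `evc`, `betweenness`).
#' @param atlas a `meg_atlas` covering all voxels.
#' @param rescale logical.
#' @return A tibble with one row per atlas parcel: `label`, `name`,
#'   `hemisphere`, `lobe`, `n_voxels`, `degree`, `evc`, `betweenness`.
#' @export
parcellate_and_scale <- function(metrics, atlas, rescale = TRUE) {
  stopifnot(inherits(atlas, "meg_atlas"))
  if (nrow(metrics) != length(atlas$labels))
    stop_meg("atlas must cover every voxel in the metric map")
  df <- dplyr::mutate(metrics, label = atlas$labels[.data$voxel])
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$label),
    n_voxels = dplyr::n(),
    degree = mean(.data$degree), evc = mean(.data$evc),
    betweenness = mean(.data$betweenness), .groups = "drop")
  out <- dplyr::left_join(atlas$parcels, agg, by = "label")
  out$n_voxels[is.na(out$n_voxels)] <- 0L
  if (rescale) {
    for (cl in c("degree", "evc", "betweenness")) {
      mx <- suppressWarnings(max(out[[cl]], na.rm = TRUE))
      if (is.finite(mx) && mx > 0) out[[cl]] <- out[[cl]] / mx
    }
  }
  out
}

#' Hemispheric laterality index of parcel centrality
#'
#' `LI = (L - R) / (L + R)` where L and R aggregate the chosen metric over
#' left/right frontal and temporal parcels (summation by default).
#' LI above the cutoff is left-lateralized, below its negative
#' right-lateralized, intermediate values bilateral (strict inequalities,
#' so LI equal to the cutoff is bilateral).
#'
#' @param parcels a parcel tibble from [parcellate_and_scale()].
#' @param metric which metric column to lateralize (default `"evc"`).
#' @param aggregate `"sum"` or `"mean"` over frontotemporal parcels.
#' @param cutoff laterality cutoff (0.25).
#' @return A one-row tibble of class `meg_laterality`: `L`, `R`, `li`,
#'   `category`.
#' @export
laterality_index <- function(parcels, metric = "evc",
                             aggregate = c("sum", "mean"), cutoff = 0.25) {
  aggregate <- match.arg(aggregate)
  ft <- parcels[parcels$lobe %in% c("frontal", "temporal"), ]
  if (!any(ft$hemisphere == "L") || !any(ft$hemisphere == "R"))
    stop_meg("need at least one frontotemporal parcel per hemisphere")
  f <- if (aggregate == "sum") sum else mean
  L <- f(ft[[metric]][ft$hemisphere == "L"], na.rm = TRUE)
  R <- f(ft[[metric]][ft$hemisphere == "R"], na.rm = TRUE)
  if (L + R <= 0) {
    warning("L + R is zero: laterality undefined, reporting bilateral")
    li <- NA_real_
  } else li <- (L - R) / (L + R)
  category <- if (!is.na(li) && li > cutoff) "left"
    else if (!is.na(li) && li < -cutoff) "right" else "bilateral"
  out <- tibble::tibble(L = L, R = R, li = li, category = category)
  class(out) <- c("meg_laterality", class(out))
  out
}

#' Parcel-wise group contrast
#'
#' Independent-samples t-test per parcel between two groups of subjects
#' (Welch by default), with Benjamini-Hochberg FDR across parcels. The
#' direction is group A minus group B. Parcels with zero variance in both
#' groups are excluded (`NA`).
#'
#' @param parcels_a,parcels_b lists of parcel tibbles (one per subject),
#'   all over the same atlas.
#' @param metric metric column to contrast.
#' @param q FDR level.
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return A tibble with one row per parcel: `label`, `name`, `hemisphere`,
#'   `lobe`, `mean_a`, `mean_b`, `t_stat`, `p_value`, `significant`.
#' @export
group_contrast <- function(parcels_a, parcels_b, metric = "evc", q = 0.05,
                           var_equal = FALSE) {
  if (length(parcels_a) < 2L || length(parcels_b) < 2L)
    stop_meg("need at least 2 subjects per group")
  labs <- parcels_a[[1]]$label
  for (p in c(parcels_a, parcels_b))
    if (!identical(p$label, labs))
      stop_meg("all subjects must share the same atlas")
  A <- sapply(parcels_a, function(p) p[[metric]])
  B <- sapply(parcels_b, function(p) p[[metric]])
  res <- lapply(seq_along(labs), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(c(mean(a), mean(b), NA_real_, NA_real_))
    tt <- stats::t.test(a, b, var.equal = var_equal)
    c(mean(a), mean(b), unname(tt$statistic), tt$p.value)
  })
  res <- do.call(rbind, res)
  out <- parcels_a[[1]][, c("label", "name", "hemisphere", "lobe")]
  out$mean_a <- res[, 1]; out$mean_b <- res[, 2]
  out$t_stat <- res[, 3]; out$p_value <- res[, 4]
  out$significant <- fdr_bh(out$p_value, q = q)
  out
}
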