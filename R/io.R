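# Persistence: datasets as an RDS payload with a JSON sidecar manifest
# (schema version, dimensions, sampling rate), and analysis bundles as a
# directory of TSV tables plus a JSON run manifest. The TSV layer is the
# exchange format; byte-identical reruns under a fixed seed are part of the
# pipeline contract and are compared at this layer.

#' Write / read a sensor-epochs dataset
#'
#' Stores a `meg_dataset` (or bare `meg_epochs`) as `payload.rds` plus a
#' `manifest.json` describing schema version, dimensions, sampling rate and
#' content hash.
#'
#' @param x a `meg_dataset` or `meg_epochs`.
#' @param path directory to create/use.
#' @return `write_meg_dataset` returns `path` invisibly; `read_meg_dataset`
#'   returns the stored object after checking the manifest.
#' @export
write_meg_dataset <- function(x, path) {
  stopifnot(inherits(x, "meg_dataset") || inherits(x, "meg_epochs"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ep <- if (inherits(x, "meg_dataset")) x$epochs else x
  manifest <- list(schema_version = "1.0",
                   class = class(x)[1],
                   n_trials = dim(ep$data)[1], n_chan = dim(ep$data)[2],
                   n_samples = dim(ep$data)[3], sfreq = ep$sfreq,
                   content_hash = rlang::hash(x))
  saveRDS(x, file.path(path, "payload.rds"), version = 3)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_meg_dataset
#' @export
read_meg_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_meg("not a dataset directory: missing manifest.json")
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$schema_version, "1.0"))
    stop_meg("unsupported schema version: ", manifest$schema_version)
  x <- readRDS(file.path(path, "payload.rds"))
  if (!identical(rlang::hash(x), manifest$content_hash))
    stop_meg("dataset payload does not match its manifest hash")
  x
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.12g", df[[cl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a subject bundle as TSV tables
#'
#' Writes `erd.tsv` (voxel-wise ERD map with inference), `centrality.tsv`,
#' `parcels.tsv`, `laterality.tsv` and a `manifest.json` with provenance
#' (config hash, seed, package version). Output is byte-stable for a fixed
#' seed and input.
#'
#' @param bundle a `meg_bundle` from [run_subject()].
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
write_bundle_tsv <- function(bundle, dir) {
  stopifnot(inherits(bundle, "meg_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(bundle$erd, file.path(dir, "erd.tsv"))
  write_tsv_plain(bundle$centrality, file.path(dir, "centrality.tsv"))
  write_tsv_plain(bundle$parcels, file.path(dir, "parcels.tsv"))
  write_tsv_plain(bundle$laterality, file.path(dir, "laterality.tsv"))
  jsonlite::write_json(bundle$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
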