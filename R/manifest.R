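# Reproducibility manifests: seeds, input digests, per-stage record counts.

#' Write a run manifest for one pipeline stage
#'
#' Records the package version, the stage name, every seed the stage used,
#' MD5 digests of its input files, per-stage record and skip counts, and a
#' timestamp. Manifests make a run auditable: the report stage re-hashes the
#' inputs and warns on mismatch.
#'
#' @param path output JSON path.
#' @param stage stage name (e.g. `"angles"`).
#' @param seeds named list/vector of seeds used (may be empty for
#'   deterministic stages).
#' @param inputs character vector of input file paths to digest.
#' @param counts named list of record counts (e.g. `cells_in`, `angles_out`,
#'   `skipped`).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, stage, seeds = list(), inputs = character(),
                           counts = list()) {
  digests <- if (length(inputs)) {
    d <- as.list(tools::md5sum(inputs))
    names(d) <- basename(inputs)
    d
  } else {
    list()
  }
  manifest <- list(
    tool = "gcorient",
    version = as.character(utils::packageVersion("gcorient")),
    stage = stage,
    seeds = seeds,
    input_digests = digests,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a run manifest
#' @param path manifest JSON path.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path)
}

#' Verify the input digests recorded in a manifest
#'
#' @param manifest a manifest list (from [read_manifest()]).
#' @param dir directory in which the input files live.
#' @return Character vector of file names whose current digest differs from
#'   the recorded one (empty when everything matches; missing files are
#'   reported too).
#' @export
verify_manifest_digests <- function(manifest, dir) {
  bad <- character()
  for (fname in names(manifest$input_digests)) {
    fp <- file.path(dir, fname)
    if (!file.exists(fp)) {
      bad <- c(bad, fname)
    } else if (!identical(unname(tools::md5sum(fp)), manifest$input_digests[[fname]])) {
      bad <- c(bad, fname)
    }
  }
  bad
}
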