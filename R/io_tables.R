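#' Read/write spike tables
#'
#' Two-column plain text: gid, time (ms), one spike per line.
#'
#' @param spikes data.frame (gid, time).
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.table(spikes[, c("gid", "time")], path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  x <- utils::read.table(path, col.names = c("gid", "time"))
  x$gid <- as.integer(x$gid)
  x
}

#' Read/write tabular cell and synapse stores (TSV)
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Load a structured run configuration (YAML)
#'
#' @param path YAML file.
#' @return nested list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a provenance record for a pipeline run
#'
#' Records the configuration, seeds and package version as JSON next to the
#' outputs so runs are reproducible.
#'
#' @param config list of run parameters.
#' @param seed integer seed used.
#' @param path output JSON path.
#' @export
write_provenance <- function(config, seed, path) {
  rec <- list(
    package = "ca1forge",
    version = as.character(utils::packageVersion("ca1forge")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
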