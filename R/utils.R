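`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a TSV file with a header row
#'
#' All tabular artifacts of the pipeline (profiles, correlation maps,
#' networks, scores) are written through this helper so that the on-disk
#' format is uniform: tab-separated, header row, no quoting, no row names.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a configuration mapping from JSON or YAML
#'
#' Used for segment tables, Ballesteros-Weinstein label maps, region
#' definitions and pipeline configs.  Format is chosen by file extension;
#' YAML requires the optional \pkg{yaml} package.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, " (use JSON or YAML)")
  }
}

# Stable md5 fingerprint of an R object (used in output manifests).
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# 32-bit-safe sub-seed derivation: a small counter-based scheme so that
# each (ligand, state) stream depends only on the master seed and its own
# counters, never on generation order.
derive_seed <- function(master, ligand_index, state_index) {
  s <- (as.double(master) * 48271 + ligand_index * 9973 + state_index * 101) %%
    2147483647
  as.integer(s) + 1L
}

# validation failures get their own condition class so the CLI can map
# them to exit code 1 (vs 2 for runtime errors)
validate_stop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("flx_validation_error", "error", "condition")))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  invisible(x)
}
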