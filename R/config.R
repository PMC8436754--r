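#' Hash a configuration for run provenance
#'
#' MD5 of the canonical JSON serialisation; recorded in every artifact a
#' harness run writes so outputs are traceable to their configuration and
#' seed.
#'
#' @param x any jsonlite-serialisable object.
#' @return character MD5 hash.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file with optional keys `phantom` (arguments of
#' [phantom_config]) and `detector` (arguments of [detector_config]) and
#' returns the two constructed configurations. A top-level `seed`
#' applies to both unless overridden inside a section.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return list with elements `phantom`, `detector` and `hash`.
#' @export
load_run_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations",
         call. = FALSE)
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  top_seed <- seed %||% raw$seed
  ph <- raw$phantom %||% list()
  if (is.null(ph$seed)) ph$seed <- top_seed
  if (is.null(ph$seed))
    stop("a seed is required (top-level 'seed', 'phantom$seed' or the ",
         "--seed option)", call. = FALSE)
  det <- raw$detector %||% list()
  phantom <- do.call(phantom_config, ph)
  detector <- do.call(detector_config, det)
  list(phantom = phantom, detector = detector,
       hash = config_hash(list(phantom = unclass(phantom),
                               detector = unclass(detector))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
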