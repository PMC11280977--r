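# Configuration files (YAML or JSON) for phantoms and studies, plus run
# manifests. Every pipeline run can be reproduced from its manifest: the
# echoed configuration, the global seed, and the package version.

read_config_file <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read a phantom configuration from a YAML or JSON file
#'
#' Every field of [phantom_config()] (and of its [lesion_spec()] entries) is
#' addressable in the file; unknown fields are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [phantom_config()].
#' @export
phantom_config_from_file <- function(path) {
  raw <- read_config_file(path)
  allowed <- names(formals(phantom_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown phantom config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$lesions)) {
    raw$lesions <- lapply(raw$lesions, function(l) do.call(lesion_spec, l))
  }
  do.call(phantom_config, raw)
}

#' Read a study configuration from a YAML or JSON file
#'
#' Accepts any argument of [simulate_ff_study()] except `readers`, plus an
#' optional `readers` block with per-reader [reader_model()] fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of arguments for [simulate_ff_study()].
#' @export
study_config_from_file <- function(path) {
  raw <- read_config_file(path)
  allowed <- names(formals(simulate_ff_study))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown study config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$readers)) {
    raw$readers <- lapply(raw$readers, function(r) do.call(reader_model, r))
  }
  raw
}

#' Write a run manifest
#'
#' Records the configuration echo, the global seed and the package version
#' next to a run's outputs so any output file can be regenerated exactly.
#'
#' @param config List (or config object) to echo.
#' @param seed Global seed used.
#' @param dir Output directory.
#' @param name Manifest file name.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(config, seed, dir, name = "manifest.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, name)
  jsonlite::write_json(
    list(
      package = "ffrepro",
      version = as.character(utils::packageVersion("ffrepro")),
      seed = seed,
      config = config
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(path)
}
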