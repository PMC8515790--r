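#' Read a model configuration from YAML or JSON
#'
#' Keys must match [kai_params()] field names; unknown keys and invalid
#' values are rejected with messages naming the field. Missing keys fall
#' back to the package defaults (or to the preset named in the optional
#' `preset` key). Decimal values round-trip exactly through
#' [write_params()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `kai_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  if (!is.list(raw)) stop("config must be a mapping of parameter fields")
  preset <- raw$preset
  raw$preset <- NULL
  base <- if (is.null(preset)) kai_params() else kai_preset(preset)
  known <- names(unclass(base))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(kai_set, c(list(base), raw))
}

#' Write a model configuration
#'
#' JSON output preserves full double precision (`digits = NA`); YAML output
#' uses 15 significant digits, enough to round-trip decimal literals.
#'
#' @param params A `kai_params` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  x <- unclass(validate_params(params))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  invisible(path)
}

#' Save a results table as CSV
#'
#' @param table A data frame (e.g. from [run_sweep()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_results <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
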