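#' Serialize generator parameters to YAML or JSON
#'
#' Round-trips a [registry_params()] object through a plain-text config
#' file; the format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param params A `registry_params` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_registry_params()` returns `path` invisibly;
#'   `read_registry_params()` returns a validated `registry_params`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_registry_params(registry_params(seed = 3), f)
#' read_registry_params(f)$seed  # 3
write_registry_params <- function(params, path) {
  stopifnot(inherits(params, "registry_params"))
  plain <- unclass(params)
  plain$effect_corr <- as.numeric(plain$effect_corr)  # stored column-major
  # named vectors become mappings so names survive JSON
  plain$admission_type_mix <- as.list(plain$admission_type_mix)
  plain$diag_group_mix <- as.list(plain$diag_group_mix)
  if (format_of(path) == "yaml")
    yaml::write_yaml(plain, path, precision = 17)
  else
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  invisible(path)
}

#' @rdname write_registry_params
#' @export
read_registry_params <- function(path) {
  plain <- if (format_of(path) == "yaml")
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  plain$effect_corr <- matrix(as.numeric(plain$effect_corr), 3, 3)
  for (nm in c("admission_type_mix", "diag_group_mix"))
    plain[[nm]] <- unlist(plain[[nm]])
  args <- plain[names(plain) %in% names(formals(registry_params))]
  do.call(registry_params, args)
}

format_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  abort_icubench(
    sprintf("Unsupported config extension '.%s' (use .yaml, .yml or .json).",
            ext),
    "icubench_bad_config")
}
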