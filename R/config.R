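#' Read a sampler configuration from YAML
#'
#' Keys mirror the arguments of [eqtel_control()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#' @param path YAML file.
#' @return an [eqtel_control()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(eqtel_control))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(eqtel_control, cfg)
}

#' Write a JSON run manifest
#'
#' Records the seed, the full configuration and its MD5 hash, package and R
#' versions, and any extra fields (e.g. convergence flags) so a run can be
#' reproduced exactly.
#' @param path output JSON file.
#' @param seed the run seed.
#' @param control the [eqtel_control()] used.
#' @param extra optional named list appended to the manifest.
#' @export
write_run_manifest <- function(path, seed, control, extra = list()) {
  cfg <- lapply(unclass(control), function(x) if (is.null(x)) NA else x)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), tmp)
  manifest <- c(list(
    seed = seed, config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(packageVersion("eqtel")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
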