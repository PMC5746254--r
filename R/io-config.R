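# YAML round-tripping for the two configuration objects users are likely
# to keep under version control.

#' Read and write configuration objects as YAML
#'
#' [connectivity_spec()] and [five_node_config()] objects round-trip
#' through plain YAML files keyed by their field names.
#'
#' @param config A `connectivity_spec` or `five_node_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  kind <- class(config)[1]
  yaml::write_yaml(c(list(kind = kind), unclass(config)), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  kind <- raw$kind
  raw$kind <- NULL
  switch(kind,
    connectivity_spec = do.call(connectivity_spec, c(
      list(rule = raw$rule),
      raw[setdiff(names(raw), "rule")])),
    five_node_config = do.call(five_node_config, raw),
    abort(sprintf("Unknown config kind '%s'.", kind)))
}
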