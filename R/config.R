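#' Read a pipeline configuration file
#'
#' Parses a YAML configuration into the typed config objects the pipeline
#' stages take. Recognized blocks (all optional; omitted keys fall back to
#' the documented defaults):
#'
#' * `columns`: column-name overrides for [compound_schema()];
#' * `descriptor_provider`: `name` (only `"openbabel"` is built in) and
#'   `exclusion_prefixes`;
#' * `thermo`: `constants` with `h_h_atom`, `h_proton`, `h_electron`;
#' * `selection`: arguments of [selection_config()];
#' * `embedding`: arguments of [embedding_config()].
#'
#' @param path Path to a YAML file.
#' @return A list with elements `schema`, `exclusion_prefixes`, `constants`,
#'   `selection`, `embedding`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  schema <- do.call(compound_schema, as.list(raw$columns))
  prefixes <- raw$descriptor_provider$exclusion_prefixes
  if (is.null(prefixes)) prefixes <- default_exclusion_prefixes()
  constants <- do.call(reference_constants, as.list(raw$thermo$constants))
  sel_args <- as.list(raw$selection)
  if (!is.null(sel_args$stages)) sel_args$stages <- unlist(sel_args$stages)
  if (is.null(sel_args$exclusion_prefixes))
    sel_args$exclusion_prefixes <- prefixes
  selection <- do.call(selection_config, sel_args)
  embedding <- do.call(embedding_config, as.list(raw$embedding))
  list(schema = schema, exclusion_prefixes = prefixes,
       constants = constants, selection = selection, embedding = embedding)
}
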