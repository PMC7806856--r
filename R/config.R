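# YAML configuration for the command-line wrapper: generator overrides and
# cascade rule sets can be supplied as plain config files.

#' Read a generator spec from YAML
#'
#' Recognised keys (all optional, defaults from [defaultGeneratorSpec()]):
#' `seed`, `n_per_group` (mapping group -> count), `family`,
#' `outlier_rate`, `outlier_magnitude`.
#'
#' @param path YAML file path.
#' @return A [CohortGeneratorSpec-class].
#' @export
readGeneratorConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  if (!is.null(cfg$n_per_group)) args$nPerGroup <- unlist(cfg$n_per_group)
  if (!is.null(cfg$family)) args$family <- cfg$family
  if (!is.null(cfg$outlier_rate)) args$outlierRate <- cfg$outlier_rate
  if (!is.null(cfg$outlier_magnitude))
    args$outlierMagnitude <- cfg$outlier_magnitude
  do.call(defaultGeneratorSpec, args)
}

.rule_from_yaml <- function(r) {
  .testRule(r$marker, r$cutoff,
            if (is.null(r$direction)) "higher" else r$direction, r$label)
}

#' Read a cascade configuration from YAML
#'
#' Expected layout: `screen:` (mapping with `marker`, `cutoff`, optional
#' `direction`, `label`), `ic_rules:` / `oab_rules:` (lists of the same),
#' optional `combiner` and `on_conflict`. Missing sections fall back to the
#' published default cascade.
#'
#' @param path YAML file path.
#' @return A [CascadeConfig-class].
#' @export
readCascadeConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultCascadeConfig()
  cascadeConfig(
    screen = if (is.null(cfg$screen)) def@screen
    else .rule_from_yaml(cfg$screen),
    icRules = if (is.null(cfg$ic_rules)) def@icRules
    else lapply(cfg$ic_rules, .rule_from_yaml),
    oabRules = if (is.null(cfg$oab_rules)) def@oabRules
    else lapply(cfg$oab_rules, .rule_from_yaml),
    combiner = if (is.null(cfg$combiner)) def@combiner else cfg$combiner,
    onConflict = if (is.null(cfg$on_conflict)) def@onConflict
    else cfg$on_conflict)
}
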