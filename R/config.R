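# Taxon-group configuration: the guild, phylum, Gram, and pathogen
# lookups ship as a YAML file so analyses of real tables can override them
# without touching code.

#' Read a taxon-group configuration
#'
#' Loads guild definitions, the genus-to-phylum and Gram-status lookups,
#' the pathogen species lists, and the mycotoxin food-group weights from a
#' YAML file. With no argument, the configuration shipped with the package
#' (which mirrors the in-code defaults) is read.
#'
#' @param path Path to a YAML configuration; default the shipped file.
#' @return List with `guilds`, `phylum` (named character vector), `gram`
#'   (named character vector), `pathogens`, and `mycotoxin_food_weights`.
#' @export
read_taxon_config <- function(path = system.file("extdata",
                                                 "taxon_groups.yaml",
                                                 package = "micromediate")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(all(c("guilds", "phylum", "gram", "pathogens") %in% names(cfg)))
  cfg$guilds <- lapply(cfg$guilds, as.character)
  cfg$phylum <- unlist(cfg$phylum)
  cfg$gram <- unlist(cfg$gram)
  cfg$pathogens <- lapply(cfg$pathogens, as.character)
  w <- cfg$mycotoxin_food_weights
  if (!is.null(w)) {
    cfg$mycotoxin_food_weights <- unlist(w[c("grains", "dairy", "nuts")])
  }
  cfg
}
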