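# Network and configuration serialization: columnar text tables that
# round-trip losslessly, plus a YAML run configuration.

#' Write a network to delimited text files
#'
#' Writes `<stem>_neurons.tsv`, `<stem>_synapses.tsv` and
#' `<stem>_config.yaml`.
#'
#' @param network a wired `cereb_network`.
#' @param stem path stem.
#' @return The stem, invisibly.
#' @export
write_network <- function(network, stem) {
  stopifnot(inherits(network, "cereb_network"))
  data.table::fwrite(network$neurons, paste0(stem, "_neurons.tsv"),
                     sep = "\t")
  if (!is.null(network$synapses))
    data.table::fwrite(network$synapses, paste0(stem, "_synapses.tsv"),
                       sep = "\t")
  cfg <- network$config
  yaml::write_yaml(list(
    scale_factor = cfg$scale_factor,
    population_sizes = as.list(cfg$population_sizes),
    downbound_fraction = cfg$downbound_fraction,
    mf_cs_target_count = cfg$mf_cs_target_count,
    seed = cfg$seed, scale_deep = cfg$scale_deep,
    scale_relays = cfg$scale_relays
  ), paste0(stem, "_config.yaml"))
  invisible(stem)
}

#' Read a network written by [write_network()]
#'
#' @param stem path stem used when writing.
#' @return A `cereb_network`.
#' @export
read_network <- function(stem) {
  y <- yaml::read_yaml(paste0(stem, "_config.yaml"))
  cfg <- network_config(
    scale_factor = y$scale_factor,
    population_sizes = unlist(y$population_sizes),
    downbound_fraction = y$downbound_fraction,
    mf_cs_target_count = y$mf_cs_target_count,
    seed = y$seed, scale_deep = isTRUE(y$scale_deep),
    scale_relays = isTRUE(y$scale_relays))
  neurons <- data.table::fread(paste0(stem, "_neurons.tsv"))
  neurons[, population := as.character(population)]
  neurons[, module := as.character(module)]
  neurons[, pref := as.character(pref)]
  neurons[pref == "", pref := NA_character_]
  syn_path <- paste0(stem, "_synapses.tsv")
  synapses <- if (file.exists(syn_path)) data.table::fread(syn_path)
              else NULL
  structure(list(neurons = neurons, synapses = synapses, config = cfg,
                 specs = NULL),
            class = "cereb_network")
}
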