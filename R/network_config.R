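# Population bookkeeping ------------------------------------------------------

#' Default population sizes at scale 1
#'
#' Cortical counts follow the detailed scaffold reconstruction of the
#' cerebellar cortex (29,230 neurons: granule, Golgi, Purkinje, stellate and
#' basket cells) plus its mossy-fibre and glomerulus input elements. The deep
#' cerebellar nuclei and inferior olive counts are package fallback defaults
#' chosen to preserve realistic PC:DCN and PC:IO convergence ratios in a
#' two-micromodule mesoscale volume; they are synthetic stand-ins, not
#' literature censuses.
#'
#' @return Named integer vector of counts per population.
#' @export
default_population_sizes <- function() {
  c(GrC = 28615L, GoC = 70L, PC = 99L, SC = 299L, BC = 147L,
    DCN_p = 96L, DCN_GABA = 32L, IO = 14L, mf = 117L, glom = 2336L)
}

cortical_populations <- c("GrC", "GoC", "PC", "SC", "BC")
relay_populations    <- c("mf", "glom")
deep_populations     <- c("DCN_p", "DCN_GABA", "IO")
labelled_populations <- c("PC", "DCN_p", "DCN_GABA", "IO")
mli_populations      <- c("SC", "BC")

# Network configuration --------------------------------------------------------

#' Configure an olivocerebellar network
#'
#' @param scale_factor scale in (0, 1]; applied to the cortical populations.
#' @param population_sizes named counts at scale 1 (see
#'   [default_population_sizes()]).
#' @param downbound_fraction fraction of PC/DCN/IO cells assigned to the
#'   downbound micromodule (default 0.70).
#' @param mf_cs_target_count number of mossy fibres (at scale 1) in the
#'   central cylinder that receives the conditioned stimulus (default 45 of
#'   117).
#' @param seed integer master seed for construction randomness.
#' @param scale_deep,scale_relays whether `scale_factor` also applies to the
#'   deep populations (DCN_p, DCN_GABA, IO) and to the relay input elements
#'   (mf, glom). Both default to `FALSE`: the deep nuclei are already at a
#'   mesoscale minimum and form the motor readout, and keeping the full
#'   mossy-fibre/glomerulus battery preserves the richness of the input code
#'   at reduced cortical scale.
#' @return A `network_config` list with the scaled per-population counts in
#'   `$sizes` and per-micromodule counts in `$module_sizes`.
#' @export
#' @examples
#' cfg <- network_config(scale_factor = 0.1, seed = 1)
#' cfg$sizes[["PC"]]
network_config <- function(scale_factor = 1,
                           population_sizes = default_population_sizes(),
                           downbound_fraction = 0.70,
                           mf_cs_target_count = 45L,
                           seed = 1L,
                           scale_deep = FALSE,
                           scale_relays = FALSE) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0, scale_factor <= 1,
            downbound_fraction > 0, downbound_fraction < 1)
  pops <- names(default_population_sizes())
  if (!all(pops %in% names(population_sizes)))
    stop("population_sizes must name all of: ", paste(pops, collapse = ", "))
  population_sizes <- population_sizes[pops]
  if (any(population_sizes < 1))
    stop("all population counts at scale 1 must be >= 1")

  # Granule cells (and optionally the relay battery) scale linearly: they
  # dominate the computational cost. The sparser readout-chain populations
  # (GoC, PC, SC, BC) scale with sqrt(scale) so that the per-capita
  # signal-to-noise of population-averaged readouts degrades as the fourth
  # root of the scale rather than its square root.
  scaled <- vapply(pops, function(p) {
    f <- if (p == "GrC" ||
             (p %in% relay_populations && scale_relays)) scale_factor
         else if (p %in% cortical_populations ||
                  (p %in% deep_populations && scale_deep)) sqrt(scale_factor)
         else 1
    as.integer(round(f * population_sizes[[p]]))
  }, integer(1))
  zero <- pops[scaled < 1]
  if (length(zero))
    stop("scale factor ", scale_factor, " produces an empty population: ",
         paste(zero, collapse = ", "))

  module_sizes <- lapply(setNames(labelled_populations, labelled_populations),
    function(p) {
      n <- scaled[[p]]
      nd <- as.integer(round(downbound_fraction * n))
      c(downbound = nd, upbound = n - nd)
    })
  for (p in labelled_populations)
    if (any(module_sizes[[p]] < 1))
      stop("population ", p, " has an empty micromodule at this scale; ",
           "increase scale_factor or the population count")

  n_cs <- as.integer(if (scale_relays) round(scale_factor * mf_cs_target_count)
                     else mf_cs_target_count)
  n_cs <- min(n_cs, scaled[["mf"]])
  if (n_cs < 1) stop("no mossy fibres left in the CS target cylinder")

  structure(list(
    scale_factor = scale_factor,
    population_sizes = population_sizes,
    sizes = scaled,
    module_sizes = module_sizes,
    downbound_fraction = downbound_fraction,
    mf_cs_target_count = n_cs,
    seed = as.integer(seed),
    scale_deep = scale_deep,
    scale_relays = scale_relays
  ), class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config> scale", x$scale_factor, "seed", x$seed, "\n")
  print(x$sizes)
  cat("downbound fraction:", x$downbound_fraction,
      " CS mossy fibres:", x$mf_cs_target_count, "of", x$sizes[["mf"]], "\n")
  invisible(x)
}
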