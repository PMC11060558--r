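# The 24 connection types of the olivocerebellar network: 15 within the
# cerebellar cortex and 9 involving the deep nuclei and inferior olive.
#
# Convergence values (mean in-degree at scale 1) and the synaptic weight,
# delay and receptor time constants are package fallback defaults in the
# range reported for the cerebellar scaffold literature; weights carry the
# sign of their effect (negative = inhibitory) and were refined against the
# target baseline discharges with the bisection calibration (see
# calibrate_weights() and the shipped calibration script).

#' Default connection specifications
#'
#' Returns the 24 connection types as one row each. Columns:
#' \describe{
#'   \item{name}{connection type, `pre-post` with the granule-cell axon
#'     segment (`aa` ascending axon, `pf` parallel fibre) spelled out.}
#'   \item{pre, post}{population names.}
#'   \item{convergence}{mean in-degree at scale 1; capped by the available
#'     presynaptic pool when the network is scaled down.}
#'   \item{n_contacts}{parallel synapses realized per connected pair.}
#'   \item{weight}{synaptic conductance (nS); sign encodes effect.}
#'   \item{weight_upbound}{optional differentiated weight for synapses onto
#'     upbound-module cells (micromodule-confined types only); `NA` means
#'     the same weight in both modules.}
#'   \item{delay}{transmission delay (ms), >= 1.}
#'   \item{tau_syn}{alpha-conductance rise/decay time constant (ms).}
#'   \item{plastic}{whether the type is subject to long-term plasticity.}
#'   \item{confined}{whether connections stay within one micromodule.}
#'   \item{local}{whether presynaptic partners are drawn with a spatial
#'     kernel along the mediolateral axis (ascending axons, molecular layer
#'     axons, mossy-fibre rosettes) rather than uniformly (parallel fibres).}
#'   \item{gradient}{climbing-fibre spillover types whose source micromodule
#'     follows the parasagittal probability ramp.}
#'   \item{group}{`cortical` (15 types) or `extracortical` (9 types).}
#' }
#' @return A data.frame with 24 rows.
#' @export
default_connection_specs <- function() {
  s <- function(name, pre, post, conv, contacts, w, delay, tau,
                plastic = FALSE, confined = FALSE, local = FALSE,
                gradient = FALSE, group = "cortical",
                w_upbound = NA_real_) {
    data.frame(name = name, pre = pre, post = post, convergence = conv,
               n_contacts = contacts, weight = w,
               weight_upbound = w_upbound, delay = delay,
               tau_syn = tau, plastic = plastic, confined = confined,
               local = local, gradient = gradient, group = group,
               stringsAsFactors = FALSE)
  }
  rbind(
    # granular-layer input pathway
    s("mf-glom",      "mf",   "glom",     1,   1,  1.000, 1, 1.0, local = TRUE),
    s("glom-GrC",     "glom", "GrC",      4,   1,  0.850, 1, 2.0, local = TRUE),
    s("glom-GoC",     "glom", "GoC",     40,   1,  0.320, 1, 2.0, local = TRUE),
    s("GoC-GrC",      "GoC",  "GrC",      2,   1, -1.200, 2, 5.0, local = TRUE),
    s("GoC-GoC",      "GoC",  "GoC",      8,   1, -0.150, 1, 5.0),
    s("GrC_aa-GoC",   "GrC",  "GoC",    100,   1,  0.040, 2, 1.0, local = TRUE),
    s("GrC_pf-GoC",   "GrC",  "GoC",    400,   1,  0.020, 4, 3.0),
    # granule-to-Purkinje / molecular layer
    s("GrC_aa-PC",    "GrC",  "PC",     100,   1,  0.015, 2, 1.0, local = TRUE),
    s("GrC_pf-PC",    "GrC",  "PC",    2000,   1,  0.018, 4, 3.0, plastic = TRUE),
    s("GrC_pf-SC",    "GrC",  "SC",     300,   1,  0.050, 4, 3.0, plastic = TRUE),
    s("GrC_pf-BC",    "GrC",  "BC",     300,   1,  0.050, 4, 3.0, plastic = TRUE),
    s("SC-PC",        "SC",   "PC",      12,   1, -0.450, 1, 10.0, local = TRUE),
    s("BC-PC",        "BC",   "PC",       9,   1, -0.600, 1, 10.0, local = TRUE),
    s("SC-SC",        "SC",   "SC",       4,   1, -0.100, 1, 5.0, local = TRUE),
    s("BC-BC",        "BC",   "BC",       4,   1, -0.100, 1, 5.0, local = TRUE),
    # deep cerebellar nuclei and inferior olive
    s("mf-DCN_p",     "mf",   "DCN_p",   25,   1,  0.200, 3, 4.0,
      group = "extracortical"),
    s("PC-DCN_p",     "PC",   "DCN_p",   20,   3, -0.250, 2, 14.0,
      confined = TRUE, group = "extracortical", w_upbound = -0.120),
    s("IO-DCN_p",     "IO",   "DCN_p",    1,   1,  0.600, 3, 1.0,
      confined = TRUE, group = "extracortical"),
    s("PC-DCN_GABA",  "PC",   "DCN_GABA", 15,  2, -0.075, 2, 14.0,
      confined = TRUE, group = "extracortical"),
    s("IO-DCN_GABA",  "IO",   "DCN_GABA",  1,  1,  0.500, 3, 1.0,
      confined = TRUE, group = "extracortical"),
    s("DCN_GABA-IO",  "DCN_GABA", "IO",    5,  1, -0.060, 10, 25.0,
      confined = TRUE, group = "extracortical"),
    s("IO-PC",        "IO",   "PC",        1, 10,  2.400, 4, 1.0,
      confined = TRUE, group = "extracortical"),
    s("IO-SC",        "IO",   "SC",        1,  1,  0.700, 4, 1.0,
      gradient = TRUE, group = "extracortical"),
    s("IO-BC",        "IO",   "BC",        1,  1,  0.700, 4, 1.0,
      gradient = TRUE, group = "extracortical")
  )
}

validate_connection_specs <- function(specs, sizes = NULL) {
  req <- c("name", "pre", "post", "convergence", "n_contacts", "weight",
           "weight_upbound", "delay", "tau_syn", "plastic", "confined",
           "local", "gradient", "group")
  miss <- setdiff(req, names(specs))
  if (length(miss)) stop("connection specs missing columns: ",
                         paste(miss, collapse = ", "))
  pops <- names(default_population_sizes())
  bad <- setdiff(unique(c(specs$pre, specs$post)), pops)
  if (length(bad)) stop("connection spec references unknown population: ",
                        paste(bad, collapse = ", "))
  if (any(specs$delay < 1)) stop("all synaptic delays must be >= 1 ms")
  if (any(specs$tau_syn <= 0)) stop("all receptor time constants must be > 0")
  inh_src <- c("GoC", "SC", "BC", "PC", "DCN_GABA")
  up_sign_clash <- !is.na(specs$weight_upbound) &
    sign(specs$weight_upbound) != sign(specs$weight)
  if (any(up_sign_clash))
    stop("weight_upbound must have the same sign as weight: ",
         paste(specs$name[up_sign_clash], collapse = ", "))
  wrong_sign <- specs$pre %in% inh_src & specs$weight > 0
  if (any(wrong_sign))
    stop("inhibitory source with positive weight: ",
         paste(specs$name[wrong_sign], collapse = ", "))
  if (any(!specs$pre %in% inh_src & specs$weight < 0))
    stop("excitatory source with negative weight")
  invisible(specs)
}
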