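# Alpha-shaped conductance synapses and the two climbing-fibre supervised
# long-term plasticity rules.
#
# Both rules are gated by the climbing fibre (teaching signal):
#   pf-MLI: a cf spike potentiates pf synapses in proportion to the alpha
#           kernel K(t) evaluated at the lag of each preceding pf spike;
#           a pf spike without a coincident cf spike depresses its synapse
#           by a fixed amount.
#   pf-PC:  mirror structure with the signs reversed (cf-gated LTD, solo-pf
#           LTP). The pf-PC eligibility kernel is taken as the same alpha
#           form with its own rise time; this is a package fallback for the
#           original rule's kernel and is flagged as such.
# "Coincident" means the same 1-ms simulation step.

#' Alpha-shaped synaptic conductance
#'
#' `g(t) = weight * (t/tau_syn) * exp(1 - t/tau_syn)`, which peaks at
#' exactly `weight` when `t = tau_syn`. Conductances from successive spikes
#' superpose additively.
#'
#' @param t_since_presyn_spike time since the presynaptic spike (ms), >= 0.
#' @param weight peak conductance (nS); sign encodes the synaptic effect.
#' @param tau_syn rise/decay time constant (ms).
#' @return Conductance value(s).
#' @export
#' @examples
#' alpha_conductance(5, weight = 2, tau_syn = 5)   # == 2 at the peak
alpha_conductance <- function(t_since_presyn_spike, weight, tau_syn) {
  stopifnot(tau_syn > 0)
  if (any(t_since_presyn_spike < 0))
    stop("alpha_conductance requires t >= 0")
  weight * (t_since_presyn_spike / tau_syn) *
    exp(1 - t_since_presyn_spike / tau_syn)
}

#' Eligibility kernel of the pf-MLI plasticity rule
#'
#' Alpha function `K(t) = (t/tau) * exp(1 - t/tau)` for `t >= 0` and 0
#' before; its maximum is exactly 1 at `t = tau`. The default rise time of
#' 50 ms matches the peak of interneuron activity modulation within the
#' inter-stimulus interval.
#'
#' @param t lag of a parallel-fibre spike before the climbing-fibre spike
#'   (ms); vectorized.
#' @param tau kernel rise time (ms), default 50.
#' @return Dimensionless kernel value(s) in `[0, 1]`.
#' @export
#' @examples
#' mli_kernel(50)    # 1, the kernel peak
#' mli_kernel(-3)    # 0, no acausal contribution
mli_kernel <- function(t, tau = 50) {
  stopifnot(tau > 0)
  ifelse(t >= 0, (t / tau) * exp(1 - t / tau), 0)
}

#' Parameters of the two plasticity rules
#'
#' @param LTP_PC,LTD_PC,LTP_MLI,LTD_MLI weight-change rates (nS per event);
#'   all >= 0. The shipped defaults were calibrated against the reference
#'   end-of-learning firing modulation and learning-curve shape directly at
#'   the full 10x100-trial protocol (see `scripts/calibrate_rates.R` and
#'   the methods vignette for why the short-sequence x50 shortcut was
#'   rejected).
#' @param tau_mli pf-MLI kernel rise time (ms), default 50.
#' @param tau_pc pf-PC eligibility rise time (ms); fallback default 50.
#' @param w_max_factor upper weight bound as a multiple of the initial
#'   weight (lower bound 0 for the excitatory pf synapses).
#' @return A `plasticity_params` list.
#' @export
plasticity_params <- function(LTP_PC = 2e-6, LTD_PC = 1.6e-5,
                              LTP_MLI = 6e-5, LTD_MLI = 1.4e-5,
                              tau_mli = 50, tau_pc = 50,
                              w_max_factor = 4) {
  stopifnot(LTP_PC >= 0, LTD_PC >= 0, LTP_MLI >= 0, LTD_MLI >= 0,
            tau_mli > 0, tau_pc > 0, w_max_factor > 1)
  structure(list(LTP_PC = LTP_PC, LTD_PC = LTD_PC, LTP_MLI = LTP_MLI,
                 LTD_MLI = LTD_MLI, tau_mli = tau_mli, tau_pc = tau_pc,
                 w_max_factor = w_max_factor),
            class = "plasticity_params")
}

# shared helper: cf-supervised kernel rule over a pair of spike trains.
# Returns a data.frame of weight-change events. `sign_kernel` is +1 for the
# pf-MLI site (cf-gated LTP) and -1 for the pf-PC site (cf-gated LTD);
# `solo_dw` is the per-pf-spike change when no cf spike is coincident.
supervised_kernel_updates <- function(pf_spike_times, cf_spike_times,
                                      rate_kernel, tau, solo_dw,
                                      sign_kernel) {
  if (is.unsorted(pf_spike_times) || is.unsorted(cf_spike_times))
    stop("spike trains must be sorted")
  ev <- list()
  if (length(pf_spike_times)) {
    solo <- !(pf_spike_times %in% cf_spike_times)
    if (any(solo))
      ev[[1]] <- data.frame(time = pf_spike_times[solo], event = "pf_solo",
                            dw = rep(solo_dw, sum(solo)))
  }
  if (length(cf_spike_times) && length(pf_spike_times)) {
    dws <- vapply(cf_spike_times, function(tc) {
      sum(mli_kernel(tc - pf_spike_times[pf_spike_times <= tc], tau = tau))
    }, numeric(1))
    ev[[length(ev) + 1L]] <- data.frame(time = cf_spike_times, event = "cf",
                                        dw = sign_kernel * rate_kernel * dws)
  }
  out <- if (length(ev)) do.call(rbind, ev)
         else data.frame(time = numeric(0), event = character(0),
                         dw = numeric(0))
  out[order(out$time), , drop = FALSE]
}

#' Weight changes of the pf-MLI plasticity rule
#'
#' At each climbing-fibre spike, the synapse is potentiated by `LTP_MLI`
#' times the sum of the kernel evaluated at the lag of every preceding
#' parallel-fibre spike; each parallel-fibre spike without a coincident cf
#' spike depresses the synapse by `LTD_MLI`.
#'
#' @param pf_spike_times,cf_spike_times sorted spike times (ms) of the
#'   parallel fibre and of the supervising climbing fibre.
#' @param params a [plasticity_params()] object.
#' @return A data.frame of weight-change events (`time`, `event`, `dw`)
#'   with the accumulated change in `attr(, "total_dw")`.
#' @export
#' @examples
#' ev <- pf_mli_update(c(700), c(750), plasticity_params(LTP_MLI = 1))
#' attr(ev, "total_dw")  # K(50) = 1 minus one solo-pf LTD step
pf_mli_update <- function(pf_spike_times, cf_spike_times,
                          params = plasticity_params()) {
  ev <- supervised_kernel_updates(pf_spike_times, cf_spike_times,
                                  rate_kernel = params$LTP_MLI,
                                  tau = params$tau_mli,
                                  solo_dw = -params$LTD_MLI,
                                  sign_kernel = +1)
  attr(ev, "total_dw") <- sum(ev$dw)
  ev
}

#' Weight changes of the pf-PC plasticity rule
#'
#' Mirror structure of [pf_mli_update()] with the signs reversed: cf-gated
#' kernel-weighted LTD, and LTP for each parallel-fibre spike without a
#' coincident cf spike.
#'
#' @inheritParams pf_mli_update
#' @return A data.frame of weight-change events, as in [pf_mli_update()].
#' @export
pf_pc_update <- function(pf_spike_times, cf_spike_times,
                         params = plasticity_params()) {
  ev <- supervised_kernel_updates(pf_spike_times, cf_spike_times,
                                  rate_kernel = params$LTD_PC,
                                  tau = params$tau_pc,
                                  solo_dw = params$LTP_PC,
                                  sign_kernel = -1)
  attr(ev, "total_dw") <- sum(ev$dw)
  ev
}

#' Configure the active plasticity rules for a lesion
#'
#' @param lesion_config one of `"control"`, `"ltd_ko"` (pf-PC LTD rate set
#'   to zero), `"mli_ko"` (plasticity untouched; the MLI-to-PC weights are
#'   zeroed by the protocol engine), `"double_ko"` (both).
#' @param params a [plasticity_params()] object.
#' @return The parameter set with the lesioned rates applied, plus a
#'   `disconnect_mli` flag consumed by the protocol engine.
#' @export
#' @examples
#' plasticity_gate("ltd_ko")$LTD_PC  # 0
plasticity_gate <- function(lesion_config,
                            params = plasticity_params()) {
  lesions <- c("control", "ltd_ko", "mli_ko", "double_ko")
  if (!is.character(lesion_config) || length(lesion_config) != 1L ||
      !lesion_config %in% lesions)
    stop("unknown lesion id; expected one of: ",
         paste(lesions, collapse = ", "))
  out <- params
  if (lesion_config %in% c("ltd_ko", "double_ko")) out$LTD_PC <- 0
  out$disconnect_mli <- lesion_config %in% c("mli_ko", "double_ko")
  out$lesion <- lesion_config
  out
}
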