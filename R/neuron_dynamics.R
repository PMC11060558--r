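# Reference R implementation of the E-GLIF point-neuron update. The C++
# simulation engine applies the identical sequence of operations, so the two
# paths are replayable against each other step for step.
#
# Update order within one 1-ms step (documented contract):
#   1. decay the spike-triggered depolarizing current: Idep *= (1 - k1*dt)
#   2. integrate the adaptation current: Iadap += dt*(k_adap*(V-E_L) - k2*Iadap)
#   3. outside the refractory period, integrate the membrane:
#        V += dt*( -(V-E_L)/tau_m + (Ie + Idep - Iadap + I_syn + I_noise)/C )
#      during the refractory period V stays clamped at V_r
#   4. threshold test: a spike is emitted when V >= V_th
#   5. on a spike: V <- V_r, Idep <- A1, Iadap <- Iadap + A2, refractory starts

#' Initial state for an E-GLIF neuron
#'
#' @param params named list of E-GLIF parameters (see
#'   [default_neuron_params()]).
#' @param V optional initial membrane potential; defaults to just below
#'   threshold so autorhythmic cells enter their limit cycle immediately.
#' @return A list with `V`, `Iadap`, `Idep` and `t_since_spike`.
#' @export
neuron_state <- function(params, V = NULL) {
  if (is.null(V)) V <- params$V_th - 1e-3
  list(V = V, Iadap = 0, Idep = 0, t_since_spike = Inf)
}

#' Advance an E-GLIF neuron by one time step
#'
#' @param state neuron state from [neuron_state()].
#' @param params E-GLIF parameter list.
#' @param synaptic_current total synaptic current (pA); finite.
#' @param dt time step (ms), 1 by default (the simulation resolution).
#' @param noise_current optional additional current (pA), e.g. membrane
#'   noise; the network engine draws this internally.
#' @return `list(state = <updated state>, spiked = <logical>)`.
#' @export
#' @examples
#' p <- neuron_params_for("PC")
#' p$Ie <- 742.54
#' st <- neuron_state(p)
#' step_neuron(st, p, synaptic_current = 0)$spiked
step_neuron <- function(state, params, synaptic_current, dt = 1,
                        noise_current = 0) {
  if (!is.finite(synaptic_current))
    stop("non-finite synaptic current passed to step_neuron")
  V <- state$V; Iadap <- state$Iadap; Idep <- state$Idep
  tss <- state$t_since_spike

  Idep <- Idep * (1 - params$k1 * dt)
  Iadap <- Iadap + dt * (params$k_adap * (V - params$E_L) - params$k2 * Iadap)

  refractory <- tss < params$t_ref
  if (refractory) {
    V <- params$V_r
  } else {
    V <- V + dt * (-(V - params$E_L) / params$tau_m +
                     (params$Ie + Idep - Iadap + synaptic_current +
                        noise_current) / params$C)
  }
  spiked <- !refractory && V >= params$V_th
  if (spiked) {
    V <- params$V_r
    Idep <- params$A1
    Iadap <- Iadap + params$A2
    tss <- 0
  } else {
    tss <- tss + dt
  }
  list(state = list(V = V, Iadap = Iadap, Idep = Idep, t_since_spike = tss),
       spiked = spiked)
}

#' Tonic firing rate of an isolated E-GLIF neuron
#'
#' Simulates the neuron for `duration` seconds under a constant drive with
#' no synaptic input and no noise, and returns the spike count divided by
#' the duration. Deterministic.
#'
#' @param params E-GLIF parameter list.
#' @param drive constant current (pA) used in place of `params$Ie`.
#' @param duration simulated time in seconds (>= 5 s recommended for < 1 Hz
#'   estimation error at tonic rates of tens of Hz).
#' @param dt time step (ms).
#' @return Firing rate in Hz.
#' @export
tonic_rate <- function(params, drive = params$Ie, duration = 10, dt = 1) {
  stopifnot(duration > 0)
  p <- params
  p$Ie <- drive
  p$noise_sd <- 0
  n_steps <- round(duration * 1000 / dt)
  egif_tonic_count(
    as.numeric(p$C), as.numeric(p$tau_m), as.numeric(p$E_L),
    as.numeric(p$V_th), as.numeric(p$V_r), as.numeric(p$t_ref),
    as.numeric(p$Ie), as.numeric(p$k_adap), as.numeric(p$k2),
    as.numeric(p$k1), as.numeric(p$A1), as.numeric(p$A2),
    n_steps, dt) / duration
}

#' Relay unit: transmit a spike train unchanged
#'
#' Mossy fibres and glomeruli are relay units that transmit the spike trains
#' they receive; per-target delays are applied downstream at the synapse.
#'
#' @param spikes_in sorted numeric vector of spike times (ms).
#' @return The identical spike train.
#' @export
relay <- function(spikes_in) {
  if (is.unsorted(spikes_in)) stop("relay input spike train must be sorted")
  spikes_in
}
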