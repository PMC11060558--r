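# Bisection calibration of synaptic weights against target baseline
# discharges.

# Default mapping from a target population to the connection type whose
# weight most directly controls its baseline rate. Autorhythmic rates are
# set by the endogenous currents (see default_neuron_params()); the
# calibrated types are the strong inhibitory afferents that shape the
# baseline of the nuclear and olivary populations, plus the granular input.
default_calibration_knobs <- function() {
  c(DCN_p = "PC-DCN_p", DCN_GABA = "PC-DCN_GABA", IO = "DCN_GABA-IO",
    GrC = "glom-GrC")
}

#' Calibrate connection weights to target baseline rates
#'
#' For each target population, a scalar multiplier on its designated
#' afferent connection type is found by bisection so that the simulated
#' no-stimulus baseline rate falls within `tolerance` of the target.
#' Populations already within tolerance keep multiplier 1 with zero
#' bisection iterations. If the initial search interval does not bracket
#' the target, a diagnostic listing the sampled rate-vs-multiplier pairs is
#' raised.
#'
#' @param network a wired `cereb_network`.
#' @param target_baseline_rates named vector, population -> Hz.
#' @param tolerance acceptable deviation (Hz); scalar or named like the
#'   targets.
#' @param knobs population -> connection-type mapping
#'   (default [default_calibration_knobs()]).
#' @param interval multiplier search interval.
#' @param max_iter bisection iteration cap per population.
#' @param duration_ms baseline-run length per evaluation.
#' @param seed integer seed for the evaluation runs.
#' @param multipliers starting multipliers (named by connection type).
#' @return `list(multipliers, report, converged)`; apply the multipliers
#'   via `engine_prep(weight_multipliers = ...)` or
#'   [run_experiment()].
#' @export
calibrate_weights <- function(network, target_baseline_rates,
                              tolerance = 5,
                              knobs = default_calibration_knobs(),
                              interval = c(0.1, 4), max_iter = 12,
                              duration_ms = 2000, seed = 1L,
                              multipliers = NULL) {
  stopifnot(all(target_baseline_rates > 0))
  pops <- names(target_baseline_rates)
  if (is.null(names(tolerance)))
    tolerance <- setNames(rep(tolerance[1], length(pops)), pops)
  mult <- setNames(rep(1, length(knobs)), unname(knobs))
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers

  eval_rates <- function(m) {
    prep <- engine_prep(network, weight_multipliers = as.list(m),
                        record_populations = names(
                          default_population_sizes()))
    baseline_rates(prep, duration_ms = duration_ms, seed = seed)
  }

  report <- list()
  rates <- eval_rates(mult)
  get_rate <- function(rates, p) rates[rates$population == p, ]$rate_hz

  for (p in pops) {
    target <- target_baseline_rates[[p]]
    r0 <- get_rate(rates, p)
    if (abs(r0 - target) <= tolerance[[p]]) {
      report[[p]] <- data.frame(population = p, multiplier = mult[[knobs[[p]]]],
                                rate_hz = r0, target_hz = target,
                                iterations = 0L, converged = TRUE)
      next
    }
    if (!p %in% names(knobs))
      stop("no calibration knob defined for population ", p)
    knob <- knobs[[p]]
    # rate is monotone in the knob multiplier; direction depends on the
    # sign of the afferent (inhibitory knobs: rate decreasing)
    lo <- interval[1]; hi <- interval[2]
    m_lo <- mult; m_lo[knob] <- lo
    m_hi <- mult; m_hi[knob] <- hi
    r_lo <- get_rate(eval_rates(m_lo), p)
    r_hi <- get_rate(eval_rates(m_hi), p)
    increasing <- r_hi >= r_lo
    if ((target < min(r_lo, r_hi) - tolerance[[p]]) ||
        (target > max(r_lo, r_hi) + tolerance[[p]])) {
      stop("calibration interval for ", p, " (knob ", knob,
           ") does not bracket the target ", target, " Hz; sampled ",
           "multiplier->rate: ", interval[1], "->", round(r_lo, 2), ", ",
           interval[2], "->", round(r_hi, 2))
    }
    it <- 0L; mid <- 1; r_mid <- r0
    while (it < max_iter) {
      mid <- (lo + hi) / 2
      m_try <- mult; m_try[knob] <- mid
      r_mid <- get_rate(eval_rates(m_try), p)
      it <- it + 1L
      if (abs(r_mid - target) <= tolerance[[p]]) break
      too_low <- r_mid < target
      if (too_low == increasing) lo <- mid else hi <- mid
    }
    mult[knob] <- mid
    rates <- eval_rates(mult)
    report[[p]] <- data.frame(population = p, multiplier = mid,
                              rate_hz = r_mid, target_hz = target,
                              iterations = it,
                              converged = abs(r_mid - target) <=
                                tolerance[[p]])
  }
  report <- do.call(rbind, report)
  list(multipliers = as.list(mult), report = report,
       converged = all(report$converged))
}
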