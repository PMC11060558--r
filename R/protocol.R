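# CEBC protocol: stimulus schedules and trial/block structure.

#' Configure the classical eyeblink conditioning protocol
#'
#' A trial is `baseline (500 ms) + CS (ISI + 10 ms, co-terminating with the
#' US) + post window (500 ms)`. The conditioned stimulus is a 10-Hz Poisson
#' pattern on the central mossy-fibre subset; the unconditioned stimulus is
#' a 500-Hz, 10-ms burst to the downbound inferior olive; the conditioned
#' olivary response (CIO) is a 400-Hz burst to a fixed half of the downbound
#' olive, 88 ms after CS onset, whose occurrence probability rises linearly
#' over trials to 0.43.
#'
#' @param isi inter-stimulus interval, CS onset to US onset (ms);
#'   default 250, variants 200 and 300.
#' @param baseline_ms,post_ms pre-CS and post-CS windows (ms).
#' @param cs_rate_hz CS Poisson rate on targeted mossy fibres (Hz).
#' @param us_rate_hz,us_duration_ms US burst rate and duration.
#' @param cio_rate_hz,cio_latency_ms,cio_max_p,cio_duration_ms,cio_fraction
#'   CIO burst rate, latency after CS onset, end-of-learning occurrence
#'   probability, burst duration (package default 10 ms, matching the US)
#'   and the fraction of downbound olivary cells targeted.
#' @param bg_rate_hz background mossy-fibre rate (Hz) throughout the trial.
#' @param n_blocks,trials_per_block,n_seeds session structure: 10 blocks of
#'   100 CS-US trials, 3 independent seeds.
#' @return A `protocol_config` list; derived fields `cs_duration_ms`,
#'   `cs_onset_ms`, `trial_len_ms`, `us_onset_ms` and the CR window
#'   `cr_window_ms` (last 200 ms of the ISI) are precomputed.
#' @export
#' @examples
#' protocol_config()$us_onset_ms   # 750
protocol_config <- function(isi = 250, baseline_ms = 500, post_ms = 500,
                            cs_rate_hz = 10, us_rate_hz = 500,
                            us_duration_ms = 10, cio_rate_hz = 400,
                            cio_latency_ms = 88, cio_max_p = 0.43,
                            cio_duration_ms = 10, cio_fraction = 0.5,
                            bg_rate_hz = 1, n_blocks = 10,
                            trials_per_block = 100, n_seeds = 3) {
  stopifnot(isi > 0, cio_latency_ms < isi, cio_max_p >= 0, cio_max_p <= 1,
            cio_fraction >= 0, cio_fraction <= 1, baseline_ms > 0)
  cs_duration <- isi + us_duration_ms       # CS and US co-terminate
  structure(list(
    isi = isi, baseline_ms = baseline_ms, post_ms = post_ms,
    cs_rate_hz = cs_rate_hz, us_rate_hz = us_rate_hz,
    us_duration_ms = us_duration_ms, cio_rate_hz = cio_rate_hz,
    cio_latency_ms = cio_latency_ms, cio_max_p = cio_max_p,
    cio_duration_ms = cio_duration_ms, cio_fraction = cio_fraction,
    bg_rate_hz = bg_rate_hz, n_blocks = n_blocks,
    trials_per_block = trials_per_block, n_seeds = n_seeds,
    cs_duration_ms = cs_duration,
    cs_onset_ms = baseline_ms,
    us_onset_ms = baseline_ms + isi,
    trial_len_ms = baseline_ms + cs_duration + post_ms,
    cr_window_ms = c(baseline_ms + isi - 200, baseline_ms + isi)
  ), class = "protocol_config")
}

poisson_train <- function(rate_hz, t0, t1) {
  n <- rpois(1, rate_hz * (t1 - t0) / 1000)
  if (n == 0) return(numeric(0))
  sort(runif(n, t0, t1))
}

#' Generate the mossy-fibre input of one trial
#'
#' Every mossy fibre receives an independent background Poisson train over
#' the whole trial; the CS-targeted central subset additionally receives an
#' independent 10-Hz Poisson pattern during the CS window. Uses the current
#' RNG state.
#'
#' @param protocol a [protocol_config()].
#' @param network a built `cereb_network` (for mossy-fibre ids and CS
#'   targets).
#' @return Named list of spike-time vectors (ms), one per mossy fibre id.
#' @export
generate_cs <- function(protocol, network) {
  ev <- generate_cs_events(protocol, network)
  mf <- network$neurons[population == "mf"]
  trains <- lapply(split(ev$time, factor(ev$neuron, levels = mf$id)), sort)
  names(trains) <- mf$id
  trains
}

# flat (neuron id, time) representation of the same draw; one rpois/runif
# pair per component instead of one per fibre
generate_cs_events <- function(protocol, network) {
  mf <- network$neurons[population == "mf"]
  n <- nrow(mf)
  nbg <- rpois(n, protocol$bg_rate_hz * protocol$trial_len_ms / 1000)
  bg_t <- runif(sum(nbg), 0, protocol$trial_len_ms)
  bg_id <- rep.int(mf$id, nbg)
  tgt <- mf$id[mf$cs_target]
  ncs <- rpois(length(tgt),
               protocol$cs_rate_hz * protocol$cs_duration_ms / 1000)
  cs_t <- runif(sum(ncs), protocol$cs_onset_ms,
                protocol$cs_onset_ms + protocol$cs_duration_ms)
  list(neuron = c(bg_id, rep.int(tgt, ncs)), time = c(bg_t, cs_t))
}

#' Generate the unconditioned-stimulus burst
#'
#' A regular burst at `us_rate_hz` for `us_duration_ms`, co-terminating
#' with the CS, delivered to every downbound inferior-olive neuron (the
#' upbound olive receives nothing).
#'
#' @param protocol a [protocol_config()].
#' @return Vector of burst spike times (ms, trial clock).
#' @export
#' @examples
#' generate_us(protocol_config())   # 750 752 754 756 758
generate_us <- function(protocol) {
  step <- 1000 / protocol$us_rate_hz
  t0 <- protocol$us_onset_ms
  t0 + seq(0, protocol$us_duration_ms - step / 2, by = step)
}

#' Draw the conditioned olivary response of one trial
#'
#' The occurrence probability grows linearly with the trial number up to
#' `cio_max_p` at the end of learning. When drawn, a `cio_rate_hz` burst of
#' `cio_duration_ms` starts `cio_latency_ms` after CS onset, aimed at a
#' fixed half of the downbound olive (chosen once per experiment).
#'
#' @param trial_index 0-based trial index.
#' @param total_trials total number of trials in the experiment.
#' @param protocol a [protocol_config()].
#' @return `list(occurred = <logical>, times = <burst times or numeric(0)>,
#'   p = <occurrence probability>)`. Uses the current RNG state.
#' @export
schedule_cio <- function(trial_index, total_trials, protocol) {
  stopifnot(trial_index >= 0, trial_index < total_trials)
  p <- protocol$cio_max_p * (trial_index + 1) / total_trials
  occurred <- runif(1) < p
  times <- if (occurred) {
    step <- 1000 / protocol$cio_rate_hz
    t0 <- protocol$cs_onset_ms + protocol$cio_latency_ms
    t0 + seq(0, protocol$cio_duration_ms - step / 2, by = step)
  } else numeric(0)
  list(occurred = occurred, times = times, p = p)
}
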