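# Motor decoding: DCN_p spiking -> analog eyelid signal -> conditioned
# response detection -> learning curves.

# centered convolution with zero padding, renormalized by the kernel mass
# that falls inside the signal (no edge plateaus from value padding)
conv_same <- function(x, k) {
  pad <- (length(k) - 1) %/% 2
  xp <- c(rep(0, pad), x, rep(0, pad))
  num <- stats::filter(xp, k, sides = 2)[(pad + 1):(pad + length(x))]
  wp <- c(rep(0, pad), rep(1, length(x)), rep(0, pad))
  den <- stats::filter(wp, k, sides = 2)[(pad + 1):(pad + length(x))]
  as.numeric(num / den)
}

moving_average <- function(x, width) {
  conv_same(x, rep(1 / width, width + 1 - width %% 2))
}

gaussian_smooth <- function(x, sigma) {
  half <- ceiling(4 * sigma)
  k <- dnorm(-half:half, sd = sigma)
  conv_same(x, k / sum(k))
}

# Filtered per-capita net DCN_p signal over a continuous spike stream
# (times in ms on [0, len_ms)); no baseline subtraction or normalization.
decode_stream <- function(down_times, up_times, n_down, n_up, len_ms,
                          ma_ms = 20, gauss_sd_ms = 25) {
  rate <- function(t, n)
    tabulate(pmin(floor(t) + 1L, len_ms), nbins = len_ms) / n * 1000
  down <- gaussian_smooth(moving_average(rate(down_times, n_down), ma_ms),
                          gauss_sd_ms)
  up <- gaussian_smooth(moving_average(rate(up_times, n_up), ma_ms),
                        gauss_sd_ms)
  down - up
}

# Wrap an amplitude vector as a MotorTrace with pre-CS baseline statistics.
motor_trace <- function(amplitude, baseline_ms = 500) {
  base <- amplitude[seq_len(baseline_ms)]
  structure(list(amplitude = amplitude,
                 baseline_mean = mean(base),
                 baseline_sd = sd(base),
                 baseline_ms = baseline_ms),
            class = "motor_trace")
}

#' Decode DCN output spikes into the analog eyelid signal
#'
#' Rate-based conversion: per-capita instantaneous rate of each DCN_p
#' population on the 1-ms grid, a 20-ms moving average, convolution with a
#' Gaussian window (25-ms width, interpreted as its standard deviation),
#' the net downbound-minus-upbound signal, per-trial baseline subtraction,
#' and normalization by the maximum amplitude of the control simulations.
#' The net signal is per-capita so the 70/30 module size split does not
#' trivially bias the amplitude.
#'
#' @param dcn_down_spikes,dcn_up_spikes spike times (ms) of all downbound /
#'   upbound DCN_p cells in the trial.
#' @param control_max_amplitude normalization constant (maximum eye
#'   closure of the control simulations); knock-out runs must pass the
#'   control value.
#' @param n_down,n_up number of cells in each population.
#' @param trial_len_ms,baseline_ms trial length and pre-CS window (ms).
#' @param ma_ms,gauss_sd_ms filter parameters.
#' @param normalize divide by `control_max_amplitude` (disable to compute
#'   the raw net amplitude when calibrating the constant itself).
#' @return A `motor_trace`: `$amplitude` on the 1-ms grid plus baseline
#'   mean/SD over the pre-CS window.
#' @export
decode_motor <- function(dcn_down_spikes, dcn_up_spikes,
                         control_max_amplitude,
                         n_down, n_up, trial_len_ms = 1260,
                         baseline_ms = 500, ma_ms = 20, gauss_sd_ms = 25,
                         normalize = TRUE) {
  if (normalize &&
      (is.null(control_max_amplitude) || is.na(control_max_amplitude)))
    stop("missing control maximum amplitude; knock-out runs must be ",
         "normalized by the control simulations")
  rate <- function(spk, n) {
    counts <- tabulate(pmin(floor(spk) + 1L, trial_len_ms),
                       nbins = trial_len_ms)
    counts / n * 1000                    # per-capita rate in Hz
  }
  down <- gaussian_smooth(moving_average(rate(dcn_down_spikes, n_down),
                                         ma_ms), gauss_sd_ms)
  up <- gaussian_smooth(moving_average(rate(dcn_up_spikes, n_up), ma_ms),
                        gauss_sd_ms)
  net <- down - up
  net <- net - mean(net[seq_len(baseline_ms)])
  if (normalize) net <- net / control_max_amplitude
  motor_trace(net, baseline_ms = baseline_ms)
}

#' Conditioned-response detection threshold of one trial
#'
#' `threshold = mean(baseline) + 2.5 * STD(baseline)`, floored at 0.2 (only
#' threshold values above 0.2 are allowed).
#'
#' @param trace a `motor_trace`.
#' @return The threshold (normalized amplitude units).
#' @export
#' @examples
#' tr <- motor_trace(c(rep(0.3, 500), rep(0.8, 760)), baseline_ms = 500)
#' compute_cr_threshold(tr)   # 0.3 + 2.5 * 0 = 0.3
compute_cr_threshold <- function(trace) {
  stopifnot(inherits(trace, "motor_trace"))
  max(0.2, trace$baseline_mean + 2.5 * trace$baseline_sd)
}

#' Detect a conditioned response
#'
#' A CR is scored when the motor output reaches the threshold within the CR
#' window, the last 200 ms of the inter-stimulus interval. The onset
#' latency is the first grid point in the window at or above threshold; the
#' peak is the maximum of the trace from the onset to the end of the trial.
#' Latencies are reported relative to CS onset.
#'
#' @param trace a `motor_trace`.
#' @param threshold from [compute_cr_threshold()].
#' @param isi inter-stimulus interval (ms).
#' @param cs_onset_ms CS onset in trial time (ms).
#' @return A `CRResult` list: `is_CR`, `threshold`, `onset_latency_ms`,
#'   `peak_latency_ms`, `peak_amplitude` (latencies `NA` when no CR).
#' @export
detect_cr <- function(trace, threshold, isi = 250, cs_onset_ms = 500) {
  stopifnot(inherits(trace, "motor_trace"))
  amp <- trace$amplitude
  w0 <- cs_onset_ms + isi - 200          # window: last 200 ms of the ISI
  w1 <- cs_onset_ms + isi
  idx <- (w0 + 1):w1                     # grid point i covers [i-1, i) ms
  above <- which(amp[idx] >= threshold)
  if (!length(above))
    return(list(is_CR = FALSE, threshold = threshold,
                onset_latency_ms = NA_real_, peak_latency_ms = NA_real_,
                peak_amplitude = NA_real_))
  onset_idx <- idx[above[1]]
  search <- onset_idx:length(amp)
  peak_idx <- search[which.max(amp[search])]
  list(is_CR = TRUE, threshold = threshold,
       onset_latency_ms = (onset_idx - 1) - cs_onset_ms,
       peak_latency_ms = (peak_idx - 1) - cs_onset_ms,
       peak_amplitude = amp[peak_idx])
}

#' Learning curve: percentage of conditioned responses per block
#'
#' @param cr_results a data.table/data.frame with columns `block`, `seed`
#'   and `is_cr` (one row per trial), e.g. `$cr` of a `cebc_experiment`.
#' @return data.table with `block`, `pct_cr` (mean across seeds of the
#'   per-seed trial percentage), `sd_cr` (across seeds) and `n_trials`.
#' @export
learning_curve <- function(cr_results) {
  dt <- data.table::as.data.table(cr_results)
  if (!nrow(dt)) stop("empty conditioned-response table")
  per_seed <- dt[, .(pct = 100 * mean(is_cr), n = .N), by = .(block, seed)]
  if (any(per_seed$n == 0)) stop("empty block in conditioned-response table")
  out <- per_seed[, .(pct_cr = mean(pct),
                      sd_cr = if (.N > 1) sd(pct) else NA_real_,
                      n_trials = sum(n)), by = block]
  data.table::setorder(out, block)
  out[]
}
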