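# Spike-train analysis: spike density functions, simple/complex spike
# separation, suppression/facilitation quantification, recruitment,
# plasticity curves and SDF-minimum timing distributions.

#' Spike density function by Gaussian-kernel convolution
#'
#' `SDF(t) = sum_k N(t; s_k, width)` in Hz (the per-ms Gaussian density
#' times 1000). "Width" is the kernel standard deviation throughout the
#' package (41 ms for MLI and PC simple spikes, 10 ms for DCN_p, 5 ms for
#' PC complex spikes and the olive).
#'
#' @param spike_times spike times (ms).
#' @param kernel_width_ms Gaussian standard deviation (ms).
#' @param grid evaluation grid (ms), default the 1260-ms trial.
#' @param baseline_ms pre-CS window over which `sdf_baseline` is averaged.
#' @return An `sdf_trace`: `$sdf` (Hz) on `$grid`, with `$sdf_baseline`.
#' @export
#' @examples
#' s <- compute_sdf(c(600, 610), 41)
#' max(s$sdf) <= 2 * 1000 / (41 * sqrt(2 * pi))   # bounded by 2 kernels
compute_sdf <- function(spike_times, kernel_width_ms,
                        grid = seq(0, 1259), baseline_ms = 500) {
  stopifnot(kernel_width_ms > 0)
  sdf <- numeric(length(grid))
  for (s in spike_times)
    sdf <- sdf + dnorm(grid, mean = s, sd = kernel_width_ms)
  sdf <- sdf * 1000                      # per-ms density -> Hz
  base <- sdf[grid >= 0 & grid < baseline_ms]
  structure(list(sdf = sdf, grid = grid,
                 sdf_baseline = if (length(base)) mean(base) else NA_real_,
                 kernel_width_ms = kernel_width_ms,
                 n_spikes = length(spike_times)),
            class = "sdf_trace")
}

#' Separate Purkinje simple spikes from complex spikes
#'
#' Complex spikes are maximal runs of two or more spikes whose
#' inter-spike intervals all correspond to more than twice the baseline
#' firing frequency (interval < `1000 / (2 * baseline_rate)` ms). Each such
#' burst is replaced by a single spike (at the burst onset) in the
#' simple-spike series; the complex-spike series records the burst onsets.
#'
#' @param pc_spike_times sorted spike times (ms) of one Purkinje cell.
#' @param baseline_rate the cell's baseline firing rate (Hz), > 0.
#' @return `list(ss_times = ..., cs_times = ...)`.
#' @export
separate_ss_cs <- function(pc_spike_times, baseline_rate) {
  stopifnot(baseline_rate > 0)
  n <- length(pc_spike_times)
  if (n == 0) return(list(ss_times = numeric(0), cs_times = numeric(0)))
  if (is.unsorted(pc_spike_times)) stop("spike train must be sorted")
  cutoff <- 1000 / (2 * baseline_rate)
  fast <- diff(pc_spike_times) < cutoff
  # run-length encode the "fast interval" flags to find maximal bursts
  run_id <- cumsum(c(TRUE, !fast))
  ss <- numeric(0); cs <- numeric(0)
  for (ids in split(seq_len(n), run_id)) {
    if (length(ids) >= 2) {
      cs <- c(cs, pc_spike_times[ids[1]])
      ss <- c(ss, pc_spike_times[ids[1]])   # burst -> one SS spike
    } else {
      ss <- c(ss, pc_spike_times[ids])
    }
  }
  list(ss_times = ss, cs_times = cs)
}

#' Suppression and facilitation of an SDF trace in the CR window
#'
#' Average percentage deviation from the baseline SDF over the CR-window
#' instants, computed separately over the instants below baseline
#' (suppression, reported <= 0) and above baseline (facilitation, >= 0);
#' instants exactly at baseline belong to neither set. Traces with ~0
#' baseline (e.g. complex-spike SDFs) are flagged as undefined.
#'
#' @param sdf an `sdf_trace`.
#' @param cr_window `c(t0, t1)` in ms (instants `t0 <= t < t1`).
#' @param min_baseline baseline (Hz) below which modulation is undefined.
#' @return A `ModulationResult` list: `suppression`, `facilitation` (%),
#'   `Ns`, `Nf`, and `defined`.
#' @export
compute_modulation <- function(sdf, cr_window, min_baseline = 1e-6) {
  stopifnot(inherits(sdf, "sdf_trace"), length(cr_window) == 2)
  base <- sdf$sdf_baseline
  if (!is.finite(base) || base <= min_baseline)
    return(list(suppression = NA_real_, facilitation = NA_real_,
                Ns = NA_integer_, Nf = NA_integer_, defined = FALSE))
  inw <- sdf$grid >= cr_window[1] & sdf$grid < cr_window[2]
  dev <- (sdf$sdf[inw] / base - 1) * 100
  sup <- dev[dev < 0]; fac <- dev[dev > 0]
  list(suppression = if (length(sup)) mean(sup) else 0,
       facilitation = if (length(fac)) mean(fac) else 0,
       Ns = length(sup), Nf = length(fac), defined = TRUE)
}

#' Significance of CR-window modulation against baseline variability
#'
#' A trace is significantly modulated when its dominant CR-window
#' deviation (the larger of |suppression| and facilitation) strictly
#' exceeds the corresponding deviation magnitude computed with the same
#' formula over the baseline window itself.
#'
#' @param mod CR-window [compute_modulation()] result.
#' @param baseline_mod the same computation applied to the baseline window.
#' @return Logical flag.
#' @export
flag_significant <- function(mod, baseline_mod) {
  if (!isTRUE(mod$defined) || !isTRUE(baseline_mod$defined)) return(FALSE)
  if (abs(mod$suppression) >= mod$facilitation)
    abs(mod$suppression) > abs(baseline_mod$suppression)
  else
    mod$facilitation > baseline_mod$facilitation
}

# Modulation + significance for one spike train, using the package's
# standard windows: CR window against the pre-CS baseline window.
modulate_trace <- function(spike_times, kernel_width_ms, cr_window,
                           baseline_ms = 500, grid = seq(0, 1259)) {
  sdf <- compute_sdf(spike_times, kernel_width_ms, grid = grid,
                     baseline_ms = baseline_ms)
  mod <- compute_modulation(sdf, cr_window)
  base_mod <- compute_modulation(sdf, c(0, baseline_ms))
  mod$significant <- flag_significant(mod, base_mod)
  mod$sdf <- sdf
  mod
}

#' Neuronal recruitment: percentage of significantly modulated traces
#'
#' @param mods a list of modulation results (each with `$significant`,
#'   `$suppression`, `$facilitation`).
#' @return `list(pct_significant, pct_suppressing, pct_facilitating, n)`.
#' @export
recruitment <- function(mods) {
  mods <- Filter(function(m) isTRUE(m$defined), mods)
  if (!length(mods)) stop("no defined modulation traces to summarize")
  sig <- vapply(mods, function(m) isTRUE(m$significant), logical(1))
  dir_sup <- vapply(mods, function(m)
    abs(m$suppression) >= m$facilitation, logical(1))
  list(pct_significant = 100 * mean(sig),
       pct_suppressing = 100 * mean(sig & dir_sup),
       pct_facilitating = 100 * mean(sig & !dir_sup),
       n = length(mods))
}

#' Plasticity curves from per-block weight snapshots
#'
#' For each block, the average percentage weight change relative to the
#' initial weight, multiplied by the fraction of synapses undergoing that
#' change, reported separately for the LTD (negative) and LTP (positive)
#' directions.
#'
#' @param snapshots blocks x synapses matrix of weights.
#' @param w_init initial weights (length = columns of `snapshots`).
#' @return data.table with `block`, `ltd`, `ltp` (both in %).
#' @export
plasticity_curves <- function(snapshots, w_init) {
  stopifnot(ncol(snapshots) == length(w_init), all(w_init > 0))
  out <- lapply(seq_len(nrow(snapshots)), function(b) {
    pct <- (snapshots[b, ] / w_init - 1) * 100
    dn <- pct[pct < 0]; up <- pct[pct > 0]
    data.table::data.table(
      block = b,
      ltd = if (length(dn)) mean(dn) * length(dn) / length(pct) else 0,
      ltp = if (length(up)) mean(up) * length(up) / length(pct) else 0)
  })
  data.table::rbindlist(out)
}

#' Distribution of SDF minimum times in the CR window
#'
#' Histogram (probability per bin) of the time of the SDF minimum within
#' the CR window across traces; a proxy of simple-spike suppression timing
#' precision. The squared distance between two such histograms is
#' `sum((p1 - p2)^2)`.
#'
#' @param sdf_list list of `sdf_trace` objects.
#' @param cr_window `c(t0, t1)` ms.
#' @param bin_ms histogram bin width.
#' @return `list(breaks, prob, min_times)`.
#' @export
sdf_min_time_distribution <- function(sdf_list, cr_window, bin_ms = 10) {
  stopifnot(length(sdf_list) > 0)
  mins <- vapply(sdf_list, function(s) {
    inw <- s$grid >= cr_window[1] & s$grid < cr_window[2]
    s$grid[inw][which.min(s$sdf[inw])]
  }, numeric(1))
  breaks <- seq(cr_window[1], cr_window[2], by = bin_ms)
  if (breaks[length(breaks)] < cr_window[2])
    breaks <- c(breaks, cr_window[2])
  h <- hist(mins, breaks = breaks, plot = FALSE)
  list(breaks = breaks, prob = h$counts / sum(h$counts), min_times = mins)
}

#' Squared distance between two histograms
#'
#' @param p1,p2 probability vectors over identical bins.
#' @return `sum((p1 - p2)^2)`.
#' @export
histogram_sq_distance <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  sum((p1 - p2)^2)
}

#' @importFrom graphics hist
NULL

#' Full modulation analysis of a CEBC experiment's retained spikes
#'
#' Applies the package's standard pipeline to the last retained block of a
#' `cebc_experiment`: per cell and trial, Purkinje trains are split into
#' simple and complex spikes (using each cell's first-block baseline rate),
#' SDFs are computed with the population-specific kernels, and
#' suppression/facilitation with significance are evaluated in the CR
#' window.
#'
#' @param exp_res a `cebc_experiment` with spikes kept for the block of
#'   interest.
#' @param population one of `"PC"` (simple spikes), `"MLI"`, `"DCN_p"`.
#' @param module `"downbound"` or `"upbound"`; for MLIs this selects the
#'   preference label.
#' @param block which retained block to analyse (default the last).
#' @param trials optional subset of trial indices within the block.
#' @return list of per-trace modulation results (cells x trials).
#' @export
analyse_modulation <- function(exp_res, population = "PC",
                               module = "downbound", block = NULL,
                               trials = NULL) {
  stopifnot(inherits(exp_res, "cebc_experiment"))
  pr <- exp_res$protocol
  crw <- pr$cr_window_ms
  crw[1] <- pr$cs_onset_ms + 50          # exclude first 50 ms of the ISI
  grid <- seq(0, pr$trial_len_ms - 1)
  kern <- c(PC = 41, MLI = 41, DCN_p = 10)[[population]]
  want_pop <- population
  want_mod <- module
  mods <- list()
  for (si in seq_along(exp_res$spikes)) {
    blocks <- exp_res$spikes[[si]]
    if (!length(blocks)) next
    bname <- if (is.null(block)) names(blocks)[length(blocks)]
             else as.character(block)
    sp <- blocks[[bname]]
    first <- blocks[[1]]
    sel <- if (want_pop == "MLI")
      sp[population %in% c("SC", "BC") & pref == want_mod]
    else sp[population == want_pop & module == want_mod]
    if (!is.null(trials)) sel <- sel[trial %in% trials]
    for (cell in unique(sel$neuron)) {
      cell_tr <- sel[neuron == cell]
      # cell's baseline rate: pre-CS windows of the first retained block
      fb <- first[neuron == cell & time < pr$baseline_ms]
      base_rate <- nrow(fb) / (length(unique(first$trial)) *
                                 pr$baseline_ms / 1000)
      for (tr in unique(cell_tr$trial)) {
        st <- sort(cell_tr[trial == tr, time])
        if (want_pop == "PC") {
          if (base_rate <= 0) next
          st <- separate_ss_cs(st, base_rate)$ss_times
        }
        mods[[length(mods) + 1L]] <-
          modulate_trace(st, kern, crw, baseline_ms = pr$baseline_ms,
                         grid = grid)
      }
    }
  }
  mods
}
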