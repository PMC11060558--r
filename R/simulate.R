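# Engine preparation and the trial/experiment runners.
#
# engine_prep() flattens a wired network into the columnar arrays the C++
# core consumes (0-based ids, CSR adjacency, per-(neuron, receptor)
# conductance channels); engine_state() allocates the mutable state the
# engine updates in place. run_trial()/run_experiment() drive the CEBC
# protocol on top of them.

plastic_site_of <- function(type) {
  ifelse(type == "GrC_pf-PC", 1L,
         ifelse(type %in% c("GrC_pf-SC", "GrC_pf-BC"), 2L, 0L))
}

#' Compile a wired network for the simulation engine
#'
#' @param network a wired `cereb_network`.
#' @param neuron_params E-GLIF parameter table ([default_neuron_params()]).
#' @param plasticity a (possibly lesion-gated) [plasticity_params()] object;
#'   use [plasticity_gate()] to apply a knock-out. The `mli_ko` lesion is
#'   realized here by zeroing the SC-PC and BC-PC weights.
#' @param record_populations populations whose spikes are recorded.
#' @param weight_multipliers optional named per-connection-type weight
#'   multipliers (e.g. from [calibrate_weights()]).
#' @param stim_populations populations given a direct-stimulation
#'   conductance channel (default the inferior olive, the US/CIO entry
#'   point).
#' @param stim_E,stim_tau reversal (mV) and time constant (ms) of the
#'   stimulation channel.
#' @param gap_w fast spike-mediated electrical coupling between Golgi cells
#'   (mV depolarization of the other GoCs per GoC spike); an approximation
#'   of their gap junctions.
#' @return An opaque `engine_prep` list consumed by [run_trial()] and
#'   [run_experiment()].
#' @export
engine_prep <- function(network,
                        neuron_params = default_neuron_params(),
                        plasticity = plasticity_gate("control"),
                        record_populations = c("GoC", "PC", "SC", "BC",
                                               "DCN_p", "DCN_GABA", "IO"),
                        weight_multipliers = NULL,
                        stim_populations = "IO",
                        stim_E = 0, stim_tau = 1,
                        gap_w = 0.2) {
  stopifnot(inherits(network, "cereb_network"), !is.null(network$synapses))
  nt <- network$neurons
  n <- nrow(nt)
  syn <- data.table::copy(network$synapses)

  if (!is.null(weight_multipliers)) {
    for (tp in names(weight_multipliers))
      syn[type == tp, weight := weight * weight_multipliers[[tp]]]
  }
  if (isTRUE(plasticity$disconnect_mli))
    syn[type %in% c("SC-PC", "BC-PC"), weight := 0]

  # per-neuron parameters (relays get inert zeros)
  pt <- neuron_params[match(nt$population, neuron_params$population), ]
  pt[is.na(pt$C), setdiff(names(pt), "population")] <- 0
  pt$C[pt$C == 0] <- 1
  pt$tau_m[pt$tau_m == 0] <- 1
  ie <- pt$Ie
  for (pop in intersect(labelled_populations, neuron_params$population)) {
    prow <- neuron_params[neuron_params$population == pop, ]
    rows <- which(nt$population == pop)
    if (!length(rows)) next
    down <- rows[nt$module[rows] == "downbound"]
    up <- rows[nt$module[rows] == "upbound"]
    if (!is.na(prow$Ie_downbound)) ie[down] <- prow$Ie_downbound
    if (!is.na(prow$Ie_upbound)) ie[up] <- prow$Ie_upbound
  }
  is_relay <- as.integer(nt$population %in% relay_populations)

  # conductance channels: one per (postsynaptic neuron, tau, reversal class)
  syn[, cls := ifelse(weight < 0, "inh", "exc")]
  post_relay <- nt$population[syn$post] %in% relay_populations
  chan_src <- unique(syn[!post_relay, .(neuron = post, tau = tau_syn, cls)])
  stim_rows <- which(nt$population %in% stim_populations)
  if (length(stim_rows))
    chan_src <- rbind(chan_src,
                      data.table::data.table(neuron = stim_rows,
                                             tau = stim_tau, cls = "stim"))
  data.table::setorder(chan_src, neuron, tau, cls)
  chan_src[, idx0 := .I - 1L]
  ch_E <- ifelse(chan_src$cls == "inh", -80,
                 ifelse(chan_src$cls == "stim", stim_E, 0))
  ch_decay <- exp(-1 / chan_src$tau)
  neuron_ch_ptr <- c(0L, cumsum(tabulate(chan_src$neuron, nbins = n)))

  stim_ch <- rep(-1L, n)
  sr <- chan_src[cls == "stim"]
  stim_ch[sr$neuron] <- sr$idx0

  # synapse arrays, CSR by presynaptic id
  key <- function(neuron, tau, cls) paste(neuron, tau, cls, sep = "\r")
  ch_map <- setNames(chan_src$idx0, key(chan_src$neuron, chan_src$tau,
                                        chan_src$cls))
  syn[, channel := ifelse(post_relay, -1L,
                          ch_map[key(post, tau_syn, cls)])]
  syn[, site := plastic_site_of(type)]
  cf_types <- c("IO-PC", "IO-SC", "IO-BC")
  syn[, is_cf := type %in% cf_types & !duplicated(paste(pre, post, type))]
  data.table::setorder(syn, pre)
  syn_ptr <- c(0L, cumsum(tabulate(syn$pre, nbins = n)))

  w_init <- abs(syn$weight)
  w_max <- ifelse(syn$site > 0L, plasticity$w_max_factor * w_init, Inf)

  pl_rows <- which(syn$site > 0L)
  pl_ord <- pl_rows[order(syn$post[pl_rows])]
  plastic_ptr <- c(0L, cumsum(tabulate(syn$post[pl_ord], nbins = n)))

  spec <- list(
    n_neurons = n,
    is_relay = is_relay,
    record = as.integer(nt$population %in% record_populations),
    C = as.numeric(pt$C), tau_m = as.numeric(pt$tau_m),
    E_L = as.numeric(pt$E_L), V_th = as.numeric(pt$V_th),
    V_r = as.numeric(pt$V_r),
    ref_steps = as.integer(ceiling(pt$t_ref)),
    Ie = as.numeric(ie), k_adap = as.numeric(pt$k_adap),
    k2 = as.numeric(pt$k2), k1 = as.numeric(pt$k1),
    A1 = as.numeric(pt$A1), A2 = as.numeric(pt$A2),
    noise_sd = as.numeric(pt$noise_sd),
    neuron_ch_ptr = as.integer(neuron_ch_ptr),
    ch_E = as.numeric(ch_E), ch_decay = as.numeric(ch_decay),
    syn_ptr = as.integer(syn_ptr),
    syn_post = as.integer(syn$post - 1L),
    syn_channel = as.integer(syn$channel),
    syn_delay = as.integer(round(syn$delay)),
    syn_site = as.integer(syn$site),
    syn_is_cf = as.integer(syn$is_cf),
    syn_post_relay = as.integer(nt$population[syn$post] %in%
                                  relay_populations),
    syn_coef = as.numeric(exp(1) / syn$tau_syn),
    plastic_ptr = as.integer(plastic_ptr),
    plastic_idx = as.integer(pl_ord - 1L),
    w_max = as.numeric(w_max),
    LTP_PC = plasticity$LTP_PC, LTD_PC = plasticity$LTD_PC,
    LTP_MLI = plasticity$LTP_MLI, LTD_MLI = plasticity$LTD_MLI,
    tau_pc = plasticity$tau_pc, tau_mli = plasticity$tau_mli,
    goc_ids = as.integer(which(nt$population == "GoC") - 1L),
    gap_w = gap_w,
    stim_ch = as.integer(stim_ch),
    stim_coef = exp(1) / stim_tau,
    max_delay = max(as.integer(round(syn$delay)))
  )

  meta <- list(
    neurons = nt,
    syn_type = syn$type, syn_pre = syn$pre, syn_post1 = syn$post,
    w_signed = syn$weight, w_init = w_init,
    plastic_rows = pl_rows,
    plasticity = plasticity,
    record_populations = record_populations
  )
  structure(list(spec = spec, meta = meta, network = network),
            class = "engine_prep")
}

#' Allocate mutable engine state
#'
#' Membrane potentials start staggered uniformly between reset and
#' threshold so autorhythmic populations desynchronize immediately.
#'
#' @param prep an [engine_prep()] object.
#' @param seed integer seed for the initial-condition stagger.
#' @return A state list updated in place by the engine.
#' @export
engine_state <- function(prep, seed = 1L) {
  spec <- prep$spec
  n <- spec$n_neurons
  init <- with_seed(derive_seed(seed, "init"), {
    # stagger membrane potential and adaptation phase so pacemaker
    # populations desynchronize from the first trial
    list(V = runif(n, spec$V_r, spec$V_th),
         Iadap = runif(n, 0, 1) * spec$A2)
  })
  list(
    V = as.numeric(init$V),
    Iadap = as.numeric(init$Iadap), Idep = numeric(n),
    refr = integer(n),
    ch_g = numeric(length(spec$ch_E)), ch_h = numeric(length(spec$ch_E)),
    syn_w = as.numeric(abs(prep$meta$w_signed)),
    trace_P = numeric(length(prep$meta$w_signed)),
    trace_Q = numeric(length(prep$meta$w_signed)),
    trace_t = integer(length(prep$meta$w_signed)),
    last_cf = integer(spec$n_neurons)
  )
}

# Build the flattened stimulus arrays for a set of trials.
# `cio_draws` is a list (occurred flag + times) per trial, already drawn.
build_stim <- function(prep, protocol, mf_trains_per_trial, cio_draws,
                       us_stim_w = 30, cio_stim_w = 18) {
  nt <- prep$meta$neurons
  mf_ids <- nt[population == "mf", id]
  io_down <- nt[population == "IO" & module == "downbound", id]

  us_times <- as.integer(floor(generate_us(protocol)))
  n_tr <- length(mf_trains_per_trial)
  RL <- vector("list", n_tr)
  CD <- vector("list", n_tr)

  for (k in seq_len(n_tr)) {
    trains <- mf_trains_per_trial[[k]]
    if (!is.null(trains$neuron)) {           # pre-flattened (neuron, time)
      rl_nr <- as.integer(trains$neuron)
      rl_tm <- as.integer(floor(trains$time))
    } else {                                 # named list of per-fibre trains
      lens <- lengths(trains)
      rl_nr <- rep.int(as.integer(names(trains)), lens)
      rl_tm <- as.integer(floor(unlist(trains, use.names = FALSE)))
    }
    RL[[k]] <- list(tr = rep.int(k - 1L, length(rl_nr)), nr = rl_nr,
                    tm = rl_tm)
    cd_nr <- rep(io_down, each = length(us_times))
    cd_tm <- rep.int(us_times, length(io_down))
    cd_am <- rep.int(us_stim_w, length(cd_nr))
    cio <- cio_draws[[k]]
    if (isTRUE(cio$occurred) && length(cio$targets)) {
      tms <- as.integer(floor(cio$times))
      cd_nr <- c(cd_nr, rep(cio$targets, each = length(tms)))
      cd_tm <- c(cd_tm, rep.int(tms, length(cio$targets)))
      cd_am <- c(cd_am, rep.int(cio_stim_w, length(tms) * length(cio$targets)))
    }
    CD[[k]] <- list(tr = rep.int(k - 1L, length(cd_nr)), nr = cd_nr,
                    tm = cd_tm, am = cd_am)
  }
  pull <- function(L, f) unlist(lapply(L, `[[`, f), use.names = FALSE)
  rl_tr <- pull(RL, "tr"); rl_nr <- pull(RL, "nr"); rl_tm <- pull(RL, "tm")
  cd_tr <- pull(CD, "tr"); cd_nr <- pull(CD, "nr"); cd_tm <- pull(CD, "tm")
  cd_am <- pull(CD, "am")
  ro <- order(rl_tr, rl_tm)
  co <- order(cd_tr, cd_tm)
  list(relay_trial = rl_tr[ro], relay_neuron = as.integer(rl_nr[ro] - 1L),
       relay_time = rl_tm[ro],
       cond_trial = cd_tr[co], cond_neuron = as.integer(cd_nr[co] - 1L),
       cond_time = cd_tm[co], cond_amt = cd_am[co])
}

spikes_to_dt <- function(raw, prep, trial_offset = 0L) {
  nt <- prep$meta$neurons
  data.table::data.table(
    trial = raw$trial + 1L + trial_offset,
    neuron = raw$neuron + 1L,
    population = nt$population[raw$neuron + 1L],
    module = nt$module[raw$neuron + 1L],
    pref = nt$pref[raw$neuron + 1L],
    time = as.numeric(raw$time))
}

#' Run a single CEBC trial
#'
#' Generates the trial's stimuli (CS + background mossy-fibre input, US
#' burst, optional CIO), advances the engine for one full trial and returns
#' the recorded spikes. The state is updated in place.
#'
#' @param prep an [engine_prep()] (encapsulates network, lesion and
#'   plasticity configuration).
#' @param state an [engine_state()], modified in place.
#' @param protocol a [protocol_config()].
#' @param trial_index 0-based index of this trial within the experiment
#'   (drives the CIO probability ramp).
#' @param total_trials total number of trials in the experiment.
#' @param cio_targets ids of the downbound olivary cells eligible for the
#'   CIO (fixed per experiment); `NULL` disables the CIO.
#' @param seed integer seed for this trial's stimuli and noise.
#' @param plastic_on whether plastic updates are applied.
#' @param us_on whether the US is delivered (background-only runs set
#'   `FALSE`).
#' @param us_stim_w,cio_stim_w stimulation conductances (nS) of the US and
#'   CIO bursts at the olive.
#' @return A data.table of spikes (trial, neuron, population, module, time).
#' @export
run_trial <- function(prep, state, protocol, trial_index = 0L,
                      total_trials = 1L, cio_targets = NULL, seed = 1L,
                      plastic_on = TRUE, us_on = TRUE,
                      us_stim_w = 30, cio_stim_w = 18) {
  stim <- with_seed(derive_seed(seed, paste0("stim", trial_index)), {
    trains <- generate_cs(protocol, prep$network)
    cio <- if (!is.null(cio_targets) && length(cio_targets)) {
      d <- schedule_cio(trial_index, total_trials, protocol)
      d$targets <- cio_targets
      d
    } else list(occurred = FALSE, times = numeric(0), targets = integer(0))
    build_stim(prep, protocol, list(trains), list(cio),
               us_stim_w = if (us_on) us_stim_w else 0,
               cio_stim_w = cio_stim_w)
  })
  raw <- engine_run(prep$spec, state, stim, 1L, protocol$trial_len_ms,
                    derive_seed(seed, "noise"), as.integer(trial_index),
                    plastic_on)
  spikes_to_dt(raw, prep, trial_offset = as.integer(trial_index))
}

# Mean firing rate per population (Hz) from a background-only run.
population_rates <- function(spikes, prep, window_ms, by_module = FALSE) {
  nt <- prep$meta$neurons
  counts <- spikes[time >= window_ms[1] & time < window_ms[2]]
  dur_s <- (window_ms[2] - window_ms[1]) / 1000
  grp <- if (by_module) c("population", "module") else "population"
  base <- unique(nt[, c("population", "module")])
  if (!by_module) base <- unique(base[, "population"])
  cnt <- counts[, .N, by = grp]
  out <- merge(base, cnt, by = grp, all.x = TRUE)
  out$N[is.na(out$N)] <- 0L
  sizes <- nt[, .N, by = grp]
  data.table::setnames(sizes, "N", "n_cells")
  out <- merge(out, sizes, by = grp)
  out$rate_hz <- out$N / out$n_cells / dur_s
  data.table::setDT(out)[]
}

#' Baseline population rates under background input only
#'
#' Runs the network with 1-Hz mossy-fibre background and no CS/US/CIO for
#' `duration_ms`, and returns mean per-capita firing rates (the transient
#' before `settle_ms` is discarded).
#'
#' @param prep an [engine_prep()] built with the populations of interest in
#'   `record_populations`.
#' @param protocol a [protocol_config()] (for the background rate).
#' @param duration_ms,settle_ms run length and discarded initial transient.
#' @param seed integer seed.
#' @param by_module split PC/DCN/IO rates by micromodule.
#' @return data.table of per-population rates (Hz).
#' @export
baseline_rates <- function(prep, protocol = protocol_config(),
                           duration_ms = 3000, settle_ms = 500,
                           seed = 1L, by_module = FALSE) {
  pr <- protocol
  pr$trial_len_ms <- duration_ms
  pr$cs_onset_ms <- duration_ms + 1     # no CS window inside the run
  pr$cs_duration_ms <- 0
  state <- engine_state(prep, seed = seed)
  stim <- with_seed(derive_seed(seed, "baseline"), {
    nt <- prep$meta$neurons
    mf <- nt[population == "mf"]
    trains <- lapply(seq_len(nrow(mf)), function(i)
      poisson_train(pr$bg_rate_hz, 0, duration_ms))
    names(trains) <- mf$id
    build_stim(prep, pr, list(trains),
               list(list(occurred = FALSE, times = numeric(0),
                         targets = integer(0))),
               us_stim_w = 0)
  })
  raw <- engine_run(prep$spec, state, stim, 1L, as.integer(duration_ms),
                    derive_seed(seed, "noise"), 0L, FALSE)
  spikes <- spikes_to_dt(raw, prep)
  population_rates(spikes, prep, c(settle_ms, duration_ms),
                   by_module = by_module)
}

#' Run a full CEBC experiment
#'
#' Runs `n_seeds` independent simulations of `n_blocks` x
#' `trials_per_block` CS-US trials under a lesion configuration, decoding
#' the motor output of every trial and snapshotting the plastic weights
#' once per block.
#'
#' @param network a wired `cereb_network` (or a [network_config()], which
#'   is then built and wired with defaults).
#' @param protocol a [protocol_config()].
#' @param lesion one of `"control"`, `"ltd_ko"`, `"mli_ko"`, `"double_ko"`.
#' @param plasticity base [plasticity_params()] before lesion gating.
#' @param control_max maximum motor amplitude of the control simulations,
#'   required to normalize knock-out runs; `NULL` is only valid for
#'   `lesion = "control"`, where it is computed from the run itself.
#' @param keep_spike_blocks block indices whose spikes are retained in the
#'   result (default first and last).
#' @param n_seeds,n_blocks optional overrides of the protocol values.
#' @param weight_multipliers passed to [engine_prep()].
#' @param us_stim_w,cio_stim_w stimulation conductances (nS) at the olive.
#' @param progress print a line per block.
#' @return A `cebc_experiment` object: conditioned-response table (`$cr`),
#'   normalized motor traces (`$motor`, one matrix per seed), per-block
#'   weight snapshots (`$weights`), retained spikes (`$spikes`), baseline
#'   rates of the first trial (`$baseline`), and the normalization constant
#'   (`$control_max`).
#' @export
run_experiment <- function(network, protocol = protocol_config(),
                           lesion = "control",
                           plasticity = plasticity_params(),
                           control_max = NULL,
                           keep_spike_blocks = NULL,
                           n_seeds = NULL, n_blocks = NULL,
                           weight_multipliers = NULL,
                           us_stim_w = 30, cio_stim_w = 18,
                           progress = FALSE) {
  if (inherits(network, "network_config"))
    network <- generate_connectivity(build_network(network))
  stopifnot(inherits(network, "cereb_network"), !is.null(network$synapses))
  if (is.null(control_max) && lesion != "control")
    stop("knock-out runs need the control simulations' maximum motor ",
         "amplitude (control_max)")
  gated <- plasticity_gate(lesion, plasticity)
  if (is.null(n_seeds)) n_seeds <- protocol$n_seeds
  if (is.null(n_blocks)) n_blocks <- protocol$n_blocks
  tpb <- protocol$trials_per_block
  total_trials <- n_blocks * tpb
  if (is.null(keep_spike_blocks)) keep_spike_blocks <- c(1L, n_blocks)
  Tms <- protocol$trial_len_ms

  prep <- engine_prep(network, plasticity = gated,
                      weight_multipliers = weight_multipliers)
  nt <- prep$meta$neurons
  dcn_down <- nt[population == "DCN_p" & module == "downbound", id]
  dcn_up <- nt[population == "DCN_p" & module == "upbound", id]
  io_down <- nt[population == "IO" & module == "downbound", id]
  pl_rows <- prep$meta$plastic_rows

  master <- network$config$seed
  seed_list <- vapply(seq_len(n_seeds),
                      function(i) derive_seed(master, paste0("run", i)),
                      integer(1))

  motor_raw <- vector("list", n_seeds)
  weights <- vector("list", n_seeds)
  spikes_kept <- vector("list", n_seeds)
  baseline <- vector("list", n_seeds)
  cio_flags <- vector("list", n_seeds)

  for (si in seq_len(n_seeds)) {
    run_seed <- seed_list[si]
    state <- engine_state(prep, seed = run_seed)
    n_cio <- max(1L, round(protocol$cio_fraction * length(io_down)))
    cio_targets <- with_seed(derive_seed(run_seed, "cio_targets"),
                             sort(sample(io_down, n_cio)))
    motor_raw[[si]] <- matrix(NA_real_, nrow = total_trials, ncol = Tms)
    weights[[si]] <- matrix(NA_real_, nrow = n_blocks,
                            ncol = length(pl_rows))
    spikes_kept[[si]] <- list()
    cio_flags[[si]] <- logical(total_trials)

    for (b in seq_len(n_blocks)) {
      offset <- (b - 1L) * tpb
      stim_seed <- derive_seed(run_seed, paste0("stim_b", b))
      blk <- with_seed(stim_seed, {
        trains <- lapply(seq_len(tpb), function(k)
          generate_cs_events(protocol, network))
        cio <- lapply(seq_len(tpb), function(k) {
          d <- schedule_cio(offset + k - 1L, total_trials, protocol)
          d$targets <- cio_targets
          d
        })
        list(trains = trains, cio = cio)
      })
      stim <- build_stim(prep, protocol, blk$trains, blk$cio,
                         us_stim_w = us_stim_w, cio_stim_w = cio_stim_w)
      raw <- engine_run(prep$spec, state, stim, tpb, Tms,
                        derive_seed(run_seed, "noise"), offset, TRUE)
      sp <- spikes_to_dt(raw, prep, trial_offset = offset)
      cio_flags[[si]][offset + seq_len(tpb)] <-
        vapply(blk$cio, function(d) isTRUE(d$occurred), logical(1))

      # decode the whole block as one continuous stream (trials are
      # contiguous in engine time), then slice per trial: identical
      # filtering without per-trial edge effects
      dcn <- sp[population == "DCN_p"]
      gt_down <- (dcn[module == "downbound", trial] - 1L - offset) * Tms +
        dcn[module == "downbound", time]
      gt_up <- (dcn[module == "upbound", trial] - 1L - offset) * Tms +
        dcn[module == "upbound", time]
      net_blk <- decode_stream(gt_down, gt_up, length(dcn_down),
                               length(dcn_up), tpb * Tms)
      for (k in seq_len(tpb)) {
        seg <- net_blk[((k - 1L) * Tms + 1L):(k * Tms)]
        motor_raw[[si]][offset + k, ] <-
          seg - mean(seg[seq_len(protocol$baseline_ms)])
      }
      if (b == 1L && si == 1L)
        baseline[[si]] <- population_rates(
          sp[trial == 1L], prep, c(0, protocol$baseline_ms),
          by_module = TRUE)
      weights[[si]][b, ] <- state$syn_w[pl_rows]
      if (b %in% keep_spike_blocks)
        spikes_kept[[si]][[as.character(b)]] <- sp
      if (progress)
        cat(sprintf("[%s seed %d] block %d/%d done\n", lesion, si, b,
                    n_blocks))
    }
  }

  if (is.null(control_max))
    control_max <- max(vapply(motor_raw, max, numeric(1)))
  if (control_max <= 0) stop("control maximum motor amplitude must be > 0")

  # vectorized CR scoring; same semantics as compute_cr_threshold/detect_cr
  cr <- data.table::rbindlist(lapply(seq_len(n_seeds), function(si) {
    m <- motor_raw[[si]] / control_max
    base <- m[, seq_len(protocol$baseline_ms), drop = FALSE]
    th <- pmax(0.2, rowMeans(base) + 2.5 * apply(base, 1, sd))
    w0 <- protocol$cs_onset_ms + protocol$isi - 200
    win <- (w0 + 1L):(protocol$cs_onset_ms + protocol$isi)
    onset <- rep(NA_real_, total_trials)
    peak <- onset; pamp <- onset
    is_cr <- logical(total_trials)
    for (tr in seq_len(total_trials)) {
      above <- which(m[tr, win] >= th[tr])
      if (length(above)) {
        is_cr[tr] <- TRUE
        oi <- win[above[1]]
        seg <- oi:ncol(m)
        pi <- seg[which.max(m[tr, seg])]
        onset[tr] <- (oi - 1L) - protocol$cs_onset_ms
        peak[tr] <- (pi - 1L) - protocol$cs_onset_ms
        pamp[tr] <- m[tr, pi]
      }
    }
    data.table::data.table(
      seed = si, trial = seq_len(total_trials),
      block = (seq_len(total_trials) - 1L) %/% tpb + 1L,
      is_cr = is_cr, threshold = th, onset_ms = onset, peak_ms = peak,
      peak_amplitude = pamp, cio = cio_flags[[si]])
  }))

  pm <- data.table::data.table(
    row = pl_rows,
    type = prep$meta$syn_type[pl_rows],
    site = c("", "pf-PC", "pf-MLI")[plastic_site_of(
      prep$meta$syn_type[pl_rows]) + 1L],
    post = prep$meta$syn_post1[pl_rows],
    post_module = nt$module[prep$meta$syn_post1[pl_rows]],
    post_pref = nt$pref[prep$meta$syn_post1[pl_rows]],
    w_init = prep$meta$w_init[pl_rows])

  structure(list(
    lesion = lesion, protocol = protocol, n_seeds = n_seeds,
    n_blocks = n_blocks, seeds = seed_list,
    motor = lapply(motor_raw, function(m) m / control_max),
    control_max = control_max,
    cr = cr, weights = weights, plastic_meta = pm,
    spikes = spikes_kept, baseline = baseline[[1]],
    scale = network$config$scale_factor
  ), class = "cebc_experiment")
}

#' @export
print.cebc_experiment <- function(x, ...) {
  lc <- learning_curve(x$cr)
  cat("<cebc_experiment>", x$lesion, "-", x$n_seeds, "seed(s),",
      x$n_blocks, "blocks\n")
  cat("last-block %CR:", round(lc$pct_cr[nrow(lc)], 1), "\n")
  invisible(x)
}
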