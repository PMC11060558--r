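# CEBC stimulus schedules and the trial engine contracts.

test_that("trial timeline arithmetic follows the protocol", {
  pr <- protocol_config()
  expect_identical(pr$trial_len_ms, 1260)
  expect_identical(pr$cs_onset_ms, 500)
  expect_identical(pr$us_onset_ms, 750)
  expect_identical(pr$cr_window_ms, c(550, 750))
  # shorter inter-stimulus interval shifts the co-terminating US
  pr200 <- protocol_config(isi = 200)
  expect_identical(pr200$us_onset_ms, 700)
  expect_identical(pr200$cs_duration_ms, 210)
  pr300 <- protocol_config(isi = 300)
  expect_identical(pr300$us_onset_ms, 800)
  expect_error(protocol_config(isi = 80), "cio_latency")
})

test_that("US is a regular 500-Hz burst co-terminating with the CS", {
  us <- generate_us(protocol_config())
  expect_identical(us, c(750, 752, 754, 756, 758))   # 5 spikes in 10 ms
  us200 <- generate_us(protocol_config(isi = 200))
  expect_true(all(us200 >= 700 & us200 < 710))
})

test_that("CS targets the central mossy-fibre subset at the right rate", {
  net <- small_network()
  pr <- protocol_config()
  mf <- net$neurons[population == "mf"]
  expect_identical(sum(mf$cs_target), 45L)
  # targeted fibres carry ~ 10 Hz x 0.26 s = 2.6 extra spikes in the CS
  # window; non-targeted fibres only background
  set.seed(5)
  n_rep <- 300
  cs_in_window <- function(ids) {
    tot <- 0
    for (r in seq_len(n_rep)) {
      tr <- generate_cs(pr, net)
      tot <- tot + sum(vapply(as.character(ids), function(i)
        sum(tr[[i]] >= 500 & tr[[i]] < 760), numeric(1)))
    }
    tot / n_rep / length(ids)
  }
  tgt <- cs_in_window(mf$id[mf$cs_target][1:10])
  non <- cs_in_window(mf$id[!mf$cs_target][1:10])
  lambda_bg <- 1 * 0.26
  expect_equal(tgt, 2.6 + lambda_bg, tolerance = 3 * sqrt(2.86 / (10 * n_rep)) / 2.86)
  expect_lt(non, 0.6)
  # zero-rate configuration produces background-only trains
  pr0 <- protocol_config(cs_rate_hz = 0)
  pr0$bg_rate_hz <- 0
  tr0 <- generate_cs(pr0, net)
  expect_true(all(lengths(tr0) == 0))
})

test_that("CIO probability ramps linearly to its maximum", {
  pr <- protocol_config()
  set.seed(1)
  expect_equal(schedule_cio(999, 1000, pr)$p, 0.43)
  expect_equal(schedule_cio(0, 1000, pr)$p, 0.00043)
  expect_equal(schedule_cio(499, 1000, pr)$p, 0.215)
  d <- schedule_cio(999, 1000, pr)
  if (d$occurred)
    expect_true(all(d$times >= 588 & d$times < 598))
  # empirical occurrence at the end of learning
  set.seed(2)
  occ <- mean(vapply(1:2000, function(i)
    schedule_cio(999, 1000, pr)$occurred, logical(1)))
  expect_equal(occ, 0.43, tolerance = 0.1)
})

test_that("a trial is bit-reproducible for a fixed seed and state", {
  net <- small_network()
  prep <- engine_prep(net)
  pr <- protocol_config()
  s1 <- engine_state(prep, seed = 3)
  a <- run_trial(prep, s1, pr, seed = 99)
  s2 <- engine_state(prep, seed = 3)
  b <- run_trial(prep, s2, pr, seed = 99)
  expect_identical(a, b)
  expect_identical(s1$V, s2$V)
  s3 <- engine_state(prep, seed = 3)
  c <- run_trial(prep, s3, pr, seed = 100)
  expect_false(identical(a, c))
})

test_that("US drives only the downbound olive and evokes complex spikes", {
  net <- small_network()
  prep <- engine_prep(net)
  pr <- protocol_config()
  state <- engine_state(prep, seed = 1)
  hit_io <- 0; hit_pc <- 0; n_tr <- 10
  nio <- nrow(net$neurons[population == "IO" & module == "downbound"])
  npc <- nrow(net$neurons[population == "PC" & module == "downbound"])
  for (i in seq_len(n_tr)) {
    sp <- run_trial(prep, state, pr, trial_index = i - 1L,
                    total_trials = n_tr, seed = 40 + i, plastic_on = FALSE)
    io_up <- sp[population == "IO" & module == "upbound" &
                  time >= 750 & time < 765]
    expect_lte(nrow(io_up), 1)    # at most chance-level background
    io_dn <- sp[population == "IO" & module == "downbound" &
                  time >= 750 & time < 765]
    hit_io <- hit_io + (length(unique(io_dn$neuron)) >= 0.9 * nio)
    pc <- sp[population == "PC" & module == "downbound" &
               time >= 752 & time < 775]
    bursts <- pc[, .N, by = neuron]
    hit_pc <- hit_pc + (nrow(bursts[N >= 2]) >= 0.9 * npc)
  }
  expect_gte(hit_io, 9)           # >= 90% of trials
  expect_gte(hit_pc, 9)
})

test_that("with all plasticity rates zero the weights never change", {
  net <- small_network()
  zero <- plasticity_params(LTP_PC = 0, LTD_PC = 0, LTP_MLI = 0,
                            LTD_MLI = 0)
  prep <- engine_prep(net, plasticity = zero)
  pr <- protocol_config()
  state <- engine_state(prep, seed = 1)
  w0 <- state$syn_w + 0          # force a copy: the engine updates in place
  for (i in 0:2)
    run_trial(prep, state, pr, trial_index = i, total_trials = 3,
              seed = 7 + i, plastic_on = TRUE)
  expect_identical(state$syn_w, w0)
})

test_that("the MLI-output lesion zeroes molecular-layer inhibition of PCs", {
  net <- small_network()
  prep <- engine_prep(net, plasticity = plasticity_gate("mli_ko"))
  w <- prep$meta$w_signed
  tp <- prep$meta$syn_type
  expect_true(all(w[tp %in% c("SC-PC", "BC-PC")] == 0))
  expect_true(all(w[tp == "GrC_pf-PC"] > 0))
})

test_that("olivary feedback from DCN_GABA damps the conditioned response input", {
  # same CIO burst with and without the nucleo-olivary loop: the intact
  # loop yields fewer evoked olivary spikes
  net <- small_network()
  pr <- protocol_config()
  count_io <- function(mult) {
    prep <- engine_prep(net, weight_multipliers = mult)
    state <- engine_state(prep, seed = 2)
    nt <- net$neurons
    cio_t <- nt[population == "IO" & module == "downbound", id]
    tot <- 0
    for (i in 1:8) {
      sp <- run_trial(prep, state, pr, trial_index = 999L,
                      total_trials = 1000L, cio_targets = cio_t,
                      seed = 500 + i, plastic_on = FALSE)
      tot <- tot + nrow(sp[population == "IO" & module == "downbound" &
                             time >= 588 & time < 605])
    }
    tot
  }
  with_loop <- count_io(NULL)
  without_loop <- count_io(list("DCN_GABA-IO" = 0))
  expect_lt(with_loop, without_loop)
})
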