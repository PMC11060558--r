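# E-GLIF point-neuron dynamics: printed Purkinje anchors, f-I monotonicity,
# rebound and burst-pause signatures, relay units.

test_that("Purkinje endogenous-current anchors reproduce the tonic rates", {
  p <- olivosim:::neuron_params_for("PC")
  expect_equal(tonic_rate(p, drive = 176.3, duration = 10), 39,
               tolerance = 1 / 39)           # 39 +/- 1 Hz
  expect_equal(tonic_rate(p, drive = 742.54, duration = 10), 86,
               tolerance = 1 / 86)           # 86 +/- 1 Hz
})

test_that("tonic rate is non-decreasing in the drive", {
  p <- olivosim:::neuron_params_for("PC")
  rates <- vapply(seq(0, 1000, by = 50),
                  function(ie) tonic_rate(p, drive = ie, duration = 5),
                  numeric(1))
  expect_true(all(diff(rates) >= -0.2))      # sweep at 50 pA steps
})

test_that("a silent cell stays silent without drive", {
  g <- olivosim:::neuron_params_for("GrC")
  expect_identical(tonic_rate(g, drive = 0, duration = 5), 0)
  # V at rest with no input: step never spikes
  st <- neuron_state(g, V = g$E_L)
  out <- step_neuron(st, g, synaptic_current = 0)
  expect_false(out$spiked)
  expect_equal(out$state$V, g$E_L)
})

test_that("step_neuron rejects non-finite input current", {
  p <- olivosim:::neuron_params_for("PC")
  st <- neuron_state(p)
  expect_error(step_neuron(st, p, synaptic_current = NaN), "non-finite")
  expect_error(step_neuron(st, p, synaptic_current = Inf), "non-finite")
})

test_that("R reference stepper matches the compiled tonic counter", {
  for (pop in c("PC", "GoC", "DCN_p")) {
    p <- olivosim:::neuron_params_for(pop)
    p$noise_sd <- 0
    n_steps <- 2000L
    st <- neuron_state(p)
    count <- 0L
    for (i in seq_len(n_steps)) {
      out <- step_neuron(st, p, synaptic_current = 0)
      st <- out$state
      count <- count + out$spiked
    }
    expect_identical(count,
                     olivosim:::egif_tonic_count(
                       p$C, p$tau_m, p$E_L, p$V_th, p$V_r, p$t_ref, p$Ie,
                       p$k_adap, p$k2, p$k1, p$A1, p$A2, n_steps, 1),
                     label = paste("spike count of", pop))
  }
})

test_that("hyperpolarizing pulses evoke rebound firing in nuclear cells", {
  p <- olivosim:::neuron_params_for("DCN_p")
  p$noise_sd <- 0
  run <- function(pulse) {
    st <- neuron_state(p)
    spikes <- integer(0)
    for (t in 1:1500) {
      I <- if (pulse && t > 1000 && t <= 1200) -3000 else 0
      out <- step_neuron(st, p, synaptic_current = I)
      st <- out$state
      if (out$spiked) spikes <- c(spikes, t)
    }
    spikes
  }
  sp <- run(TRUE)
  pre <- sum(sp > 900 & sp <= 1000)
  during <- sum(sp > 1000 & sp <= 1200)
  post <- sum(sp > 1200 & sp <= 1300)
  expect_lt(during / 2, pre)                # pulse silences the cell
  expect_gt(post, pre)                      # rebound above the pre-pulse rate
})

test_that("strong brief input to a Purkinje cell gives burst then pause", {
  p <- olivosim:::neuron_params_for("PC")
  p$Ie <- 742.54
  p$noise_sd <- 0
  st <- neuron_state(p)
  spikes <- integer(0)
  for (t in 1:1200) {
    I <- if (t > 1000 && t <= 1004) 8000 else 0
    out <- step_neuron(st, p, synaptic_current = I)
    st <- out$state
    if (out$spiked) spikes <- c(spikes, t)
  }
  base_rate <- sum(spikes <= 1000) / 1000   # spikes per ms
  burst <- sum(spikes > 1000 & spikes <= 1020)
  pause <- sum(spikes > 1020 & spikes <= 1080)
  expect_gt(burst, base_rate * 20)          # above baseline expectation
  expect_lt(pause, base_rate * 60)          # below baseline expectation
})

test_that("relay units transmit spike trains unchanged", {
  expect_identical(relay(numeric(0)), numeric(0))
  expect_identical(relay(c(10, 20, 30)), c(10, 20, 30))
  train <- sort(runif(1000, 0, 1e4))
  expect_identical(relay(train), train)
  expect_error(relay(c(3, 1, 2)), "sorted")
})
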