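# Alpha conductances and the climbing-fibre-supervised plasticity rules.

test_that("alpha conductance has the normalized alpha form", {
  expect_identical(alpha_conductance(0, weight = 2, tau_syn = 5), 0)
  expect_equal(alpha_conductance(5, weight = 2, tau_syn = 5), 2)
  # hand evaluation at t = 2 tau: 2 e^-1
  expect_equal(alpha_conductance(10, weight = 1, tau_syn = 5),
               2 * exp(-1), tolerance = 1e-12)
  expect_error(alpha_conductance(-1, 1, 5), "t >= 0")
  # superposition over spikes is additive
  g2 <- alpha_conductance(7, 1, 5) + alpha_conductance(3, 1, 5)
  expect_equal(g2, sum(vapply(c(7, 3), alpha_conductance, 0,
                              weight = 1, tau_syn = 5)))
})

test_that("the pf-MLI kernel is the unit-peak alpha function", {
  expect_identical(mli_kernel(0), 0)
  expect_identical(mli_kernel(-3), 0)
  expect_equal(mli_kernel(50), 1)
  expect_equal(mli_kernel(100), 2 * exp(-1), tolerance = 1e-12)
  # positivity and a single maximum at t = tau, on the 1-ms grid
  k <- mli_kernel(0:600, tau = 50)
  expect_true(all(k >= 0))
  expect_identical(which.max(k), 51L)
  expect_true(all(diff(k[1:51]) > 0) && all(diff(k[51:601]) < 0))
})

test_that("pf-MLI updates follow the printed branch rules", {
  pp <- plasticity_params(LTP_MLI = 1, LTD_MLI = 0.25)
  # silent pf: no change at all
  ev <- pf_mli_update(numeric(0), c(100), pp)
  expect_identical(attr(ev, "total_dw"), 0)
  # pf spike without any cf: one LTD step
  ev <- pf_mli_update(c(80), numeric(0), pp)
  expect_equal(attr(ev, "total_dw"), -0.25)
  # pf spike exactly tau before the cf spike: LTP of K(tau) = 1
  ev <- pf_mli_update(c(700), c(750), pp)
  expect_equal(attr(ev, "total_dw"), 1 - 0.25)
  # coincident pf spike: neither LTD nor a kernel contribution (K(0)=0)
  ev <- pf_mli_update(c(750), c(750), pp)
  expect_equal(attr(ev, "total_dw"), 0)
  expect_error(pf_mli_update(c(3, 1), c(10), pp), "sorted")
})

test_that("pf-PC updates mirror the MLI rule with reversed signs", {
  pp <- plasticity_params(LTP_PC = 0.5, LTD_PC = 2)
  expect_identical(attr(pf_pc_update(numeric(0), c(10), pp), "total_dw"), 0)
  expect_equal(attr(pf_pc_update(c(5), numeric(0), pp), "total_dw"), 0.5)
  ev <- pf_pc_update(c(700), c(750), pp)   # kernel peak lag
  expect_equal(attr(ev, "total_dw"), -2 * 1 + 0.5)
})

test_that("rule updates equal the brute-force convolution oracle", {
  set.seed(42)
  pp <- plasticity_params(LTP_MLI = 0.7, LTD_MLI = 0, LTD_PC = 1.3,
                          LTP_PC = 0)
  for (rep in 1:20) {
    pf <- sort(round(runif(rpois(1, 40), 0, 1200)))
    cf <- sort(round(runif(rpois(1, 5), 0, 1200)))
    oracle <- sum(brute_kernel_sum(pf, cf, tau = 50))
    expect_equal(attr(pf_mli_update(pf, cf, pp), "total_dw"),
                 0.7 * oracle, tolerance = 1e-12)
    expect_equal(attr(pf_pc_update(pf, cf, pp), "total_dw"),
                 -1.3 * oracle, tolerance = 1e-12)
  }
})

test_that("paired stimulation moves the two sites in opposite directions", {
  pp <- plasticity_params()
  pf <- seq(600, 740, by = 20)
  cf <- 750
  pc_paired <- attr(pf_pc_update(pf, cf, pp), "total_dw")
  pc_alone <- attr(pf_pc_update(pf, numeric(0), pp), "total_dw")
  mli_paired <- attr(pf_mli_update(pf, cf, pp), "total_dw")
  mli_alone <- attr(pf_mli_update(pf, numeric(0), pp), "total_dw")
  expect_lt(pc_paired, pc_alone)
  expect_gt(mli_paired, mli_alone)
})

test_that("lesion gating switches off the right rules", {
  base <- plasticity_params()
  expect_identical(plasticity_gate("control", base)[names(base)], base[names(base)])
  ko <- plasticity_gate("ltd_ko", base)
  expect_identical(ko$LTD_PC, 0)
  expect_identical(ko$LTP_PC, base$LTP_PC)
  expect_false(ko$disconnect_mli)
  expect_true(plasticity_gate("mli_ko", base)$disconnect_mli)
  dbl <- plasticity_gate("double_ko", base)
  expect_identical(dbl$LTD_PC, 0)
  expect_true(dbl$disconnect_mli)
  expect_error(plasticity_gate("no_such"), "unknown lesion")
})
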