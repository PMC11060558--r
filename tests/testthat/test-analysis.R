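# Spike density functions, spike sorting, modulation quantification and the
# derived summaries.

test_that("SDF matches a brute-force Gaussian sum to 1e-9 relative error", {
  set.seed(3)
  grid <- seq(0, 1259)
  for (rep in 1:5) {
    spk <- runif(rpois(1, 60), 0, 1260)
    got <- compute_sdf(spk, kernel_width_ms = 41, grid = grid)
    oracle <- vapply(grid, function(t)
      1000 * sum(exp(-(t - spk)^2 / (2 * 41^2)) / (41 * sqrt(2 * pi))),
      numeric(1))
    expect_lt(max(abs(got$sdf - oracle)) / max(oracle), 1e-9)
  }
})

test_that("SDF peak and mass follow the kernel normalization", {
  expect_identical(compute_sdf(numeric(0), 10)$sdf, rep(0, 1260))
  s <- compute_sdf(600, kernel_width_ms = 10)
  expect_equal(max(s$sdf), 1000 / (10 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(s$grid[which.max(s$sdf)], 600)
  # integral over the grid ~ spike count (1-ms bins, kernel well inside)
  s2 <- compute_sdf(c(300, 600, 900), 41)
  expect_equal(sum(s2$sdf) / 1000, 3, tolerance = 1e-6)
})

test_that("complex spikes are maximal fast runs replaced by one spike", {
  # baseline 100 Hz -> burst threshold at ISI < 5 ms
  train <- c(seq(10, 100, by = 10), 103, 105, seq(120, 160, by = 10))
  out <- separate_ss_cs(train, baseline_rate = 100)
  expect_identical(out$cs_times, 100)        # triplet 100,103,105
  expect_true(100 %in% out$ss_times)
  expect_false(any(c(103, 105) %in% out$ss_times))
  # conservation: |SS| + sum(run lengths - 1) = original count
  expect_identical(length(out$ss_times) + 2L, length(train))

  # a regular train at baseline rate has no complex spikes
  reg <- seq(0, 1000, by = 10)
  out2 <- separate_ss_cs(reg, baseline_rate = 100)
  expect_identical(length(out2$cs_times), 0L)
  expect_identical(out2$ss_times, reg)
  expect_identical(separate_ss_cs(numeric(0), 50)$cs_times, numeric(0))
})

test_that("event conservation holds on random bursty trains", {
  set.seed(11)
  for (rep in 1:20) {
    base <- sort(runif(60, 0, 2000))
    bursts <- unlist(lapply(sample(base, 5), function(t) t + c(1, 2)))
    train <- sort(c(base, bursts))
    out <- separate_ss_cs(train, baseline_rate = 60)
    runs <- length(train) - length(out$ss_times)
    expect_identical(length(out$ss_times) + runs, length(train))
    expect_true(all(out$cs_times %in% train))
  }
})

test_that("suppression and facilitation average the strict deviation sets", {
  mk <- function(vals, base) {
    s <- compute_sdf(numeric(0), 10, grid = seq(0, 999), baseline_ms = 500)
    s$sdf <- vals
    s$sdf_baseline <- base
    s
  }
  flat <- mk(rep(50, 1000), 50)
  m <- compute_modulation(flat, c(500, 700))
  expect_identical(m$suppression, 0)
  expect_identical(m$facilitation, 0)

  v <- rep(50, 1000); v[501:700] <- 40          # 0.8 x baseline
  m2 <- compute_modulation(mk(v, 50), c(500, 700))
  expect_equal(m2$suppression, -20)
  expect_identical(m2$facilitation, 0)
  expect_identical(m2$Ns, 200L)

  v[501:600] <- 40; v[601:700] <- 65            # half 0.8x, half 1.3x
  m3 <- compute_modulation(mk(v, 50), c(500, 700))
  expect_equal(m3$suppression, -20)
  expect_equal(m3$facilitation, 30)
  expect_identical(c(m3$Ns, m3$Nf), c(100L, 100L))

  # ~0 baseline: undefined, flagged
  m4 <- compute_modulation(mk(rep(0.5, 1000), 0), c(500, 700))
  expect_false(m4$defined)
})

test_that("significance requires strictly exceeding baseline deviation", {
  mod <- list(suppression = -20, facilitation = 0, defined = TRUE)
  base5 <- list(suppression = -5, facilitation = 2, defined = TRUE)
  expect_true(flag_significant(mod, base5))
  equal <- list(suppression = -20, facilitation = 0, defined = TRUE)
  expect_false(flag_significant(equal, equal))     # strict inequality
  none <- list(suppression = 0, facilitation = 0, defined = TRUE)
  expect_false(flag_significant(none, base5))
})

test_that("recruitment is the percentage of significant traces", {
  mods <- c(
    replicate(7, list(list(defined = TRUE, significant = TRUE,
                           suppression = -10, facilitation = 1))),
    replicate(3, list(list(defined = TRUE, significant = FALSE,
                           suppression = -1, facilitation = 0))))
  r <- recruitment(mods)
  expect_equal(r$pct_significant, 70)
  expect_equal(r$pct_suppressing, 70)
  expect_error(recruitment(list()), "no defined")
})

test_that("plasticity curves weight mean change by the changed fraction", {
  w0 <- rep(1, 10)
  snap <- rbind(rep(1, 10),                       # block 1: no change
                c(rep(0.9, 5), rep(1.2, 5)))      # block 2: half LTD/LTP
  pc <- plasticity_curves(snap, w0)
  expect_equal(pc$ltd, c(0, -5))
  expect_equal(pc$ltp, c(0, 10))
  snap3 <- rbind(rep(0.9, 10))
  expect_equal(plasticity_curves(snap3, w0)$ltd, -10)
})

test_that("SDF minimum-time histograms and their squared distance", {
  mk <- function(tmin) {
    s <- compute_sdf(numeric(0), 10, grid = seq(0, 999))
    s$sdf <- rep(10, 1000)
    s$sdf[tmin + 1] <- 1
    s
  }
  h1 <- sdf_min_time_distribution(lapply(c(605, 605, 605), mk), c(600, 700),
                                  bin_ms = 10)
  expect_equal(sum(h1$prob), 1)
  expect_equal(max(h1$prob), 1)                   # point mass
  h2 <- sdf_min_time_distribution(lapply(c(615, 615, 615), mk), c(600, 700),
                                  bin_ms = 10)
  expect_equal(histogram_sq_distance(h1$prob, h1$prob), 0)
  # two-bin shift: sum((1-0)^2 + (0-1)^2) = 2
  expect_equal(histogram_sq_distance(h1$prob, h2$prob), 2)
})

test_that("a planted rate dip is recovered by the modulation pipeline", {
  # inhomogeneous Poisson: 60 Hz baseline, -20% in the CR window; the
  # per-trial SDFs are averaged over 100 trials (as for the population
  # traces) before the deviation formulas are applied
  set.seed(21)
  n_tr <- 1000                    # 100 trials for each of 10 cells
  acc <- numeric(1260)
  for (i in seq_len(n_tr)) {
    rate <- rep(60, 1260)
    rate[551:750] <- 48
    spk <- which(runif(1260) < rate / 1000) - 1
    acc <- acc + compute_sdf(spk, 10, baseline_ms = 500)$sdf
  }
  avg <- compute_sdf(numeric(0), 10, baseline_ms = 500)
  avg$sdf <- acc / n_tr
  avg$sdf_baseline <- mean(avg$sdf[1:500])
  m <- compute_modulation(avg, c(550, 750))
  est <- (m$suppression * m$Ns + m$facilitation * m$Nf) / (m$Ns + m$Nf)
  expect_equal(est, -20, tolerance = 3 / 20)          # within +/- 3 points
})
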