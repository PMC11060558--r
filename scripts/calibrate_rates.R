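#!/usr/bin/env Rscript
# Learning-rate calibration recipe.
#
# The four learning rates (LTP_PC, LTD_PC, LTP_MLI, LTD_MLI) are free
# parameters. The shipped defaults were obtained by tuning against the
# reference end-of-learning firing modulation (downbound PC-SS suppression
# ~ -14%, MLI facilitation, DCN_p facilitation) and the shape of the %CR
# learning curve, directly at the full 10x100-trial protocol.
#
# A short-sequence variant (tune on ~20 trials, then divide the rates by
# 50 to stretch to 1000 trials) is also provided (--short); with bounded
# weights it is only a coarse starting point, because rates that produce
# end-of-learning modulation within 20 trials drive many synapses to their
# bounds almost immediately, and the linear extrapolation then overshoots.
#
# Usage:
#   Rscript scripts/calibrate_rates.R [--short] [--scale S] [--seed N] \
#       [LTP_PC LTD_PC LTP_MLI LTD_MLI]
#
# Prints the modulation summary and last-block %CR for the candidate
# rates; iterate by hand toward the targets, then ship the winners as the
# plasticity_params() defaults.

suppressMessages(library(olivosim))

args <- commandArgs(trailingOnly = TRUE)
short <- "--short" %in% args
args <- setdiff(args, "--short")
get_opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1) {
    v <- args[i + 1]
    args <<- args[-c(i, i + 1)]
    as.numeric(v)
  } else default
}
scale <- get_opt("--scale", 0.1)
seed <- as.integer(get_opt("--seed", 1))
rr <- if (length(args) >= 4) as.numeric(args[1:4]) else {
  d <- plasticity_params()
  c(d$LTP_PC, d$LTD_PC, d$LTP_MLI, d$LTD_MLI) * (if (short) 50 else 1)
}
cat("candidate rates:", rr, if (short) "(20-trial short form)" else "", "\n")

net <- generate_connectivity(build_network(
  network_config(scale_factor = scale, seed = seed)))
pr <- if (short) protocol_config(trials_per_block = 20, n_blocks = 1,
                                 n_seeds = 1)
      else protocol_config()
ex <- run_experiment(net, pr, "control",
                     plasticity = plasticity_params(rr[1], rr[2], rr[3], rr[4]),
                     n_seeds = 1, progress = TRUE)

print(learning_curve(ex$cr))
show <- function(pop, mod, dir) {
  mods <- analyse_modulation(ex, pop, mod)
  sig <- Filter(function(m) isTRUE(m$significant), mods)
  v <- vapply(sig, `[[`, numeric(1),
              if (dir == "sup") "suppression" else "facilitation")
  cat(sprintf("%-6s %-10s significant %4d/%4d  mean %s %7.1f%%\n",
              pop, mod, length(sig), length(mods), dir,
              if (length(v)) mean(v) else NA))
}
show("PC", "downbound", "sup")
show("PC", "upbound", "fac")
show("MLI", "downbound", "fac")
show("MLI", "upbound", "sup")
show("DCN_p", "downbound", "fac")
cat("targets: PC down ~ -14%, MLI down-pref strongly facilitating,\n",
    "DCN_p down facilitating; last-block %CR ~ 81 in control\n")
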