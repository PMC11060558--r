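# Shared small fixtures, built once per test run.

small_network <- local({
  net <- NULL
  function() {
    if (is.null(net))
      net <<- suppressWarnings(generate_connectivity(
        build_network(network_config(scale_factor = 0.05, seed = 7))))
    net
  }
})

# brute-force alpha-kernel convolution sum: direct double loop over all
# pf/cf spike pairs (independent oracle for the trace-based implementation)
brute_kernel_sum <- function(pf, cf, tau) {
  vapply(cf, function(tc) {
    lags <- tc - pf[pf <= tc]
    sum((lags / tau) * exp(1 - lags / tau))
  }, numeric(1))
}
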