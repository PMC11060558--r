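# Network construction: population counts, micromodule split, the 24
# connection types, confinement and reproducibility.

test_that("full-scale network has the canonical population counts", {
  cfg <- network_config(scale_factor = 1, seed = 1)
  cortex <- sum(cfg$sizes[c("GrC", "GoC", "PC", "SC", "BC")])
  expect_identical(cortex, 29230L)
  expect_identical(cfg$sizes[["mf"]], 117L)
  expect_identical(cfg$mf_cs_target_count, 45L)
  # 70/30 micromodule split of the Purkinje population
  expect_identical(cfg$module_sizes$PC[["downbound"]],
                   as.integer(round(0.7 * 99)))
})

test_that("scaled counts follow the documented scaling rule", {
  cfg <- network_config(scale_factor = 0.09, seed = 1)
  expect_identical(cfg$sizes[["GrC"]], as.integer(round(0.09 * 28615)))
  for (p in c("GoC", "PC", "SC", "BC"))
    expect_identical(cfg$sizes[[p]],
                     as.integer(round(sqrt(0.09) * default_population_sizes()[[p]])))
  # deep populations and relays are held at full size by default
  expect_identical(cfg$sizes[["DCN_p"]], 96L)
  expect_identical(cfg$sizes[["mf"]], 117L)
  # downbound fraction preserved within rounding
  ms <- cfg$module_sizes$PC
  expect_equal(ms[["downbound"]] / sum(ms), 0.7, tolerance = 0.05)
})

test_that("tiny scales that empty a population raise a named error", {
  expect_error(network_config(scale_factor = 1e-5), "empty population")
  # a surviving population whose upbound micromodule empties is also caught
  expect_error(network_config(scale_factor = 1e-4), "empty micromodule")
  small <- default_population_sizes()
  small["PC"] <- 5L   # scales to a single Purkinje cell
  expect_error(network_config(scale_factor = 0.04,
                              population_sizes = small),
               "empty micromodule")
})

test_that("wiring realizes exactly 15 cortical and 9 extracortical types", {
  net <- small_network()
  specs <- default_connection_specs()
  expect_identical(nrow(specs), 24L)
  expect_identical(sum(specs$group == "cortical"), 15L)
  expect_identical(sum(specs$group == "extracortical"), 9L)
  realized <- unique(net$synapses$type)
  expect_setequal(realized, specs$name)
  # per-type synapse counts partition the synapse table
  expect_identical(sum(table(net$synapses$type)), nrow(net$synapses))
})

test_that("micromodule-confined types never cross modules", {
  net <- small_network()
  mod <- setNames(net$neurons$module, net$neurons$id)
  conf <- net$synapses[confined == TRUE]
  expect_gt(nrow(conf), 0)
  expect_true(all(mod[as.character(conf$pre)] ==
                    mod[as.character(conf$post)]))
})

test_that("self-connections are excluded within a population", {
  net <- small_network()
  same_pop <- net$synapses[type %in% c("GoC-GoC", "SC-SC", "BC-BC")]
  expect_true(all(same_pop$pre != same_pop$post))
})

test_that("realized in-degrees match the specification", {
  net <- suppressWarnings(generate_connectivity(
    build_network(network_config(scale_factor = 0.3, seed = 3))))
  specs <- default_connection_specs()
  for (tp in c("glom-GrC", "SC-PC", "mf-DCN_p", "IO-PC")) {
    sp <- specs[specs$name == tp, ]
    n_pre_pool <- net$config$sizes[[sp$pre]]
    expected <- min(round(sp$convergence), n_pre_pool) * sp$n_contacts
    got <- net$synapses[type == tp, .N, by = post]$N
    expect_equal(mean(got), expected, tolerance = 0.1 * expected + 0.5,
                 label = paste("in-degree of", tp))
  }
})

test_that("construction is reproducible for a fixed seed and differs across seeds", {
  a <- suppressWarnings(generate_connectivity(
    build_network(network_config(scale_factor = 0.05, seed = 11))))
  b <- suppressWarnings(generate_connectivity(
    build_network(network_config(scale_factor = 0.05, seed = 11))))
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$synapses, b$synapses)
  c <- suppressWarnings(generate_connectivity(
    build_network(network_config(scale_factor = 0.05, seed = 12))))
  expect_false(identical(a$synapses, c$synapses))
})

test_that("MLI preference follows the majority of inhibited Purkinje cells", {
  net <- small_network()
  nt <- net$neurons
  mod <- setNames(nt$module, nt$id)
  mli_pc <- net$synapses[type %in% c("SC-PC", "BC-PC")]
  counts <- mli_pc[, .(down = sum(mod[as.character(post)] == "downbound"),
                       up = sum(mod[as.character(post)] == "upbound")),
                   by = pre]
  pref <- setNames(nt$pref, nt$id)
  clear <- counts[down != up]
  expect_true(all(
    pref[as.character(clear$pre)] ==
      ifelse(clear$down > clear$up, "downbound", "upbound")))
})

test_that("downbound-preferring fraction tracks the downbound PC share", {
  fr <- vapply(1:4, function(s) {
    net <- suppressWarnings(generate_connectivity(
      build_network(network_config(scale_factor = 0.15, seed = s))))
    mli <- net$neurons[population %in% c("SC", "BC")]
    mean(mli$pref == "downbound")
  }, numeric(1))
  expect_gt(mean(fr), 0.55)
  expect_lt(mean(fr), 0.95)
})

test_that("network tables round-trip through delimited text", {
  net <- small_network()
  stem <- file.path(tempdir(), "net_roundtrip")
  write_network(net, stem)
  back <- read_network(stem)
  expect_equal(as.data.frame(back$neurons), as.data.frame(net$neurons))
  expect_equal(as.data.frame(back$synapses)[, c("pre", "post", "type")],
               as.data.frame(net$synapses)[, c("pre", "post", "type")])
  expect_identical(back$config$sizes, net$config$sizes)
})
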