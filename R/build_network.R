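# Network construction: statistical placement along a single mediolateral
# coordinate, exact micromodule counts, in-degree driven wiring.

#' Build the two-micromodule olivocerebellar network
#'
#' Instantiates all populations at the configured scale, assigns every
#' Purkinje, nuclear and olivary neuron to the downbound or upbound
#' micromodule (70/30 by default) by its mediolateral position, and marks the
#' central mossy-fibre subset that will receive the conditioned stimulus.
#' Connectivity is added by [generate_connectivity()].
#'
#' @param config a [network_config()].
#' @return A `cereb_network` object with a `neurons` data.table
#'   (id, population, module, x, cs_target, pref) and an empty synapse slot.
#' @export
#' @examples
#' net <- build_network(network_config(scale_factor = 0.05, seed = 1))
#' table(net$neurons$population)
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  sizes <- config$sizes
  df <- config$downbound_fraction

  neurons <- with_seed(derive_seed(config$seed, "construction"), {
    tabs <- lapply(names(sizes), function(p) {
      n <- sizes[[p]]
      if (p %in% labelled_populations) {
        ms <- config$module_sizes[[p]]
        x <- c(runif(ms[["downbound"]], 0, df), runif(ms[["upbound"]], df, 1))
        module <- rep(c("downbound", "upbound"), ms)
      } else {
        x <- runif(n, 0, 1)
        module <- rep("shared", n)
      }
      data.table::data.table(population = p, module = module, x = x)
    })
    dt <- data.table::rbindlist(tabs)
    dt[, id := seq_len(.N)]
    # CS target cylinder: the central mf fraction along the mediolateral axis
    dt[, cs_target := FALSE]
    mf_rows <- which(dt$population == "mf")
    n_cs <- config$mf_cs_target_count
    ord <- mf_rows[order(dt$x[mf_rows])]
    lo <- floor((length(ord) - n_cs) / 2)
    dt[ord[(lo + 1):(lo + n_cs)], cs_target := TRUE]
    dt[, pref := NA_character_]
    data.table::setcolorder(dt, c("id", "population", "module", "x",
                                  "cs_target", "pref"))
    dt[]
  })

  structure(list(neurons = neurons, synapses = NULL, config = config,
                 specs = NULL),
            class = "cereb_network")
}

#' @export
print.cereb_network <- function(x, ...) {
  cat("<cereb_network> scale", x$config$scale_factor, "\n")
  print(table(x$neurons$population))
  if (!is.null(x$synapses))
    cat(nrow(x$synapses), "synapses across",
        length(unique(x$synapses$type)), "connection types\n")
  invisible(x)
}

# Sample `k` distinct presynaptic partners for one postsynaptic cell.
# Local types use a sliding mediolateral window (pre-sorted x), expanding
# until enough candidates are available; non-local types sample uniformly.
sample_pre <- function(pool_x_sorted, pool_ids_sorted, x0, k, local,
                       exclude = integer(0)) {
  n <- length(pool_ids_sorted)
  if (!local) {
    ids <- pool_ids_sorted
    if (length(exclude)) ids <- setdiff(ids, exclude)
    k <- min(k, length(ids))
    return(if (k == length(ids)) ids else sample(ids, k))
  }
  r <- max(0.05, 2 * k / n)
  repeat {
    i1 <- findInterval(x0 - r, pool_x_sorted) + 1L
    i2 <- findInterval(x0 + r, pool_x_sorted)
    ids <- if (i2 >= i1) pool_ids_sorted[i1:i2] else integer(0)
    if (length(exclude)) ids <- setdiff(ids, exclude)
    if (length(ids) >= min(k, n - length(exclude)) || r >= 1) break
    r <- r * 2
  }
  k <- min(k, length(ids))
  if (k == length(ids)) ids else sample(ids, k)
}

#' Wire the network according to connection specifications
#'
#' Realizes every connection type by drawing, for each postsynaptic neuron,
#' a set of distinct presynaptic partners of the specified mean in-degree
#' (capped by the available pool at reduced scale). Micromodule-confined
#' types only connect within a module; climbing-fibre spillover onto
#' molecular layer interneurons follows a linear parasagittal ramp that
#' favours downbound olivary sources near the downbound microzone. Multiple
#' anatomical contacts per pair are realized as parallel synapses.
#'
#' @param network a `cereb_network` from [build_network()].
#' @param specs a connection-spec data.frame (default
#'   [default_connection_specs()]).
#' @return The network with its `synapses` data.table filled in
#'   (pre, post, type, weight, delay, tau_syn, plastic, confined).
#' @export
generate_connectivity <- function(network, specs = default_connection_specs()) {
  stopifnot(inherits(network, "cereb_network"))
  validate_connection_specs(specs)
  nt <- network$neurons

  syn <- with_seed(derive_seed(network$config$seed, "connectivity"), {
    parts <- vector("list", nrow(specs))
    for (si in seq_len(nrow(specs))) {
      sp <- specs[si, ]
      pre_rows <- nt[population == sp$pre]
      post_rows <- nt[population == sp$post]
      same_pop <- sp$pre == sp$post

      # pre-sorted pools, split by module for confined/gradient types
      make_pool <- function(rows) {
        o <- order(rows$x)
        list(x = rows$x[o], id = rows$id[o])
      }
      pools <- if (sp$confined || sp$gradient) {
        list(downbound = make_pool(pre_rows[module == "downbound"]),
             upbound   = make_pool(pre_rows[module == "upbound"]))
      } else list(shared = make_pool(pre_rows))

      pre_list <- vector("list", nrow(post_rows))
      for (j in seq_len(nrow(post_rows))) {
        x0 <- post_rows$x[j]
        pool <- if (sp$confined) {
          pools[[post_rows$module[j]]]
        } else if (sp$gradient) {
          # linear ramp: probability of a downbound climbing-fibre source
          # decreases with mediolateral distance from the downbound zone
          p_down <- 1 - x0
          if (runif(1) < p_down) pools$downbound else pools$upbound
        } else pools$shared
        excl <- if (same_pop) post_rows$id[j] else integer(0)
        pre_list[[j]] <- sample_pre(pool$x, pool$id, x0,
                                    k = round(sp$convergence),
                                    local = sp$local, exclude = excl)
      }
      counts <- lengths(pre_list)
      pairs <- data.table::data.table(
        pre = unlist(pre_list),
        post = rep(post_rows$id, counts))
      if (sp$n_contacts > 1)
        pairs <- pairs[rep(seq_len(.N), each = sp$n_contacts)]
      w_up <- sp$weight_upbound
      post_mod <- nt$module[pairs$post]
      pairs[, `:=`(type = sp$name,
                   weight = ifelse(!is.na(w_up) & post_mod == "upbound",
                                   w_up, sp$weight),
                   delay = sp$delay,
                   tau_syn = sp$tau_syn, plastic = sp$plastic,
                   confined = sp$confined)]
      parts[[si]] <- pairs
    }
    data.table::rbindlist(parts)
  })

  network$synapses <- syn
  network$specs <- specs
  assign_mli_preference(network)
}

#' Label molecular layer interneurons as downbound- or upbound-preferring
#'
#' Each stellate and basket cell is labelled by the micromodule of the
#' majority of the Purkinje cells it inhibits; ties are broken by the module
#' of its climbing-fibre (olivary spillover) afferents, then by id parity.
#' MLIs with no PC target are labelled by their climbing-fibre afferent
#' alone (with a warning).
#'
#' @param network a wired `cereb_network`.
#' @return The network with the `pref` column filled for SC/BC neurons.
#' @export
assign_mli_preference <- function(network) {
  stopifnot(inherits(network, "cereb_network"), !is.null(network$synapses))
  nt <- network$neurons
  syn <- network$synapses
  mod_of <- setNames(nt$module, nt$id)

  mli_ids <- nt[population %in% mli_populations, id]
  mli_pc <- syn[type %in% c("SC-PC", "BC-PC")]
  mli_pc[, post_module := mod_of[as.character(post)]]
  pc_down <- mli_pc[, .(down = sum(post_module == "downbound"),
                        up = sum(post_module == "upbound")), by = pre]

  cf <- syn[type %in% c("IO-SC", "IO-BC")]
  cf[, pre_module := mod_of[as.character(pre)]]
  cf_down <- cf[, .(cf_down = sum(pre_module == "downbound"),
                    cf_up = sum(pre_module == "upbound")), by = post]

  lab <- setNames(rep(NA_character_, length(mli_ids)), mli_ids)
  down_n <- setNames(rep(0L, length(mli_ids)), mli_ids)
  up_n <- down_n
  down_n[as.character(pc_down$pre)] <- pc_down$down
  up_n[as.character(pc_down$pre)] <- pc_down$up
  cfd <- setNames(rep(0L, length(mli_ids)), mli_ids)
  cfu <- cfd
  cfd[as.character(cf_down$post)] <- cf_down$cf_down
  cfu[as.character(cf_down$post)] <- cf_down$cf_up

  no_target <- down_n + up_n == 0
  if (any(no_target))
    warning(sum(no_target), " MLI(s) with no PC target; labelled by ",
            "climbing-fibre in-degree alone")

  lab[down_n > up_n] <- "downbound"
  lab[up_n > down_n] <- "upbound"
  tie <- is.na(lab)
  lab[tie & cfd > cfu] <- "downbound"
  lab[tie & cfu > cfd] <- "upbound"
  still <- is.na(lab)
  lab[still] <- ifelse(as.integer(names(lab)[still]) %% 2L == 0L,
                       "downbound", "upbound")

  rows <- match(as.integer(names(lab)), network$neurons$id)
  data.table::set(network$neurons, i = rows, j = "pref",
                  value = unname(lab))
  network
}
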