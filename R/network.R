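#' Network build configuration
#'
#' Population sizes, wiring rules and per-edge-class synaptic conductances for
#' the sensory-to-reticulospinal model circuit: 30 sensory-pathway DLC input
#' neurons, a recurrent core of 30 hexNs, 5 uncoupled monitor hdINs and a
#' 30-cell electrically coupled hdIN population.
#'
#' In-degrees of the hexN core are sampled as the floor of a normal variable
#' (mu = sigma = 3.0), clamped to the feasible range. DLC to hexN edges are
#' independent Bernoulli draws with probability 0.4; hexN to monitor edges
#' Bernoulli 0.2; each population hdIN receives input from exactly 3 distinct
#' randomly chosen hexNs.
#'
#' @param n_dlc,n_hexn,n_mon,n_pop population sizes
#' @param indegree_mu,indegree_sigma parameters of the hexN in-degree law
#' @param p_dlc_hexn,p_hexn_mon connection probabilities
#' @param k_hexn_pop hexN inputs per population hdIN
#' @param k_pop_feedback recurrent excitatory inputs per population hdIN
#' @param gap_g gap-junction conductance within the hdIN population (nS)
#' @param gap_window each population hdIN is electrically coupled to its
#'   `gap_window` nearest neighbours on either side in an ordered chain
#' @param conductances named list of `c(ampa, nmda)` maximal conductances
#'   (nS) per edge class
#' @return an object of class `build_config`
#' @export
build_config <- function(n_dlc = 30, n_hexn = 30, n_mon = 5, n_pop = 30,
                         indegree_mu = 3, indegree_sigma = 3,
                         p_dlc_hexn = 0.4, p_hexn_mon = 0.2,
                         k_hexn_pop = 3, k_pop_feedback = 3,
                         gap_g = 0.3, gap_window = 8,
                         conductances = list(
                           dlc_hexn  = c(ampa = 1.1,   nmda = 1.4),
                           hexn_hexn = c(ampa = 1.5,   nmda = 1.8),
                           hexn_mon  = c(ampa = 0.25,  nmda = 0.1),
                           hexn_pop  = c(ampa = 0.125, nmda = 0.15),
                           pop_pop   = c(ampa = 0.15,  nmda = 1.2))) {
  counts <- c(n_dlc, n_hexn, n_mon, n_pop)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("population sizes must be non-negative integers")
  for (p in c(p_dlc_hexn, p_hexn_mon))
    if (p < 0 || p > 1) stop("connection probabilities must lie in [0, 1]")
  if (gap_g < 0) stop("gap_g must be >= 0")
  structure(list(n_dlc = n_dlc, n_hexn = n_hexn, n_mon = n_mon, n_pop = n_pop,
                 indegree_mu = indegree_mu, indegree_sigma = indegree_sigma,
                 p_dlc_hexn = p_dlc_hexn, p_hexn_mon = p_hexn_mon,
                 k_hexn_pop = k_hexn_pop, k_pop_feedback = k_pop_feedback,
                 gap_g = gap_g, gap_window = gap_window,
                 conductances = conductances),
            class = "build_config")
}

#' Sample a hexN in-degree
#'
#' Floor of a normal draw with the given mean and standard deviation, clamped
#' to `[0, n_max - 1]` (a neuron cannot receive from itself, and negative
#' draws are clamped to zero).
#'
#' @param mu,sigma normal parameters
#' @param n_max population size (so the maximum in-degree is `n_max - 1`)
#' @param n number of draws
#' @return integer vector
#' @export
sample_indegree <- function(mu = 3, sigma = 3, n_max = 30, n = 1) {
  k <- floor(rnorm(n, mu, sigma))
  pmin(pmax(k, 0), n_max - 1)
}

.edge_df <- function(pre = integer(0), post = integer(0),
                     class = character(0), g = NULL) {
  if (length(pre) == 0)
    return(data.frame(pre = integer(0), post = integer(0),
                      class = character(0), gmax_ampa = numeric(0),
                      gmax_nmda = numeric(0)))
  data.frame(pre = pre, post = post, class = class,
             gmax_ampa = g[["ampa"]], gmax_nmda = g[["nmda"]])
}

#' Build the recurrent hexN core
#'
#' Samples each hexN's in-degree with [sample_indegree()] and chooses its
#' presynaptic hexNs uniformly without replacement, excluding itself; no
#' duplicate edges. Uses the current R random-number stream.
#'
#' @param cfg a [build_config()]
#' @return an object of class `hexnet_graph` containing only the hexN
#'   population (ids `n_dlc + 1 ...`) and its recurrent edges
#' @export
build_hexn_recurrent <- function(cfg = build_config()) {
  ids <- cfg$n_dlc + seq_len(cfg$n_hexn)
  edges <- list()
  for (i in seq_len(cfg$n_hexn)) {
    k <- sample_indegree(cfg$indegree_mu, cfg$indegree_sigma, cfg$n_hexn)
    if (k > 0) {
      pres <- sample(ids[-i], k)
      edges[[length(edges) + 1]] <-
        .edge_df(pres, rep(ids[i], k), "hexn_hexn", cfg$conductances$hexn_hexn)
    }
  }
  chem <- if (length(edges)) do.call(rbind, edges) else .edge_df()
  neurons <- data.frame(
    id = c(seq_len(cfg$n_dlc), ids),
    population = rep(c("DLC", "HEXN"), c(cfg$n_dlc, cfg$n_hexn)))
  structure(list(neurons = neurons, chemical = chem,
                 electrical = data.frame(a = integer(0), b = integer(0),
                                         g = numeric(0)),
                 cfg = cfg),
            class = "hexnet_graph")
}

#' Attach sensory inputs and monitor outputs to the hexN core
#'
#' Adds DLC to hexN edges by independent Bernoulli(`p_dlc_hexn`) draws per
#' pair, and 5 monitor hdINs each receiving from hexNs by Bernoulli
#' (`p_hexn_mon`) draws. Connections are drawn once per network and then held
#' fixed across all trials.
#'
#' @param core graph from [build_hexn_recurrent()]
#' @return extended `hexnet_graph` with DLC and monitor hdIN populations
#' @export
attach_inputs_and_outputs <- function(core) {
  cfg <- core$cfg
  dlc_ids <- seq_len(cfg$n_dlc)
  hexn_ids <- cfg$n_dlc + seq_len(cfg$n_hexn)
  mon_ids <- cfg$n_dlc + cfg$n_hexn + seq_len(cfg$n_mon)

  pairs <- expand.grid(pre = dlc_ids, post = hexn_ids)
  keep <- runif(nrow(pairs)) < cfg$p_dlc_hexn
  dlc_edges <- .edge_df(pairs$pre[keep], pairs$post[keep], "dlc_hexn",
                        cfg$conductances$dlc_hexn)

  pairs2 <- expand.grid(pre = hexn_ids, post = mon_ids)
  keep2 <- runif(nrow(pairs2)) < cfg$p_hexn_mon
  mon_edges <- .edge_df(pairs2$pre[keep2], pairs2$post[keep2], "hexn_mon",
                        cfg$conductances$hexn_mon)

  core$chemical <- rbind(dlc_edges, core$chemical, mon_edges)
  core$neurons <- rbind(
    core$neurons,
    data.frame(id = mon_ids, population = "HDIN_MON"))
  core$neurons <- core$neurons[order(core$neurons$id), ]
  rownames(core$neurons) <- NULL
  core
}

#' Build the full sensory-to-monitor network
#'
#' Convenience wrapper: seeds the R random-number stream with `build_seed`,
#' builds the recurrent hexN core, then attaches DLC inputs and monitor
#' hdINs. The resulting structure is a pure function of (`cfg`, `build_seed`).
#'
#' @param cfg a [build_config()]
#' @param build_seed integer seed
#' @return a `hexnet_graph`
#' @export
build_network <- function(cfg = build_config(), build_seed = 1) {
  set.seed(build_seed)
  g <- attach_inputs_and_outputs(build_hexn_recurrent(cfg))
  g$build_seed <- build_seed
  .validate_graph(g)
  g
}

#' Build the coupled hdIN population
#'
#' 30 reticulospinal hdINs arranged in an ordered chain, electrically coupled
#' to their `gap_window` nearest neighbours on each side, with random
#' recurrent glutamatergic feedback (each cell receives from
#' `k_pop_feedback` distinct others) and each receiving sensory-memory input
#' from `k_hexn_pop` distinct randomly selected hexNs. The uncoupled variant
#' (electrical edges removed, chemical edges unchanged) is built with
#' `coupled = FALSE`.
#'
#' @param cfg a [build_config()]
#' @param build_seed integer seed
#' @param coupled keep the electrical edges?
#' @return a `hexnet_graph` whose neuron ids `1...n_pop` are hdINs; hexN
#'   input sources are referenced as external ids `n_pop + 1 ... n_pop +
#'   n_hexn` in the `hexn_pop` edges
#' @export
build_hdin_population <- function(cfg = build_config(), build_seed = 1,
                                  coupled = TRUE) {
  set.seed(build_seed)
  n <- cfg$n_pop
  ids <- seq_len(n)
  hexn_src <- n + seq_len(cfg$n_hexn)

  elec <- list()
  if (coupled && cfg$gap_g > 0 && cfg$gap_window > 0) {
    for (i in ids) for (d in seq_len(cfg$gap_window)) {
      if (i + d <= n)
        elec[[length(elec) + 1]] <- c(i, i + d, cfg$gap_g)
    }
  }
  elec <- if (length(elec)) {
    m <- do.call(rbind, elec)
    data.frame(a = m[, 1], b = m[, 2], g = m[, 3])
  } else data.frame(a = integer(0), b = integer(0), g = numeric(0))

  fb <- list()
  for (i in ids) {
    k <- min(cfg$k_pop_feedback, n - 1)
    if (k > 0) {
      pres <- sample(ids[-i], k)
      fb[[length(fb) + 1]] <- .edge_df(pres, rep(i, k), "pop_pop",
                                       cfg$conductances$pop_pop)
    }
  }
  inp <- list()
  for (i in ids) {
    src <- sample(hexn_src, min(cfg$k_hexn_pop, cfg$n_hexn))
    inp[[length(inp) + 1]] <- .edge_df(src, rep(i, length(src)), "hexn_pop",
                                       cfg$conductances$hexn_pop)
  }
  chem <- do.call(rbind, c(inp, fb))
  g <- structure(list(
    neurons = data.frame(id = ids, population = "HDIN_POP"),
    chemical = chem, electrical = elec, cfg = cfg, build_seed = build_seed,
    coupled = coupled), class = "hexnet_graph")
  .validate_graph(g, external_pre = hexn_src)
  g
}

# invariant checks: no self edges, no duplicated (pre, post, class), DLCs
# have no incoming edges
.validate_graph <- function(g, external_pre = integer(0)) {
  ch <- g$chemical
  if (any(ch$pre == ch$post)) stop("graph contains self-connections")
  key <- paste(ch$pre, ch$post, ch$class)
  if (anyDuplicated(key)) stop("graph contains duplicate connections")
  dlc <- g$neurons$id[g$neurons$population == "DLC"]
  if (any(ch$post %in% dlc)) stop("DLC neurons cannot receive edges")
  known <- c(g$neurons$id, external_pre)
  if (!all(ch$pre %in% known) || !all(ch$post %in% g$neurons$id))
    stop("edge references unknown neuron id")
  if (nrow(g$electrical)) {
    if (any(g$electrical$a == g$electrical$b))
      stop("electrical self-connection")
    if (any(g$electrical$g < 0)) stop("negative gap conductance")
  }
  invisible(g)
}

#' @export
print.hexnet_graph <- function(x, ...) {
  tab <- table(x$neurons$population)
  cat("<hexnet_graph> ",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n",
      sprintf("  chemical edges: %d  electrical edges: %d  build_seed: %s\n",
              nrow(x$chemical), nrow(x$electrical),
              ifelse(is.null(x$build_seed), "NA", x$build_seed)))
  invisible(x)
}

#' Export / import a network as an edge-list table
#'
#' Writes the graph as a CSV edge list (`type, pre, post, class, gmax_ampa,
#' gmax_nmda, g`) preceded by a single `#`-prefixed JSON header line carrying
#' the population sizes, the build seed and the build parameters, so a file
#' round-trips losslessly.
#'
#' @param g a `hexnet_graph`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_graph_csv <- function(g, path) {
  hdr <- jsonlite::toJSON(list(
    populations = as.list(table(g$neurons$population)),
    build_seed = g$build_seed,
    coupled = g$coupled,
    cfg = g$cfg[setdiff(names(g$cfg), "conductances")],
    conductances = lapply(g$cfg$conductances, as.list)), auto_unbox = TRUE)
  ch <- g$chemical
  el <- g$electrical
  tab <- rbind(
    data.frame(type = rep("chem", nrow(ch)), pre = ch$pre, post = ch$post,
               class = ch$class, gmax_ampa = ch$gmax_ampa,
               gmax_nmda = ch$gmax_nmda, g = rep(NA_real_, nrow(ch))),
    data.frame(type = rep("elec", nrow(el)), pre = el$a, post = el$b,
               class = rep(NA_character_, nrow(el)),
               gmax_ampa = rep(NA_real_, nrow(el)),
               gmax_nmda = rep(NA_real_, nrow(el)), g = el$g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @param path file path
#' @return for `read_graph_csv`, a `hexnet_graph`
#' @export
read_graph_csv <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# ")) stop("missing JSON header line")
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  tab <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE)
  ch <- tab[tab$type == "chem", ]
  el <- tab[tab$type == "elec", ]
  cfg_args <- hdr$cfg
  cfg_args$conductances <- lapply(hdr$conductances, function(x)
    c(ampa = as.numeric(x$ampa), nmda = as.numeric(x$nmda)))
  cfg <- do.call(build_config, cfg_args)
  pops <- hdr$populations
  neurons <- do.call(rbind, lapply(names(pops), function(p)
    data.frame(population = p, n = pops[[p]])))
  # ids are reconstructed in canonical order: DLC, HEXN, HDIN_MON / HDIN_POP
  order_p <- intersect(c("DLC", "HEXN", "HDIN_MON", "HDIN_POP"),
                       neurons$population)
  ids <- integer(0); popv <- character(0)
  nxt <- 1L
  for (p in order_p) {
    np <- neurons$n[neurons$population == p]
    ids <- c(ids, seq(nxt, length.out = np))
    popv <- c(popv, rep(p, np))
    nxt <- nxt + np
  }
  g <- structure(list(
    neurons = data.frame(id = ids, population = popv),
    chemical = data.frame(pre = ch$pre, post = ch$post, class = ch$class,
                          gmax_ampa = ch$gmax_ampa, gmax_nmda = ch$gmax_nmda),
    electrical = data.frame(a = el$pre, b = el$post, g = el$g),
    cfg = cfg, build_seed = hdr$build_seed,
    coupled = if (!is.null(hdr$coupled)) hdr$coupled else NULL),
    class = "hexnet_graph")
  g
}
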