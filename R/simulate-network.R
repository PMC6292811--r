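#' Trial configuration
#'
#' Integration and recording settings for one simulated trial. The hexN
#' network stage uses a 0.025 ms step; the hdIN population stage a 0.1 ms
#' step. Voltages are stored at `out_dt` intervals.
#'
#' @param duration trial length (ms)
#' @param dt integration step (ms)
#' @param out_dt voltage output sample interval (ms; multiple of `dt`)
#' @param record which voltages to store: monitor hdINs and/or example hexN
#'   somas
#' @param n_record_hexn number of hexN somatic voltages to store
#' @return an object of class `trial_config`
#' @export
trial_config <- function(duration = 1500, dt = 0.025, out_dt = 0.1,
                         record = c("monitors", "hexn"),
                         n_record_hexn = 2) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  out_every <- round(out_dt / dt)
  if (abs(out_every * dt - out_dt) > 1e-9)
    stop("out_dt must be an integer multiple of dt")
  structure(list(duration = duration, dt = dt, out_dt = out_dt,
                 out_every = as.integer(out_every), record = record,
                 n_record_hexn = n_record_hexn), class = "trial_config")
}

#' Default cell specifications per population
#'
#' @return named list of [neuron_spec()] objects keyed by population label
#' @export
default_cell_specs <- function() {
  list(HEXN = make_hexn(),
       HDIN_MON = make_hdin("monitor"),
       HDIN_POP = make_hdin("population"))
}

# memoised resting potentials so trials start from the settled state
.rest_cache <- new.env(parent = emptyenv())
.rest_of <- function(spec, dt) {
  key <- paste(spec$role, dt,
               paste(signif(unlist(spec$channels), 10), collapse = ","),
               paste(signif(unlist(spec$kinetics), 10), collapse = ","),
               sep = "|")
  if (is.null(.rest_cache[[key]]))
    .rest_cache[[key]] <- suppressWarnings(as.numeric(
      resting_potential(spec, dt = max(dt, 0.025))))
  .rest_cache[[key]]
}

# Assemble a hexnet_graph plus cell specs into engine arguments.
# external_src: integer ids (graph-level) treated as external event sources.
.assemble_graph <- function(graph, specs, dt, scales, per_spike_flag,
                            syn_tables, external_src = integer(0)) {
  nn <- graph$neurons
  model_ids <- nn$id[nn$population != "DLC"]
  spec_list <- lapply(model_ids, function(id)
    specs[[nn$population[nn$id == id]]])
  v0 <- lapply(spec_list, function(s)
    rep(.rest_of(s, dt), s$n_compartments))
  asm <- .assemble_cells(spec_list, v0 = v0)
  soma_of <- stats::setNames(asm$soma, model_ids)
  axon_of <- stats::setNames(asm$axon, model_ids)

  ch <- graph$chemical
  # sources: internal model neurons that have outgoing edges, then externals
  pre_ids <- unique(ch$pre)
  int_src <- sort(intersect(pre_ids, model_ids))
  ext_src <- sort(unique(c(external_src, setdiff(pre_ids, model_ids))))
  src_id_of <- c(stats::setNames(seq_along(int_src), int_src),
                 stats::setNames(length(int_src) + seq_along(ext_src),
                                 ext_src))
  syn <- syn_tables
  chem <- cbind(
    src_id_of[as.character(ch$pre)],
    soma_of[as.character(ch$post)],
    ch$gmax_ampa, ch$gmax_nmda,
    vapply(ch$class, function(cl) syn[[cl]]$e_rev, 0),
    vapply(ch$class, function(cl) syn[[cl]]$tau_open_ampa, 0),
    vapply(ch$class, function(cl) syn[[cl]]$tau_close_ampa, 0),
    vapply(ch$class, function(cl) syn[[cl]]$tau_open_nmda, 0),
    vapply(ch$class, function(cl) syn[[cl]]$tau_close_nmda, 0),
    scales, as.numeric(per_spike_flag))
  gap <- graph$electrical
  coupling <- rbind(asm$coupling,
                    if (nrow(gap)) cbind(soma_of[as.character(gap$a)],
                                         soma_of[as.character(gap$b)],
                                         gap$g))
  list(asm = asm, chem = chem, coupling = coupling,
       soma_of = soma_of, axon_of = axon_of,
       int_src = int_src, ext_src = ext_src, src_id_of = src_id_of,
       model_ids = model_ids)
}

# per-edge per-trial scales and per-spike flags for a policy
.edge_scaling <- function(chemical, policy) {
  n <- nrow(chemical)
  cls <- chemical$class
  # policy classes use circuit-level names; hexn_mon and hexn_pop edges are
  # both "hexn -> hdin" class for scaling purposes
  cls_alias <- ifelse(cls %in% c("hexn_mon", "hexn_pop"), "hexn_hdin", cls)
  affected <- cls_alias %in% policy$classes
  scales <- rep(1, n)
  per_spike <- rep(FALSE, n)
  if (policy$mode %in% c("per_trial", "both"))
    scales[affected] <- draw_scale(policy, sum(affected))
  if (policy$mode %in% c("per_spike", "both"))
    per_spike[affected] <- TRUE
  list(scales = scales, per_spike = per_spike)
}

.default_syn_tables <- function() {
  base <- synapse_params(1, 1)
  tabs <- list()
  for (cl in c("dlc_hexn", "hexn_hexn", "hexn_pop", "pop_pop"))
    tabs[[cl]] <- base
  # monitor hdIN NMDA kinetics are calibrated separately: a slower rise and
  # faster decay keep the summation envelope (and hence the first-spike
  # delay distribution) on the physiological time scale
  tabs$hexn_mon <- synapse_params(1, 1, tau_open_nmda = 25,
                                  tau_close_nmda = 60)
  tabs
}

#' Run one trial of the sensory-to-monitor network
#'
#' Delivers one spike per DLC neuron at times drawn from the stimulus law,
#' integrates the recurrent hexN network and the 5 monitor hdINs, with
#' per-trial (and optionally per-spike) synaptic-strength noise, and records
#' spike trains, selected voltages and the realised noise draws.
#'
#' The result is deterministic given (`graph`, `trial_seed`).
#'
#' @param graph a [build_network()] graph
#' @param stim a [stimulus_spec()]
#' @param cfg a [trial_config()]
#' @param policy a [scaling_policy()]
#' @param trial_seed integer seed for this trial's noise streams
#' @param specs cell specifications per population
#' @return an object of class `hexnet_trial`: list with `spikes`
#'   (neuron_id, population, t), `dlc_spikes`, `delays` (first-spike delay
#'   per monitor hdIN, NA when it never fired), `traces` (times x recorded
#'   neurons), `scales` (per-edge realised per-trial factors),
#'   `per_spike_draws`, `ok`, `trial_seed`
#' @export
run_trial <- function(graph, stim = stimulus_spec(), cfg = trial_config(),
                      policy = scaling_policy(), trial_seed = 1,
                      specs = default_cell_specs()) {
  stopifnot(inherits(graph, "hexnet_graph"))
  set.seed(trial_seed)
  dlc <- generate_dlc_spikes(stim)
  sc <- .edge_scaling(graph$chemical, policy)
  A <- .assemble_graph(graph, specs, cfg$dt, sc$scales, sc$per_spike,
                       .default_syn_tables())

  nn <- graph$neurons
  dlc_ids <- nn$id[nn$population == "DLC"]
  ext <- cbind(A$src_id_of[as.character(dlc$dlc_id)], dlc$t)
  ext <- ext[!is.na(ext[, 1]), , drop = FALSE]
  ext <- ext[order(ext[, 2]), , drop = FALSE]

  mon_ids <- nn$id[nn$population == "HDIN_MON"]
  hexn_ids <- nn$id[nn$population == "HEXN"]
  rec_ids <- c(if ("monitors" %in% cfg$record) mon_ids,
               if ("hexn" %in% cfg$record)
                 utils::head(hexn_ids, cfg$n_record_hexn))
  record_comp <- unname(A$soma_of[as.character(rec_ids)])
  detect_comp <- unique(c(unname(A$axon_of[as.character(c(hexn_ids,
                                                          mon_ids))])))

  syn0 <- .default_syn_tables()[[1]]
  res <- cpp_run_network(A$asm$comp, A$asm$kinetics,
                         as.matrix(A$coupling), A$chem,
                         source_comp = unname(A$axon_of[as.character(A$int_src)]),
                         ext_events = ext,
                         inj = matrix(0, 0, 4),
                         detect_comp = detect_comp,
                         record_comp = record_comp,
                         dt = cfg$dt, duration = cfg$duration,
                         out_every = cfg$out_every,
                         value_set = policy$value_set,
                         mg_vhalf = syn0$mg_vhalf, mg_slope = syn0$mg_slope,
                         spike_thresh = 0, min_isi = 1,
                         record_gsyn = FALSE)

  comp2id <- stats::setNames(rep(A$model_ids, each = 1), A$axon_of)
  sp_comp <- res$spikes[, 1]
  sp_id <- comp2id[as.character(sp_comp)]
  keep <- !is.na(sp_id)
  spikes <- data.frame(neuron_id = as.integer(sp_id[keep]),
                       t = res$spikes[keep, 2])
  spikes$population <- nn$population[match(spikes$neuron_id, nn$id)]
  spikes <- spikes[order(spikes$t), c("neuron_id", "population", "t")]
  rownames(spikes) <- NULL

  delays <- vapply(mon_ids, function(id) {
    ts <- spikes$t[spikes$neuron_id == id]
    if (length(ts)) min(ts) else NA_real_
  }, 0)
  names(delays) <- paste0("mon_", seq_along(mon_ids))

  n <- res$n_out
  traces <- res$v[seq_len(n), , drop = FALSE]
  colnames(traces) <- paste0(nn$population[match(rec_ids, nn$id)], "_",
                             rec_ids)
  out <- list(spikes = spikes, dlc_spikes = dlc, delays = delays,
              times = res$times[seq_len(n)], traces = traces,
              scales = data.frame(edge = seq_len(nrow(graph$chemical)),
                                  class = graph$chemical$class,
                                  scale = sc$scales),
              per_spike_draws = res$per_spike_draws,
              ok = res$ok, abort_time = res$abort_time,
              trial_seed = trial_seed)
  class(out) <- "hexnet_trial"
  if (!res$ok)
    warning(sprintf("trial aborted: |v| > 200 mV at t = %.2f ms",
                    res$abort_time))
  out
}

# documented seed-splitting scheme: stream i of master seed m
.derive_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + 7919 * as.double(i)) %%
               2147483646 + 1)
}

#' Run a multi-trial experiment
#'
#' Repeats [run_trial()] with independent per-trial noise streams derived
#' from a master seed (`trial_seed_i = (master * 1000003 + 7919 i) mod
#' (2^31 - 2) + 1`), holding the network structure fixed.
#'
#' @inheritParams run_trial
#' @param n_trials number of trials
#' @param master_seed master seed for the experiment
#' @return object of class `hexnet_experiment`: list of trials plus a
#'   `delays` matrix (trial x monitor)
#' @export
run_experiment <- function(graph, stim = stimulus_spec(),
                           cfg = trial_config(), policy = scaling_policy(),
                           n_trials = 30, master_seed = 1,
                           specs = default_cell_specs()) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trials[[i]] <- run_trial(graph, stim, cfg, policy,
                             trial_seed = .derive_seed(master_seed, i),
                             specs = specs)
  }
  delays <- do.call(rbind, lapply(trials, `[[`, "delays"))
  rownames(delays) <- paste0("trial_", seq_len(n_trials))
  structure(list(trials = trials, delays = delays,
                 master_seed = master_seed), class = "hexnet_experiment")
}

#' Spike table of an experiment
#'
#' @param exp a `hexnet_experiment`
#' @param population optional population filter
#' @return data.frame (trial, population, neuron_id, t_ms)
#' @export
spike_table <- function(exp, population = NULL) {
  out <- do.call(rbind, lapply(seq_along(exp$trials), function(i) {
    s <- exp$trials[[i]]$spikes
    if (!nrow(s)) return(NULL)
    data.frame(trial = i, population = s$population,
               neuron_id = s$neuron_id, t_ms = s$t)
  }))
  if (is.null(out))
    out <- data.frame(trial = integer(0), population = character(0),
                      neuron_id = integer(0), t_ms = numeric(0))
  if (!is.null(population)) out <- out[out$population %in% population, ]
  rownames(out) <- NULL
  out
}

#' Drive the coupled hdIN population with hexN spike trains
#'
#' Second stage of the two-stage pipeline: the spike times of the hexNs from
#' a recurrent-network trial are replayed as external synaptic input to the
#' 30-cell hdIN population (each hdIN listening to its 3 assigned hexNs),
#' which also excites itself through recurrent glutamatergic synapses and is
#' synchronised by gap junctions. Returns the full population response plus
#' recruitment metrics.
#'
#' @param hexn_spikes data.frame with columns `neuron_id`, `t` (hexN spike
#'   times from [run_trial()]; ids as in the source graph)
#' @param pop_graph graph from [build_hdin_population()]
#' @param source_graph the hexN-network graph the spikes came from (used to
#'   map neuron ids onto the population graph's external sources)
#' @param cfg a [trial_config()]; the default population step is 0.1 ms
#' @param trial_seed seed for this stage's noise stream
#' @param specs cell specifications
#' @return list with `spikes`, `times`, `traces` (all 30 hdINs),
#'   `recruitment` (see [recruitment_delay()]), `cycles` (see
#'   [cycle_synchrony()]), `ok`
#' @export
run_population_recruitment <- function(hexn_spikes, pop_graph,
                                       source_graph,
                                       cfg = trial_config(dt = 0.1,
                                                          out_dt = 0.5),
                                       trial_seed = 1,
                                       specs = default_cell_specs()) {
  stopifnot(inherits(pop_graph, "hexnet_graph"))
  set.seed(trial_seed)
  bc <- pop_graph$cfg
  n_pop <- bc$n_pop
  # map hexN neuron ids (source graph) -> external ids n_pop + 1..n_pop+n_hexn
  n_dlc <- source_graph$cfg$n_dlc
  hexn_ext <- n_pop + seq_len(bc$n_hexn)
  sc <- list(scales = rep(1, nrow(pop_graph$chemical)),
             per_spike = rep(FALSE, nrow(pop_graph$chemical)))
  A <- .assemble_graph(pop_graph, specs, cfg$dt, sc$scales, sc$per_spike,
                       .default_syn_tables(), external_src = hexn_ext)

  if (nrow(hexn_spikes)) {
    src_ext <- n_pop + (hexn_spikes$neuron_id - n_dlc)
    eng_src <- A$src_id_of[as.character(src_ext)]
    keep <- !is.na(eng_src)
    ext <- cbind(eng_src[keep], hexn_spikes$t[keep])
    ext <- ext[order(ext[, 2]), , drop = FALSE]
  } else ext <- matrix(0, 0, 2)

  pop_ids <- pop_graph$neurons$id
  record_comp <- unname(A$soma_of[as.character(pop_ids)])
  syn0 <- .default_syn_tables()[[1]]
  res <- cpp_run_network(A$asm$comp, A$asm$kinetics, as.matrix(A$coupling),
                         A$chem,
                         source_comp = unname(A$axon_of[as.character(A$int_src)]),
                         ext_events = ext, inj = matrix(0, 0, 4),
                         detect_comp = record_comp,
                         record_comp = record_comp,
                         dt = cfg$dt, duration = cfg$duration,
                         out_every = cfg$out_every,
                         value_set = numeric(0),
                         mg_vhalf = syn0$mg_vhalf, mg_slope = syn0$mg_slope,
                         spike_thresh = 0, min_isi = 1,
                         record_gsyn = FALSE)
  comp2id <- stats::setNames(pop_ids, record_comp)
  spikes <- data.frame(neuron_id = as.integer(
    comp2id[as.character(res$spikes[, 1])]), t = res$spikes[, 2])
  spikes <- spikes[order(spikes$t), ]
  rownames(spikes) <- NULL
  n <- res$n_out
  traces <- res$v[seq_len(n), , drop = FALSE]
  colnames(traces) <- paste0("hdin_", pop_ids)
  list(spikes = spikes, times = res$times[seq_len(n)], traces = traces,
       recruitment = recruitment_delay(spikes, n_pop),
       cycles = cycle_synchrony(spikes),
       ok = res$ok, trial_seed = trial_seed)
}

#' Population recruitment delay
#'
#' The population counts as recruited at the first cycle in which every hdIN
#' fires within a `window` ms span; the recruitment delay is the time of the
#' first spike of that cycle.
#'
#' @param spikes data.frame with `neuron_id`, `t`
#' @param n_pop population size
#' @param window span (ms) within which all cells must fire
#' @return list with `recruited` (logical) and `delay` (ms or NA)
#' @export
recruitment_delay <- function(spikes, n_pop, window = 10) {
  if (!nrow(spikes)) return(list(recruited = FALSE, delay = NA_real_))
  o <- order(spikes$t)
  t <- spikes$t[o]; id <- spikes$neuron_id[o]
  j <- 1
  counts <- integer(max(id))
  distinct <- 0
  for (i in seq_along(t)) {
    while (t[i] - t[j] > window) {
      counts[id[j]] <- counts[id[j]] - 1
      if (counts[id[j]] == 0) distinct <- distinct - 1
      j <- j + 1
    }
    counts[id[i]] <- counts[id[i]] + 1
    if (counts[id[i]] == 1) distinct <- distinct + 1
    if (distinct == n_pop) return(list(recruited = TRUE, delay = t[j]))
  }
  list(recruited = FALSE, delay = NA_real_)
}

#' Per-cycle spike-time dispersion
#'
#' Pools all population spikes, splits them into cycles at inter-spike gaps
#' larger than `gap`, and returns the spike-time standard deviation of each
#' cycle. The synchrony summary is the median per-cycle SD: below about 2 ms
#' the population is firing as synchronised cycles, far above it the firing
#' is dispersed or continuous.
#'
#' @param spikes data.frame with `neuron_id`, `t`
#' @param gap gap (ms) that separates cycles
#' @param min_size drop clusters with fewer spikes than this
#' @return data.frame (cycle, t_first, n, sd) with attribute `median_sd`
#' @export
cycle_synchrony <- function(spikes, gap = 20, min_size = 5) {
  if (!nrow(spikes)) {
    out <- data.frame(cycle = integer(0), t_first = numeric(0),
                      n = integer(0), sd = numeric(0))
    attr(out, "median_sd") <- NA_real_
    return(out)
  }
  t <- sort(spikes$t)
  cl <- cumsum(c(1, diff(t) > gap))
  out <- do.call(rbind, lapply(split(t, cl), function(ts)
    data.frame(t_first = ts[1], n = length(ts), sd = stats::sd(ts))))
  out <- out[out$n >= min_size, , drop = FALSE]
  out <- data.frame(cycle = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "median_sd") <- if (nrow(out)) stats::median(out$sd) else NA_real_
  out
}
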