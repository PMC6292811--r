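#' Run configuration for the end-to-end pipeline
#'
#' Bundles the build, stimulus, trial, scaling and synthesis parameter
#' blocks with a master seed and an output directory, so any run is fully
#' reproducible from its saved configuration. Unknown keys inside a block
#' are rejected by name.
#'
#' @param build named list of [build_config()] arguments
#' @param stimulus named list of [stimulus_spec()] arguments
#' @param trial named list of [trial_config()] arguments
#' @param scaling named list of [scaling_policy()] arguments
#' @param synthesis named list of [synth_trace_params()] arguments
#' @param n_trials number of trials for experiments
#' @param master_seed master seed; all per-trial streams derive from it
#' @param output_dir where tables are written by the analysis drivers
#' @return object of class `run_config`
#' @export
run_config <- function(build = list(), stimulus = list(), trial = list(),
                       scaling = list(), synthesis = list(),
                       n_trials = 30, master_seed = 1,
                       output_dir = "results") {
  check_args <- function(args, fn, block) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown key(s) in %s config: %s", block,
                   paste(bad, collapse = ", ")))
    args
  }
  cfg <- list(build = check_args(build, build_config, "build"),
              stimulus = check_args(stimulus, stimulus_spec, "stimulus"),
              trial = check_args(trial, trial_config, "trial"),
              scaling = check_args(scaling, scaling_policy, "scaling"),
              synthesis = check_args(synthesis, synth_trace_params,
                                     "synthesis"),
              n_trials = n_trials, master_seed = master_seed,
              output_dir = output_dir)
  # instantiating validates the values themselves (ranges, sizes)
  do.call(build_config, cfg$build)
  do.call(stimulus_spec, cfg$stimulus)
  do.call(trial_config, cfg$trial)
  do.call(scaling_policy, cfg$scaling)
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param cfg a [run_config()]
#' @param path file path
#' @return `path` invisibly; for `read_run_config`, the `run_config`
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Serialize a neuron specification to a plain list (and back)
#'
#' Round-trips a [neuron_spec()] through nested lists of numbers so it can
#' be stored in YAML configuration files.
#'
#' @param spec a `neuron_spec`
#' @return a plain list
#' @export
spec_to_config <- function(spec) {
  stopifnot(inherits(spec, "neuron_spec"))
  k <- spec$kinetics
  list(role = spec$role,
       channels = unclass(spec$channels),
       kinetics = list(rates = apply(k$rates, 1, as.numeric,
                                     simplify = FALSE),
                       powers = as.integer(k$powers),
                       rate_scale = as.numeric(k$rate_scale)),
       n_compartments = spec$n_compartments,
       capacitance = spec$capacitance,
       link_conductance = spec$link_conductance,
       axon_scale = spec$axon_scale)
}

#' @rdname spec_to_config
#' @param x a list produced by `spec_to_config`
#' @export
spec_from_config <- function(x) {
  ch <- do.call(channel_set, x$channels)
  rates <- do.call(rbind, x$kinetics$rates)
  rownames(rates) <- c("alpha_m", "beta_m", "alpha_h", "beta_h",
                       "alpha_n", "beta_n", "alpha_s", "beta_s")
  colnames(rates) <- c("A", "B", "C", "D", "E")
  kin <- list(rates = rates, powers = as.integer(x$kinetics$powers),
              rate_scale = as.numeric(x$kinetics$rate_scale))
  neuron_spec(x$role, ch, kin, n_compartments = x$n_compartments,
              capacitance = x$capacitance,
              link_conductance = x$link_conductance,
              axon_scale = x$axon_scale)
}
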