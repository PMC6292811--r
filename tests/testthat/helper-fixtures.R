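# Shared fixtures, built once per test session. The default study conditions
# are: network built with seed 1, 30 trials with master seed 1, 1400 ms
# trials (covering the > 1 s physiological depolarisation).

.fx <- new.env(parent = emptyenv())

fixture_graph <- function() {
  if (is.null(.fx$graph)) .fx$graph <- build_network(build_config(),
                                                     build_seed = 1)
  .fx$graph
}

fixture_experiment <- function() {
  if (is.null(.fx$exp))
    .fx$exp <- run_experiment(fixture_graph(), n_trials = 30,
                              master_seed = 1,
                              cfg = trial_config(duration = 1400))
  .fx$exp
}

fixture_rest <- function(role = c("hexn", "hdin_monitor", "motoneuron")) {
  role <- match.arg(role)
  key <- paste0("rest_", role)
  if (is.null(.fx[[key]])) {
    spec <- switch(role, hexn = make_hexn(),
                   hdin_monitor = make_hdin("monitor"),
                   motoneuron = make_motoneuron_reference())
    .fx[[key]] <- suppressWarnings(as.numeric(resting_potential(spec)))
  }
  .fx[[key]]
}

# independent clamped floor-normal oracle for hexN in-degrees
indegree_oracle_mean <- function(mu, sigma, n_max) {
  k <- 0:(n_max - 1)
  p_low <- pnorm(0, mu, sigma)                   # floor < 0 -> clamp to 0
  p_k <- pnorm(k + 1, mu, sigma) - pnorm(k, mu, sigma)
  p_k[1] <- p_k[1] + p_low
  p_hi <- 1 - pnorm(n_max, mu, sigma)            # floor >= n_max -> clamp
  p_k[n_max] <- p_k[n_max] + p_hi
  sum(k * p_k)
}
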