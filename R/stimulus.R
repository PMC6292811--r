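#' Sensory stimulus specification
#'
#' Spike-time law for the 30 sensory-pathway DLC neurons: each fires exactly
#' once near the beginning of a trial, at a time drawn from a normal
#' distribution (mean 5 ms, SD 2 ms) resampled until the value exceeds the
#' lower bound of 5 ms. This reproduces the nearly synchronous firing of
#' recorded DLC neurons after a brief skin stimulus at t = 0.
#'
#' @param n_dlc number of DLC neurons
#' @param mean,sd normal parameters (ms)
#' @param lower_bound strict lower truncation (ms)
#' @return an object of class `stimulus_spec`
#' @export
stimulus_spec <- function(n_dlc = 30, mean = 5, sd = 2, lower_bound = 5) {
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n_dlc = n_dlc, mean = mean, sd = sd,
                 lower_bound = lower_bound), class = "stimulus_spec")
}

#' Generate DLC stimulus spike times
#'
#' One spike time per DLC neuron, by rejection sampling of the truncated
#' normal law in the stimulus specification. Uses the current R
#' random-number stream.
#'
#' @param spec a [stimulus_spec()]
#' @return data.frame with columns `dlc_id` and `t` (ms)
#' @export
generate_dlc_spikes <- function(spec = stimulus_spec()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  t <- numeric(spec$n_dlc)
  for (i in seq_len(spec$n_dlc)) {
    repeat {
      x <- rnorm(1, spec$mean, spec$sd)
      if (x > spec$lower_bound || spec$sd == 0 &&
          !is.finite(spec$lower_bound)) break
      if (spec$sd == 0 && x <= spec$lower_bound)
        stop("degenerate stimulus law entirely below the lower bound")
    }
    t[i] <- x
  }
  data.frame(dlc_id = seq_len(spec$n_dlc), t = t)
}
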