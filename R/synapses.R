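#' Chemical synapse parameters
#'
#' AMPA and NMDA receptor conductances triggered when the presynaptic axonal
#' compartment crosses 0 mV. Each receptor follows a dual-exponential
#' conductance time course normalised so a single event at scale 1 peaks at
#' `gmax`. The NMDA component is multiplied by a sigmoidal voltage-dependent
#' magnesium-block factor in (0, 1), increasing with depolarisation.
#'
#' @param gmax_ampa,gmax_nmda maximal conductances (nS)
#' @param e_rev reversal potential (mV), 0 for glutamatergic synapses
#' @param tau_open_ampa,tau_close_ampa AMPA rise and decay time constants (ms)
#' @param tau_open_nmda,tau_close_nmda NMDA rise and decay time constants (ms)
#' @param mg_vhalf,mg_slope magnesium-block half-unblock voltage (mV) and
#'   slope (mV)
#' @return an object of class `synapse_params`
#' @export
synapse_params <- function(gmax_ampa, gmax_nmda, e_rev = 0,
                           tau_open_ampa = 0.2, tau_close_ampa = 2,
                           tau_open_nmda = 10, tau_close_nmda = 90,
                           mg_vhalf = -40, mg_slope = 10) {
  if (gmax_ampa < 0 || gmax_nmda < 0) stop("gmax must be >= 0")
  if (any(c(tau_open_ampa, tau_close_ampa, tau_open_nmda, tau_close_nmda) <= 0))
    stop("synaptic time constants must be positive")
  if (tau_close_ampa <= tau_open_ampa || tau_close_nmda <= tau_open_nmda)
    stop("decay time constant must exceed rise time constant")
  structure(list(gmax_ampa = gmax_ampa, gmax_nmda = gmax_nmda, e_rev = e_rev,
                 tau_open_ampa = tau_open_ampa, tau_close_ampa = tau_close_ampa,
                 tau_open_nmda = tau_open_nmda, tau_close_nmda = tau_close_nmda,
                 mg_vhalf = mg_vhalf, mg_slope = mg_slope),
            class = "synapse_params")
}

#' NMDA magnesium-block factor
#'
#' Sigmoidal voltage dependence of the NMDA receptor conductance:
#' `1 / (1 + exp(-(v - vhalf)/slope))`. Strictly increasing in `v`, in (0, 1).
#'
#' @param v membrane potential (mV)
#' @param vhalf,slope half-unblock voltage and slope (mV)
#' @return unblocked fraction
#' @export
mg_block <- function(v, vhalf = -40, slope = 10) {
  1 / (1 + exp(-(v - vhalf) / slope))
}

#' Dual-exponential conductance kernel
#'
#' Closed-form conductance time course of a single synaptic event at t = 0,
#' normalised to peak at `gmax`. Used as the analytic oracle for the
#' event-driven synapse implementation.
#'
#' @param t time since event (ms); values < 0 give 0
#' @param gmax peak conductance (nS)
#' @param tau_open,tau_close rise and decay time constants (ms)
#' @return conductance (nS)
#' @export
syn_kernel <- function(t, gmax, tau_open, tau_close) {
  tp <- log(tau_close / tau_open) * tau_open * tau_close /
    (tau_close - tau_open)
  norm <- exp(-tp / tau_close) - exp(-tp / tau_open)
  ifelse(t < 0, 0, gmax * (exp(-t / tau_close) - exp(-t / tau_open)) / norm)
}

#' Discrete synaptic-strength scaling policy
#'
#' Trial-to-trial (and optionally spike-to-spike) variability of synaptic
#' strength: the maximal conductance of an affected synapse is multiplied by
#' a value drawn uniformly from `value_set` (default 0.8, 0.6, 0.4, 0.2 or 0,
#' where 0 is a transmission failure). `per_trial` draws are made once per
#' synapse at the start of a trial; `per_spike` draws are made afresh at each
#' presynaptic spike; `both` multiplies the two.
#'
#' @param mode "per_trial", "per_spike", "both" or "off"
#' @param value_set the discrete scale values
#' @param classes which edge classes the policy applies to
#' @return an object of class `scaling_policy`
#' @export
scaling_policy <- function(mode = c("per_trial", "per_spike", "both", "off"),
                           value_set = c(0.8, 0.6, 0.4, 0.2, 0),
                           classes = c("dlc_hexn", "hexn_hexn", "hexn_hdin")) {
  mode <- match.arg(mode)
  if (!length(value_set) || any(value_set < 0))
    stop("value_set must be a non-empty set of non-negative factors")
  structure(list(mode = mode, value_set = value_set, classes = classes),
            class = "scaling_policy")
}

#' Draw synaptic scale factors
#'
#' Draws `n` i.i.d. factors uniformly from the policy's value set, using the
#' current R random-number stream. With mode "off" the result is always 1.
#'
#' @param policy a [scaling_policy()]
#' @param n number of draws
#' @return numeric vector of length `n`
#' @export
draw_scale <- function(policy, n = 1) {
  stopifnot(inherits(policy, "scaling_policy"))
  if (policy$mode == "off") return(rep(1, n))
  policy$value_set[sample.int(length(policy$value_set), n, replace = TRUE)]
}

#' Gap-junction current
#'
#' Ohmic, symmetric electrical coupling: the current into cell a is
#' `g * (v_b - v_a)` and into b the exact opposite, so the pair conserves
#' charge.
#'
#' @param g coupling conductance (nS)
#' @param v_a,v_b membrane potentials (mV)
#' @return named vector `c(i_a, i_b)` in pA
#' @export
gap_current <- function(g, v_a, v_b) {
  if (g < 0) stop("gap-junction conductance must be >= 0")
  ia <- g * (v_b - v_a)
  c(i_a = ia, i_b = -ia)
}
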