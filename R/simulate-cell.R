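#' Simulate a single neuron
#'
#' Integrates one cell (optionally two-compartment) with step-current
#' injection and/or a train of synaptic events delivered to the soma.
#' This is the workhorse behind the cell-contract measurements (resting
#' potential, rheobase, spike width, depolarisation block).
#'
#' @param spec a [neuron_spec()]
#' @param duration simulation length (ms)
#' @param dt integration step (ms)
#' @param i_inj either a single number (pA, constant from 0 to duration) or a
#'   data.frame with columns `amp`, `t_on`, `t_off` (pA, ms); injected into
#'   the soma
#' @param syn_events optional data.frame with columns `t` (ms) and `scale`;
#'   each row triggers the synapse described by `synapse` onto the soma
#' @param synapse a [synapse_params()] used for `syn_events`
#' @param v0 initial voltage (mV); default the leak reversal, with gating at
#'   steady state for that voltage
#' @param out_every store voltages every `out_every` steps
#' @return list with `times`, `v` (matrix, one column per compartment),
#'   `spikes` (data.frame compartment/t for upward 0 mV crossings) and
#'   `ok`/`abort_time`
#' @export
simulate_cell <- function(spec, duration = 500, dt = 0.025, i_inj = 0,
                          syn_events = NULL, synapse = NULL, v0 = NULL,
                          out_every = 4L) {
  stopifnot(inherits(spec, "neuron_spec"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive and finite")
  if (!is.null(v0) && any(!is.finite(v0))) stop("initial state must be finite")
  asm <- .assemble_cells(list(spec), v0 = if (is.null(v0)) NULL else list(v0))
  if (is.numeric(i_inj) && length(i_inj) == 1)
    i_inj <- data.frame(amp = i_inj, t_on = 0, t_off = duration)
  inj <- cbind(1, i_inj$amp, i_inj$t_on, i_inj$t_off)
  inj <- inj[inj[, 2] != 0, , drop = FALSE]

  chem <- matrix(0, 0, 11)
  ext <- matrix(0, 0, 2)
  nsrc <- integer(0)
  if (!is.null(syn_events) && nrow(syn_events)) {
    if (is.null(synapse)) stop("syn_events requires a synapse_params object")
    if (is.null(syn_events$scale)) syn_events$scale <- 1
    # one external source per event so each can carry its own scale
    chem <- do.call(rbind, lapply(seq_len(nrow(syn_events)), function(j)
      c(j, 1, synapse$gmax_ampa, synapse$gmax_nmda, synapse$e_rev,
        synapse$tau_open_ampa, synapse$tau_close_ampa,
        synapse$tau_open_nmda, synapse$tau_close_nmda,
        syn_events$scale[j], 0)))
    ext <- cbind(seq_len(nrow(syn_events)), syn_events$t)
    ext <- ext[order(ext[, 2]), , drop = FALSE]
  }

  mg <- if (is.null(synapse)) c(-40, 10) else
    c(synapse$mg_vhalf, synapse$mg_slope)
  res <- cpp_run_network(asm$comp, asm$kinetics, asm$coupling, chem,
                         integer(0), ext, inj,
                         detect_comp = seq_len(nrow(asm$comp)),
                         record_comp = seq_len(nrow(asm$comp)),
                         dt = dt, duration = duration,
                         out_every = as.integer(out_every),
                         value_set = numeric(0),
                         mg_vhalf = mg[1], mg_slope = mg[2],
                         spike_thresh = 0, min_isi = 1,
                         record_gsyn = !is.null(syn_events))
  n <- res$n_out
  out <- list(times = res$times[seq_len(n)],
              v = res$v[seq_len(n), , drop = FALSE],
              spikes = data.frame(compartment = res$spikes[, 1],
                                  t = res$spikes[, 2]),
              ok = res$ok, abort_time = res$abort_time)
  if (!is.null(syn_events)) {
    out$g_ampa <- rowSums(res$g_ampa[seq_len(n), , drop = FALSE])
    out$g_nmda <- rowSums(res$g_nmda[seq_len(n), , drop = FALSE])
  }
  if (!res$ok)
    warning(sprintf("numerical blow-up (|v| > 200 mV) at t = %.3f ms",
                    res$abort_time))
  out
}

#' Resting potential of a cell model
#'
#' Relaxes the cell from the leak reversal potential with no input and
#' returns the final somatic voltage. Flags non-convergence (spontaneous
#' oscillation at rest) with a warning and an `oscillating` attribute.
#'
#' @param spec a [neuron_spec()]
#' @param duration relaxation time (ms), at least 500
#' @param dt integration step (ms)
#' @return resting potential (mV) with attribute `oscillating`
#' @export
resting_potential <- function(spec, duration = 800, dt = 0.025) {
  if (duration < 500) stop("relaxation must run for at least 500 ms")
  sim <- simulate_cell(spec, duration = duration, dt = dt, out_every = 20L)
  tail_idx <- sim$times >= duration - 100
  drift <- diff(range(sim$v[tail_idx, 1]))
  osc <- drift > 0.5 || nrow(sim$spikes) > 0
  if (osc) warning("cell does not settle to a stable resting potential")
  structure(sim$v[length(sim$times), 1], oscillating = osc)
}

#' Rheobase by bisection on step-current amplitude
#'
#' Brackets the smallest constant current that elicits at least one spike
#' within `duration` ms, to within `tol` pA.
#'
#' @param spec a [neuron_spec()]
#' @param lo,hi initial bracket (pA); `hi` must be suprathreshold
#' @param tol bracket width at termination (pA)
#' @param duration,dt simulation settings (ms)
#' @return list with `rheobase` (midpoint), `lo`, `hi`
#' @export
rheobase <- function(spec, lo = 0, hi = 500, tol = 1, duration = 300,
                     dt = 0.025) {
  fires <- function(amp) {
    rest <- as.numeric(resting_potential(spec))
    sim <- simulate_cell(spec, duration = duration, dt = dt, i_inj = amp,
                         v0 = rest)
    nrow(sim$spikes) > 0
  }
  if (fires(lo)) stop("lower bracket already suprathreshold")
  if (!fires(hi)) stop("upper bracket subthreshold; increase hi")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  list(rheobase = (lo + hi) / 2, lo = lo, hi = hi)
}

#' Spike width at a reference voltage
#'
#' Width of the first spike in a voltage trace, measured as the time between
#' the upward and downward crossings of `at` (default 0 mV), with linear
#' interpolation at both edges.
#'
#' @param times,v trace (ms, mV)
#' @param at reference voltage (mV)
#' @return width (ms), or NA if there is no complete crossing pair
#' @export
spike_width_at <- function(times, v, at = 0) {
  up <- which(v[-length(v)] < at & v[-1] >= at)
  if (!length(up)) return(NA_real_)
  i <- up[1]
  t_up <- times[i] + (times[i + 1] - times[i]) * (at - v[i]) / (v[i + 1] - v[i])
  dn <- which(v[-length(v)] >= at & v[-1] < at)
  dn <- dn[dn >= i + 1]
  if (!length(dn)) return(NA_real_)
  j <- dn[1]
  t_dn <- times[j] + (times[j + 1] - times[j]) * (at - v[j]) / (v[j + 1] - v[j])
  t_dn - t_up
}
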