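#' Channel set for a Hodgkin-Huxley compartment
#'
#' Maximal conductances and reversal potentials for the three active currents
#' (fast sodium, fast potassium, slow potassium) plus leak. Units: nS and mV.
#'
#' @param gbar_na,gbar_kfast,gbar_kslow,gbar_leak maximal conductances (nS)
#' @param e_na,e_k,e_leak reversal potentials (mV)
#' @return an object of class `channel_set`
#' @export
channel_set <- function(gbar_na, gbar_kfast, gbar_kslow, gbar_leak,
                        e_na = 50, e_k = -77, e_leak = -54.4) {
  g <- c(gbar_na = gbar_na, gbar_kfast = gbar_kfast,
         gbar_kslow = gbar_kslow, gbar_leak = gbar_leak)
  e <- c(e_na = e_na, e_k = e_k, e_leak = e_leak)
  if (any(!is.finite(g)) || any(g < 0))
    stop("all conductances must be finite and >= 0")
  if (any(!is.finite(e))) stop("reversal potentials must be finite")
  if (e_na <= e_k) stop("e_na must exceed e_k")
  structure(c(as.list(g), as.list(e)), class = "channel_set")
}

# Gate rate tables use the generalised form
#   r(V) = (A + B*V) / (C + exp((D + V)/E))
# one row per rate: alpha_m, beta_m, alpha_h, beta_h, alpha_n, beta_n,
# alpha_s, beta_s; columns A..E.  Voltage dependences can be shifted per
# gate: `shift` moves the Na/K activation gates (m, n), `h_shift` the Na
# inactivation gate and `n_shift` (default = shift) the delayed rectifier,
# so that spike threshold, inactivation range and resting K shunt can be
# placed independently, as the cell contracts require.
.rate_table <- function(shift = 0, h_shift = shift, n_shift = shift,
                        s_vhalf = -20, s_alpha = 0.05,
                        s_beta = 0.002, s_slope = 5) {
  r <- rbind(
    alpha_m = c(-4,    -0.1,  -1, 40, -10),
    beta_m  = c( 4,     0,     0, 65,  18),
    alpha_h = c( 0.07,  0,     0, 65,  20),
    beta_h  = c( 1,     0,     1, 35, -10),
    alpha_n = c(-0.55, -0.01, -1, 55, -10),
    beta_n  = c( 0.125, 0,     0, 65,  80),
    alpha_s = c( s_alpha, 0,   1, -s_vhalf, -s_slope),
    beta_s  = c( s_beta,  0,   0, 0,  1e6)
  )
  colnames(r) <- c("A", "B", "C", "D", "E")
  # shifting V by +s is D -> D - s (and A -> A - B*s where B != 0, to keep
  # the removable singularities aligned)
  r[1:2, "D"] <- r[1:2, "D"] - shift
  r[1, "A"] <- r[1, "A"] + 0.1 * shift
  r[3:4, "D"] <- r[3:4, "D"] - h_shift
  r[5:6, "D"] <- r[5:6, "D"] - n_shift
  r[5, "A"] <- r[5, "A"] + 0.01 * n_shift
  r
}

#' Gating kinetics for the package's cell models
#'
#' Returns the rate-function table, gate exponents and per-gate speed factors
#' for one of the built-in kinetic families. `motoneuron` is the generic
#' unspecialised tadpole neuron used for hexNs (repetitive firing);
#' `hdin_monitor` and `hdin_population` are the reticulospinal hdIN families
#' (depolarised rest, single broad spike, strong slow-K adaptation; the
#' population variant has a faster-deactivating slow K so it can fire
#' rhythmically under sustained network excitation).
#'
#' @param name one of "motoneuron", "hdin_monitor", "hdin_population"
#' @return list with elements `rates` (8 x 5 matrix), `powers` (length-4
#'   integer: exponents of m, h, n, s) and `rate_scale` (length-4 numeric)
#' @export
cell_kinetics <- function(name = c("motoneuron", "hdin_monitor",
                                   "hdin_population")) {
  name <- match.arg(name)
  switch(name,
    # high spike threshold (~-45 mV) with Na inactivation placed well above
    # it, so the cell can fire repetitively on an NMDA-driven plateau; a
    # weak slow K current paces and desynchronises repetitive firing
    motoneuron = list(
      rates = .rate_table(shift = 10, h_shift = 30, s_beta = 0.02),
      powers = c(3L, 1L, 4L, 1L),
      rate_scale = c(1, 1, 1, 1)),
    # hdIN: still higher threshold (summation target), delayed rectifier
    # shifted out of the resting range so slow synaptic summation is not
    # shunted, strong slow K for single-spike firing
    hdin_monitor = list(
      rates = .rate_table(shift = 20, n_shift = 24, s_vhalf = -20,
                          s_alpha = 0.05, s_beta = 0.002, s_slope = 3),
      powers = c(3L, 1L, 4L, 1L),
      rate_scale = c(0.9, 0.9, 0.9, 1)),
    hdin_population = list(
      rates = .rate_table(shift = 20, n_shift = 24, s_vhalf = -20,
                          s_alpha = 0.05, s_beta = 0.03, s_slope = 3),
      powers = c(3L, 1L, 4L, 1L),
      rate_scale = c(0.9, 0.9, 0.9, 1))
  )
}

#' Neuron specification
#'
#' Parameters of a model cell: one or two Hodgkin-Huxley compartments with a
#' channel set, gating kinetics, per-compartment capacitance and, for
#' two-compartment cells, the inter-compartment link conductance and the
#' factor by which active conductances are scaled up in the axonal
#' compartment.
#'
#' @param role one of "hexn", "hdin_monitor", "hdin_population",
#'   "motoneuron_reference"
#' @param channels a [channel_set()] (somatic values)
#' @param kinetics a kinetics list as returned by [cell_kinetics()]
#' @param n_compartments 1 or 2
#' @param capacitance per-compartment capacitance (pF)
#' @param link_conductance soma-axon coupling conductance (nS), two-compartment
#'   cells only
#' @param axon_scale factor applied to the active (Na, K_fast, K_slow)
#'   conductances in the axonal compartment
#' @return an object of class `neuron_spec`
#' @export
neuron_spec <- function(role, channels, kinetics, n_compartments = 1,
                        capacitance = 5, link_conductance = 10,
                        axon_scale = 5) {
  stopifnot(inherits(channels, "channel_set"))
  if (!n_compartments %in% c(1, 2)) stop("n_compartments must be 1 or 2")
  if (capacitance <= 0) stop("capacitance must be positive")
  if (role == "hexn") {
    if (n_compartments != 2) stop("hexn cells have exactly 2 compartments")
    if (capacitance != 5) stop("hexn compartments have capacitance 5 pF")
    if (link_conductance != 10) stop("hexn link conductance is 10 nS")
  }
  structure(list(role = role, channels = channels, kinetics = kinetics,
                 n_compartments = as.integer(n_compartments),
                 capacitance = capacitance,
                 link_conductance = link_conductance,
                 axon_scale = axon_scale),
            class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat(sprintf("<neuron_spec: %s, %d compartment(s), C = %g pF>\n",
              x$role, x$n_compartments, x$capacitance))
  invisible(x)
}

#' Generic motoneuron-property reference cell
#'
#' Single Hodgkin-Huxley compartment with the membrane properties of an
#' unspecialised tadpole neuron: fires repetitively to sustained
#' suprathreshold current. Used as the somatic channel set of the hexN model.
#'
#' @param channels optional [channel_set()] override
#' @return a `neuron_spec`
#' @export
make_motoneuron_reference <- function(channels = NULL) {
  if (is.null(channels))
    channels <- channel_set(gbar_na = 600, gbar_kfast = 180,
                            gbar_kslow = 2.5, gbar_leak = 3.5,
                            e_leak = -57)
  neuron_spec("motoneuron_reference", channels, cell_kinetics("motoneuron"),
              n_compartments = 1, capacitance = 5)
}

#' Two-compartment hexN cell
#'
#' Hindbrain extension neuron: two electrically linked compartments (combined
#' dendrites/soma, and axon) with motoneuron-property channels. Active
#' conductances in the axonal compartment are `axon_scale` (default 5) times
#' the somatic values; capacitance is 5 pF per compartment and the link
#' conductance 10 nS. The axonal compartment lets the cell keep firing when
#' the soma is held depolarised by strong synaptic input (no depolarisation
#' block), which a single-compartment cell cannot do.
#'
#' @param channels optional somatic [channel_set()] (defaults to the
#'   motoneuron reference set)
#' @param axon_scale multiplier for active conductances in the axon
#' @return a `neuron_spec`
#' @export
make_hexn <- function(channels = NULL, axon_scale = 5) {
  if (is.null(channels))
    channels <- channel_set(gbar_na = 600, gbar_kfast = 180,
                            gbar_kslow = 2.5, gbar_leak = 3.5,
                            e_leak = -57)
  neuron_spec("hexn", channels, cell_kinetics("motoneuron"),
              n_compartments = 2, capacitance = 5, link_conductance = 10,
              axon_scale = axon_scale)
}

#' Reticulospinal hdIN cell
#'
#' Reduced single-compartment model of a hindbrain descending interneuron,
#' calibrated to the physiological contract for these cells: resting
#' potential near -51 mV, a single broad spike (about 2 ms wide at 0 mV) in
#' response to sustained depolarising current of any suprathreshold
#' amplitude, no repetitive firing (monitor variant). The population variant
#' has a faster-deactivating slow potassium conductance so that, embedded in
#' a gap-junction-coupled population with feedback glutamatergic excitation,
#' it can be recruited into rhythmic firing.
#'
#' @param variant "monitor" (output monitor, 5-cell stage) or "population"
#'   (30-cell coupled population stage)
#' @param channels optional [channel_set()] override
#' @return a `neuron_spec`
#' @export
make_hdin <- function(variant = c("monitor", "population"), channels = NULL) {
  variant <- match.arg(variant)
  if (is.null(channels))
    channels <- channel_set(gbar_na = if (variant == "monitor") 1000 else 1400,
                            gbar_kfast = 180, gbar_kslow = 180,
                            gbar_leak = 1.0, e_na = 50, e_k = -72,
                            e_leak = -53.5)
  kin <- cell_kinetics(paste0("hdin_", variant))
  neuron_spec(paste0("hdin_", variant), channels, kin, n_compartments = 1,
              capacitance = 12)
}

# --- compartment-table assembly (internal) ----------------------------------

# Expand a list of neuron specs into the engine's compartment matrix, the
# deduplicated kinetics list, intra-cell link edges, and per-neuron soma/axon
# compartment indices.
.assemble_cells <- function(specs, v0 = NULL) {
  kin_list <- list()
  kin_key <- character()
  kin_index <- function(k) {
    key <- paste(c(k$rates, k$powers, k$rate_scale), collapse = ",")
    i <- match(key, kin_key)
    if (is.na(i)) {
      kin_list[[length(kin_list) + 1]] <<- k
      kin_key[length(kin_key) + 1] <<- key
      i <- length(kin_list)
    }
    i
  }
  rows <- list(); links <- list()
  soma <- integer(length(specs)); axon <- integer(length(specs))
  nc <- 0L
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    ch <- s$channels
    ki <- kin_index(s$kinetics)
    vstart <- if (is.null(v0)) ch$e_leak else v0[[i]]
    soma_row <- c(s$capacitance, ch$gbar_na, ch$gbar_kfast, ch$gbar_kslow,
                  ch$gbar_leak, ch$e_na, ch$e_k, ch$e_leak, ki, vstart[1])
    nc <- nc + 1L; soma[i] <- nc; rows[[nc]] <- soma_row
    if (s$n_compartments == 2) {
      ax <- soma_row
      ax[2:4] <- ax[2:4] * s$axon_scale       # active gbars only
      ax[10] <- if (length(vstart) > 1) vstart[2] else vstart[1]
      nc <- nc + 1L; axon[i] <- nc; rows[[nc]] <- ax
      links[[length(links) + 1]] <- c(soma[i], axon[i], s$link_conductance)
    } else {
      axon[i] <- soma[i]
    }
  }
  comp <- do.call(rbind, rows)
  colnames(comp) <- c("cm", "g_na", "g_kf", "g_ks", "g_leak",
                      "e_na", "e_k", "e_leak", "kin", "v0")
  coupling <- if (length(links)) do.call(rbind, links) else
    matrix(0, 0, 3)
  list(comp = comp, kinetics = kin_list, coupling = coupling,
       soma = soma, axon = axon)
}
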