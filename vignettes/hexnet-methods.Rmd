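---
title: "Model and measurement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and measurement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hexnet)
```

## The scientific problem

When a hatchling *Xenopus* tadpole is touched it decides whether to swim,
and it does so slowly and unreliably: the first motor response follows the
stimulus by tens to hundreds of milliseconds, with large trial-to-trial
variability. The sensory side of the pathway cannot explain this: skin
sensory neurons and the commissural sensory-pathway neurons (DLCs) fire
single, short-latency, highly reliable spikes. The reticulospinal hindbrain
descending interneurons (hdINs) that start and drive swimming instead
receive a *prolonged, noisy barrage of EPSPs* lasting close to a second,
which summates towards firing threshold. `hexnet` implements the circuit
hypothesis for where that barrage comes from: a small recurrent excitatory
network of hypothetical "hindbrain extension neurons" (hexNs), interposed
between the sensory pathway and the hdINs, that converts a brief,
near-synchronous sensory volley into extended, variable firing — a simple
sensory memory — and drives hdINs as accumulate-to-threshold decision
units.

The package contains four things: conductance-based cell models and a
fixed-step network simulator (C++ core); builders for the random circuit;
the electrophysiological measurement procedures (spike and EPSP detection,
latency statistics, response averaging); and a synthetic whole-cell
recording generator calibrated to the recorded statistics, so that every
measurement procedure is testable against embedded ground truth without any
recorded data.

## Circuit architecture and stated parameters

Thirty DLC input neurons each fire exactly once per trial, at times drawn
from a normal law (mean 5 ms, SD 2 ms) resampled until above 5 ms. They
excite 30 hexNs with independent Bernoulli probability 0.4 (AMPA 1.1 nS,
NMDA 1.4 nS per synapse). Each hexN receives recurrent input from a number
of other hexNs drawn as the floor of a normal variable (mu = sigma = 3,
clamped to the feasible range; negative draws clamp to zero), partners
chosen uniformly without self- or duplicate connections (AMPA 1.5 nS, NMDA
1.8 nS). Five *monitor* hdINs, not connected to each other, sample the core
with probability 0.2 (AMPA 0.25 nS, NMDA 0.1 nS). Separately, a 30-cell
hdIN *population*, electrically coupled and with recurrent glutamatergic
feedback, receives input from exactly 3 randomly chosen hexNs per cell
(AMPA 0.125 nS, NMDA 0.15 nS), replaying the hexN spike times from the
first-stage simulation (two-stage pipeline).

Synaptic-strength noise is the only trial-to-trial variability: at the
start of each trial every affected synapse's maximal conductance is
multiplied by a factor drawn uniformly from {0.8, 0.6, 0.4, 0.2, 0}
(0 being a transmission failure). A per-spike variant redraws the factor at
every presynaptic spike; both can be combined multiplicatively
(`scaling_policy()`; the default is per-trial only).

Each hexN has two compartments of 5 pF (dendrites/soma, axon) linked by
10 nS, with all active maximal conductances five times larger in the axon.
This reproduces the stated design rationale: under strong synaptic
depolarisation a single-compartment cell falls silent through
depolarisation block, while the two-compartment cell's axon keeps firing
(a regression test asserts the dichotomy). Integration is exponential
Euler for both gating and membrane (the conductance-implicit form is
needed for stability with the five-fold axonal conductances at dt =
0.025 ms); the hexN-network stage runs at 0.025 ms and the hdIN-population
stage at 0.1 ms. Units project-wide: mV, ms, nS, pF, pA, so
`dv/dt = (sum of currents)/C` directly.

## Cell models: calibration to contracts

The source publications for the hexN ("generic motoneuron-property" cell)
and hdIN channel kinetics do not print the rate functions, so the package
calibrates generic Hodgkin-Huxley-style kinetics to the cells' functional
contracts, which are the tested surface:

* **motoneuron-property / hexN**: repetitive firing to sustained
  suprathreshold current; when embedded in the network, a high spike
  threshold (about −45 mV, far above rest) with sodium inactivation placed
  well above threshold, so that the cell can fire repetitively on an
  NMDA-driven depolarised plateau. A weak, slowly deactivating slow-K
  conductance paces and desynchronises that firing.
* **hdIN (monitor and population)**: resting potential within the measured
  −50.9 ± 4.9 mV; a single broad spike (about 2 ms wide at 0 mV) to
  depolarising current of any tested suprathreshold amplitude, enforced by
  a strong slow-K adaptation conductance; a membrane slow enough to
  summate the barrage (12 pF, input conductance about 1 nS at rest, with
  the delayed rectifier shifted out of the resting range so it does not
  shunt slow summation); a full-scale unitary hexN EPSP of about 2.2 mV,
  at the top of the recorded 0.6–2.3 mV range, with scale draws spanning
  the rest of it.

All rate functions use the generalised form
$r(V) = (A + BV) / (C + e^{(D+V)/E})$, which covers the classic
alpha/beta functions as well as sigmoidal and exponential rates; per-gate
voltage shifts place threshold, inactivation and the delayed rectifier
independently. The tables are plain data (`cell_kinetics()`), serializable
with the rest of a `neuron_spec`.

NMDA receptors use a dual-exponential conductance (rise 10 ms, decay 90 ms
at most synapse classes) under a sigmoidal voltage-dependent magnesium
block with half-unblock at −40 mV (slope 10 mV). These are calibration
parameters from the cited prior models, which this source does not print;
the half-unblock voltage is deliberately in the subthreshold range, which
is what lets recurrent NMDA act regeneratively and ignite the extended
plateau firing that is the network's memory mechanism. AMPA uses
0.2 ms rise / 2 ms decay. The monitor-hdIN synapse class uses a slower
NMDA rise (25 ms) and faster decay (60 ms), calibrated so the summation
envelope — and with it the first-spike delay distribution — stays on the
physiological time scale. All synapse parameters are config-exposed.

## What a trial looks like

The DLC volley fires most hexNs once within the first ~15 ms (the early
peak of the firing-time histogram). The per-synapse NMDA conductances it
leaves behind, plus recurrent NMDA from every subsequent hexN spike, hold
a subset of cells on a depolarised plateau from which the axonal
compartments keep firing; whether the recurrent loop gain is above or
below one in a given trial is decided entirely by that trial's discrete
scale draws. Trials therefore split into brief, transient network
responses and sustained ones lasting the whole trial, with a continuum in
between — extended and variable firing from an invariant stimulus.

The monitor hdINs integrate this output as slow, noisy summation. Their
first-spike delays over 30 trials span roughly 35–200 ms with a
substantial fraction of trials never reaching threshold, reproducing the
long, variable decision delays; both the range and the mixture are
asserted by the acceptance tests at the default study conditions (network
seed 1, 30 trials, 1400 ms per trial, covering the >1 s physiological
depolarisation).

The population stage replays hexN spikes into the coupled hdIN population.
Recruitment is operationalised as the first cycle in which every cell
fires within a 10 ms window (the source reports recruitment delays without
an explicit criterion); the synchrony metric is the per-cycle spike-time
SD, cycles being gap-separated clusters (20 ms) of the pooled spike train,
with "synchronous" meaning a median per-cycle SD below 2 ms. With the
default coupling (0.3 nS to 8 chain neighbours on each side — the
coupling topology and conductance are not printed in the source and are
calibrated to the synchrony dichotomy) the population is recruited at
about 40–75 ms into near-synchronous rhythmic cycles sustained by feedback
excitation; removing the electrical coupling yields earlier, continuous,
unsynchronised firing with a per-cycle SD more than five times larger.

## Synthetic recordings and measurement procedures

The generator (`synth_epsp_trace()`, `synth_spiking_trace()`,
`synth_delay_samples()`) emulates the study's whole-cell recordings:

* **Amplitudes**: log-normal, median fixed at 2.3 mV exactly and sdlog set
  from the 1.2–4.1 mV IQR ratio (implied quartiles within ~4% of the
  targets; a two-parameter law cannot match all three quartiles at once).
* **Event times**: a small early Gaussian component (peak near 17 ms,
  matching the observed 10–25 ms peak of occurrences) plus an exponential
  tail whose time constant is calibrated *deterministically* — the
  expected envelope (event-time density convolved with the EPSP kernel) is
  measured with the package's own `average_and_half_fall()` and the tail
  constant solved so the half-fall equals the target (158 ms trunk-like,
  272 ms head-like). The solve brackets a sign change on the rising branch
  because the measured half-fall is not monotone in the tail constant.
* **Baseline noise**: AR(1) with marginal SD 0.44 mV and a 12 ms
  correlation time (membrane-filtered noise at the cell's time constant;
  white noise at the sample interval would be physiologically wrong and
  make sub-millivolt events undetectable in principle).
* **Delays**: three-parameter shifted log-normal solved in closed form so
  all three printed quartiles (behavioural 102 [81–136]; fictive 40
  [33–61]; hdIN first spike 35.4 [27.8–65.7] ms) match exactly.

The measurement procedures implement the study's definitions. EPSP
amplitude is the peak change in membrane potential between the starts of
successive events, so overlapping EPSPs are measured from each event's own
start, not from baseline. Onset detection uses local maxima of a
Savitzky-Golay derivative (4 ms window) over a running-median trend
correction (40 ms) that lets events riding on a decaying summation
shoulder be seen; the slope threshold (0.3 mV/ms) comes from the
noise-only false-positive calibration (< 1 false event/s at the recorded
0.44 mV fluctuation) while retaining at least 90% sensitivity for events
of 1 mV and larger. Summary statistics are median with
linear-interpolation quartiles (the source's statistics package does not
state its convention), mean, SD (n−1) and CV = SD/mean; the package
implements SD/mean throughout, the standard definition, although one
passage of the source's methods text inverts it.

When few responses are averaged, the measured peak of the mean response is
biased upward by noise on an almost-flat peak, which shortens the measured
half-fall; `average_and_half_fall()` therefore accepts an optional
smoothing window, and the generator round-trip checks use 200 traces with
20 ms smoothing (recovery within 15%).

## Numerical and design choices

* Exponential Euler throughout; halving dt from 0.025 to 0.0125 ms moves
  spike times by less than 0.1 ms (tested). Trials abort with a diagnostic
  if any voltage exceeds ±200 mV.
* Presynaptic events are positive-going 0 mV crossings of the axonal
  compartment with a 1 ms minimum inter-event interval; crossing times are
  refined by linear interpolation.
* Scale factors multiply the maximal conductance (so 0 is a transmission
  failure); per-trial and per-spike draws compose multiplicatively in
  "both" mode.
* Scaling applies by default to the sensory, recurrent and hexN-to-hdIN
  synapse classes; the recorded 0.6–2.3 mV unitary-EPSP span presupposes
  scaled hexN-to-hdIN synapses.
* Seed architecture: a master seed deterministically derives the build,
  stimulus and per-trial noise streams
  (`trial_seed_i = (master * 1000003 + 7919 i) mod (2^31 − 2) + 1`); every
  result carries its seeds, and replay is bit-identical.
* Problem sizes used by the tests and the reproduction script: 30 trials
  of 1400 ms for the delay distribution, 10 population trials, 1e5 draws
  for distributional checks, 200 traces for envelope recovery.

## Known limitations

* The cell kinetics are calibrated to the stated functional contracts, not
  fitted to the original (unprinted) parameter tables; quantities outside
  the contracts — rheobase values, exact firing rates, the population
  rhythm period — are not calibrated and should not be over-interpreted.
  The rhythm of the recruited population is asserted to be rhythmic and
  synchronous, not to have a specific frequency.
* Trial outcomes depend on the random wiring of the particular network
  instance. Networks whose monitor hdINs happen to draw many inputs show
  occasional early first spikes, and sparsely monitored networks can go a
  full 30-trial experiment without a monitor spike; the acceptance checks
  run at the default study conditions (build seed 1), and the reproduction
  script reports whatever its seed produces.
* The generator reproduces amplitude/timing statistics and the summation
  envelope, not biophysics: its events are stereotyped kernels, its noise
  is stationary, and electrode artefacts are not modelled. Passing
  round-trip tests on synthetic data validates the measurement procedures,
  not the model's biological fidelity.
* Cholinergic co-transmission of hdINs, reciprocal inhibition and
  side-choice, and the spinal CPG below the hdINs are out of scope.
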