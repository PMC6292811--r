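#' Fit a log-normal amplitude law from a median and IQR
#'
#' Two-parameter log-normal with the median matched exactly
#' (`meanlog = log(median)`) and `sdlog` chosen from the IQR ratio,
#' `sdlog = log(iqr[2]/iqr[1]) / (2 z_0.75)`. With the recorded EPSP
#' statistics (median 2.3 mV, IQR 1.2-4.1 mV) the implied quartiles are
#' within about 4% of the targets.
#'
#' @param median target median
#' @param iqr length-2 target interquartile range
#' @return list with `meanlog`, `sdlog`
#' @export
fit_lognormal_amplitude <- function(median = 2.3, iqr = c(1.2, 4.1)) {
  if (median <= 0 || any(iqr <= 0) || iqr[2] <= iqr[1])
    stop("median and IQR must be positive with iqr[2] > iqr[1]")
  list(meanlog = log(median),
       sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

#' Fit a shifted log-normal from three quartiles
#'
#' Three-parameter (shifted) log-normal whose 25th, 50th and 75th
#' percentiles equal the given values exactly:
#' `shift = (q25 q75 - q50^2) / (q25 + q75 - 2 q50)`, then `meanlog` and
#' `sdlog` from the shifted quartiles in closed form. Used for the
#' response-delay laws, which are reported as median with IQR.
#'
#' @param q numeric length-3: 25th, 50th, 75th percentiles
#' @return list with `shift`, `meanlog`, `sdlog` and a `quantile` function
#' @export
fit_shifted_lognormal <- function(q) {
  stopifnot(length(q) == 3, all(diff(q) > 0))
  denom <- q[1] + q[3] - 2 * q[2]
  if (abs(denom) < 1e-12) stop("quartiles are symmetric; no unique shift")
  shift <- (q[1] * q[3] - q[2]^2) / denom
  if (shift >= q[1]) stop("implied shift is not below the lower quartile")
  meanlog <- log(q[2] - shift)
  sdlog <- log((q[3] - shift) / (q[2] - shift)) / stats::qnorm(0.75)
  list(shift = shift, meanlog = meanlog, sdlog = sdlog,
       quantile = function(p) shift + stats::qlnorm(p, meanlog, sdlog))
}

# printed delay quartiles (ms) per recording kind
.delay_targets <- list(
  behavioural = c(81, 102, 136),
  fictive = c(33, 40, 61),
  hdin_spike = c(27.8, 35.4, 65.7))

#' Sample synthetic response delays
#'
#' Draws right-skewed response delays from a shifted log-normal calibrated so
#' the population quartiles match the measured values for the chosen kind:
#' behavioural first-flexion delays (median 102, IQR 81-136 ms), fictive
#' swimming ventral-root delays (40, 33-61 ms) or hdIN first-spike delays
#' (35.4, 27.8-65.7 ms).
#'
#' @param kind "behavioural", "fictive" or "hdin_spike"
#' @param n number of samples
#' @return numeric vector of delays (ms, all positive)
#' @export
synth_delay_samples <- function(kind = c("behavioural", "fictive",
                                         "hdin_spike"), n = 1) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  fit <- fit_shifted_lognormal(.delay_targets[[kind]])
  fit$shift + stats::rlnorm(n, fit$meanlog, fit$sdlog)
}

#' Parameters of the synthetic whole-cell recording generator
#'
#' Describes a synthetic hdIN voltage trace: a quiescent baseline with small
#' correlated noise (SD 0.44 mV, the measured resting fluctuation), plus a
#' train of EPSP-like events. Event amplitudes follow the log-normal law
#' fitted to the recorded statistics (median 2.3 mV, IQR 1.2-4.1 mV). Event
#' times mix an early Gaussian component (peak of occurrences between 10 and
#' 25 ms) with an exponential tail whose time constant is calibrated, by a
#' deterministic expected-envelope computation, so that the averaged
#' response measured with [average_and_half_fall()] has the configured
#' half-fall time (158 ms for trunk-stimulus-like traces, 272 ms for
#' head-stimulus-like ones).
#'
#' @param kind "trunk" or "head" preset (sets the half-fall target)
#' @param baseline_sd baseline fluctuation SD (mV)
#' @param noise_tau baseline noise correlation time (ms); the default
#'   matches membrane-filtered noise at the cell's time constant
#' @param amp_median,amp_iqr EPSP amplitude law targets (mV)
#' @param n_events expected number of events per trace
#' @param frac_early fraction of events in the early Gaussian component
#' @param early_mean,early_sd early component parameters (ms)
#' @param tail_t0 offset of the exponential tail (ms)
#' @param half_fall_target target half-fall time of the averaged response
#'   (ms); overrides the preset when given
#' @param kernel_rise,kernel_decay EPSP kernel time constants (ms)
#' @param rest resting potential of the synthetic cell (mV)
#' @param dt sample interval (ms)
#' @param duration post-stimulus trace length (ms)
#' @param baseline_ms pre-stimulus baseline length (ms)
#' @param spike_threshold depolarisation (mV above rest) at which
#'   [synth_spiking_trace()] inserts a spike
#' @return object of class `synth_trace_params` (with the calibrated
#'   `tail_tau` filled in)
#' @export
synth_trace_params <- function(kind = c("trunk", "head"),
                               baseline_sd = 0.44, noise_tau = 12,
                               amp_median = 2.3, amp_iqr = c(1.2, 4.1),
                               n_events = 30, frac_early = 0.15,
                               early_mean = 17, early_sd = 4,
                               tail_t0 = 10, half_fall_target = NULL,
                               kernel_rise = 1, kernel_decay = NULL,
                               rest = -51, dt = 0.1, duration = 1200,
                               baseline_ms = 100, spike_threshold = 12) {
  kind <- match.arg(kind)
  if (is.null(half_fall_target))
    half_fall_target <- c(trunk = 158, head = 272)[[kind]]
  if (is.null(kernel_decay))
    kernel_decay <- c(trunk = 50, head = 70)[[kind]]
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  p <- list(kind = kind, baseline_sd = baseline_sd, noise_tau = noise_tau,
            amp = fit_lognormal_amplitude(amp_median, amp_iqr),
            amp_median = amp_median, amp_iqr = amp_iqr,
            n_events = n_events, frac_early = frac_early,
            early_mean = early_mean, early_sd = early_sd,
            tail_t0 = tail_t0, half_fall_target = half_fall_target,
            kernel_rise = kernel_rise, kernel_decay = kernel_decay,
            rest = rest, dt = dt, duration = duration,
            baseline_ms = baseline_ms, spike_threshold = spike_threshold)
  p$tail_tau <- .calibrate_tail_tau(p)
  structure(p, class = "synth_trace_params")
}

# Deterministic calibration of the tail time constant: the expected envelope
# is the event-time density convolved with the EPSP kernel; solve for the tau
# whose measured half-fall equals the target.
.calibrate_tail_tau <- function(p) {
  grid_dt <- 1
  tgrid <- seq(0, p$duration + 1000, by = grid_dt)
  n <- length(tgrid)
  kern <- syn_kernel(seq(0, 12 * p$kernel_decay, by = grid_dt), 1,
                     p$kernel_rise, p$kernel_decay)
  measure <- function(tau) {
    dens <- p$frac_early * stats::dnorm(tgrid, p$early_mean, p$early_sd) +
      (1 - p$frac_early) *
        stats::dexp(pmax(tgrid - p$tail_t0, 0), 1 / tau) *
        (tgrid >= p$tail_t0)
    env <- numeric(n)
    for (i in seq_along(kern)) {
      if (kern[i] == 0) next
      env[i:n] <- env[i:n] + dens[seq_len(n - i + 1)] * kern[i]
    }
    m <- average_and_half_fall(matrix(env, ncol = 1), grid_dt,
                               stim_time = 0)
    m$half_fall
  }
  f <- function(tau) suppressWarnings(measure(tau)) - p$half_fall_target
  # the measured half-fall is not monotone in tau over its whole range
  # (once the tail plateau exceeds half the early peak the measurement
  # jumps); bracket a sign change on the rising branch first
  taus <- seq(40, 400, by = 20)
  vals <- vapply(taus, f, 0)
  ok <- which(!is.na(vals))
  flip <- ok[which(diff(sign(vals[ok])) != 0)[1]]
  if (is.na(flip) || !length(flip))
    stop("half-fall target unreachable for these envelope parameters")
  stats::uniroot(f, c(taus[flip], taus[flip + 1]), tol = 0.5)$root
}

# AR(1) noise with a given marginal SD and correlation time
.baseline_noise <- function(n, dt, sd, tau) {
  if (sd == 0) return(rep(0, n))
  rho <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  sd * x
}

.draw_events <- function(p) {
  n <- p$n_events
  n_early <- rbinom(1, n, p$frac_early)
  early <- numeric(0)
  while (length(early) < n_early) {
    x <- rnorm(n_early - length(early), p$early_mean, p$early_sd)
    early <- c(early, x[x > 0])
  }
  tail_t <- p$tail_t0 + rexp(n - n_early, 1 / p$tail_tau)
  onset <- sort(c(early, tail_t))
  onset <- onset[onset < p$duration]
  amp <- stats::rlnorm(length(onset), p$amp$meanlog, p$amp$sdlog)
  data.frame(onset = onset, amplitude = amp)
}

#' Generate a synthetic subthreshold EPSP trace
#'
#' Builds `trace = rest + baseline noise + sum of kernel(t - onset_i) *
#' amp_i`, with the ground-truth event list embedded in the result. The
#' stimulus is at t = 0; the trace starts `baseline_ms` before it.
#'
#' @param params a [synth_trace_params()]
#' @return object of class `synthetic_recording`: list with `times`, `v`,
#'   `events` (ground truth onsets/amplitudes), `spike_times` (empty here),
#'   `params`
#' @export
synth_epsp_trace <- function(params = synth_trace_params()) {
  p <- params
  times <- seq(-p$baseline_ms, p$duration, by = p$dt)
  n <- length(times)
  noise <- .baseline_noise(n, p$dt, p$baseline_sd, p$noise_tau)
  events <- .draw_events(p)
  depol <- rep(0, n)
  for (j in seq_len(nrow(events))) {
    i0 <- which(times >= events$onset[j])[1]
    if (is.na(i0)) next
    idx <- i0:n
    depol[idx] <- depol[idx] +
      syn_kernel(times[idx] - events$onset[j], events$amplitude[j],
                 p$kernel_rise, p$kernel_decay)
  }
  structure(list(times = times, v = p$rest + noise + depol,
                 depol = depol, events = events,
                 spike_times = numeric(0), params = p),
            class = "synthetic_recording")
}

#' Generate a synthetic trace with a threshold-triggered spike
#'
#' Like [synth_epsp_trace()], but when the noise-free summed depolarisation
#' first crosses `spike_threshold` (mV above rest) a stereotyped spike
#' waveform is inserted and its ground-truth time (upward 0 mV crossing of
#' the noise-free trace) is recorded. If the summation never reaches
#' threshold the output is identical to the subthreshold generator.
#'
#' @param params a [synth_trace_params()]
#' @return a `synthetic_recording` with `spike_times` of length 0 or 1
#' @export
synth_spiking_trace <- function(params = synth_trace_params()) {
  rec <- synth_epsp_trace(params)
  p <- params
  idx <- which(rec$depol >= p$spike_threshold)
  if (!length(idx)) return(rec)
  tc <- rec$times[idx[1]]
  # stereotyped spike: fast gaussian-shaped excursion to ~+28 mV
  wave <- (28 - p$rest) * exp(-((rec$times - tc - 0.8) / 0.6)^2)
  clean <- p$rest + rec$depol + wave
  truth <- detect_spikes(clean, p$dt, threshold = 0,
                         t0 = rec$times[1])[1]
  rec$v <- rec$v + wave
  rec$spike_times <- truth
  rec
}

#' Write / read a synthetic recording as paired CSV files
#'
#' Saves the trace (`<path>_trace.csv`: time_ms, v_mV) and the ground truth
#' (`<path>_events.csv`: onset_ms, amplitude_mV, plus spike times flagged in
#' a `kind` column) for fixture reuse.
#'
#' @param rec a `synthetic_recording`
#' @param path file-path prefix
#' @return `path`, invisibly
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.csv(data.frame(time_ms = rec$times, v_mV = rec$v),
                   paste0(path, "_trace.csv"), row.names = FALSE)
  gt <- data.frame(kind = "epsp", onset_ms = rec$events$onset,
                   amplitude_mV = rec$events$amplitude)
  if (length(rec$spike_times))
    gt <- rbind(gt, data.frame(kind = "spike", onset_ms = rec$spike_times,
                               amplitude_mV = NA_real_))
  utils::write.csv(gt, paste0(path, "_events.csv"), row.names = FALSE)
  invisible(path)
}
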