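test_that("delay laws reproduce the printed quartiles exactly in closed form", {
  targets <- list(behavioural = c(81, 102, 136), fictive = c(33, 40, 61),
                  hdin_spike = c(27.8, 35.4, 65.7))
  for (k in names(targets)) {
    fit <- fit_shifted_lognormal(targets[[k]])
    expect_equal(unname(fit$quantile(c(0.25, 0.5, 0.75))), targets[[k]],
                 tolerance = 1e-4)
  }
  expect_error(synth_delay_samples("nonsense"), "arg")
})

test_that("sampled fictive-swim delays recover the printed median and IQR", {
  set.seed(60)
  x <- synth_delay_samples("fictive", 1e5)
  expect_true(all(x > 0))
  q <- quantile(x, c(0.25, 0.5, 0.75))
  expect_equal(unname(q[2]), 40, tolerance = 40 * 0.05)
  expect_equal(unname(q[1]), 33, tolerance = 33 * 0.05)
  expect_equal(unname(q[3]), 61, tolerance = 61 * 0.05)
  expect_equal(length(synth_delay_samples("fictive", 1)), 1L)
})

test_that("EPSP amplitude law hits the recorded median and IQR", {
  p <- synth_trace_params()
  # closed-form median is exact by construction
  expect_equal(exp(p$amp$meanlog), 2.3)
  set.seed(61)
  a <- rlnorm(1e5, p$amp$meanlog, p$amp$sdlog)
  q <- quantile(a, c(0.25, 0.5, 0.75))
  expect_equal(unname(q[2]), 2.3, tolerance = 2.3 * 0.05)
  expect_equal(unname(q[1]), 1.2, tolerance = 1.2 * 0.05)
  expect_equal(unname(q[3]), 4.1, tolerance = 4.1 * 0.05)
})

test_that("silent generator settings give an identically flat trace", {
  set.seed(62)
  p <- synth_trace_params(baseline_sd = 0, n_events = 0)
  r <- synth_epsp_trace(p)
  expect_true(all(r$v == p$rest))
  expect_equal(nrow(r$events), 0L)
})

test_that("baseline fluctuation SD is recovered from one-second samples", {
  set.seed(63)
  p <- synth_trace_params(n_events = 0, duration = 1000)
  sds <- vapply(1:18, function(i) sd(synth_epsp_trace(p)$v), 0)
  expect_equal(mean(sds), 0.44, tolerance = 0.44 * 0.05)
})

test_that("averaged envelopes recover the configured half-fall times", {
  set.seed(64)
  p <- synth_trace_params("trunk")
  tr <- vapply(1:200, function(i) synth_epsp_trace(p)$v,
               numeric(length(seq(-p$baseline_ms, p$duration, by = p$dt))))
  m <- average_and_half_fall(tr, p$dt, stim_time = p$baseline_ms,
                             smooth_ms = 20)
  expect_equal(m$half_fall, 158, tolerance = 158 * 0.15)
  expect_gt(m$peak_time, 20)
  expect_lt(m$peak_time, 120)
})

test_that("generated traces are deterministic per seed and distinct across seeds", {
  p <- synth_trace_params()
  set.seed(70); a <- synth_epsp_trace(p)
  set.seed(70); b <- synth_epsp_trace(p)
  set.seed(71); c <- synth_epsp_trace(p)
  expect_identical(a$v, b$v)
  expect_identical(a$events, b$events)
  expect_false(identical(a$v, c$v))
})

test_that("threshold-triggered spikes are inserted and recovered by detection", {
  p <- synth_trace_params(n_events = 60, spike_threshold = 8)
  set.seed(72)
  r <- synth_spiking_trace(p)
  expect_equal(length(r$spike_times), 1L)
  det <- detect_spikes(r$v, p$dt, t0 = r$times[1])
  expect_equal(det[1], r$spike_times, tolerance = 0.5)

  # unreachable threshold: output identical to the subthreshold generator
  p2 <- synth_trace_params(spike_threshold = 1e4)
  set.seed(73); s1 <- synth_spiking_trace(p2)
  set.seed(73); s2 <- synth_epsp_trace(p2)
  expect_identical(s1$v, s2$v)
  expect_equal(length(s1$spike_times), 0L)
})

test_that("first-EPSP latencies and first-spike delays are uncorrelated when drawn independently", {
  # the recordings show no relationship between the latency of the first
  # EPSP and the time of the first spike; the generator reproduces that
  # independence when the two are drawn from their calibrated laws
  set.seed(74)
  p <- synth_trace_params()
  lat <- vapply(1:50, function(i) min(synth_epsp_trace(p)$events$onset), 0)
  spk <- synth_delay_samples("hdin_spike", 50)
  r2 <- summary(lm(spk ~ lat))$r.squared
  expect_lt(r2, 0.15)
})

test_that("detector recovers at least 90% of embedded events of 1 mV and larger", {
  set.seed(75)
  p <- synth_trace_params()
  hits <- 0; tot <- 0
  for (i in 1:20) {
    r <- synth_epsp_trace(p)
    d <- detect_epsps(r$v, p$dt, t0 = r$times[1])
    gt <- r$events$onset[r$events$amplitude >= 1]
    tot <- tot + length(gt)
    hits <- hits + sum(vapply(gt, function(o) any(abs(d$onset - o) <= 5),
                              TRUE))
  }
  expect_gt(tot, 300)
  expect_gte(hits / tot, 0.9)
})

test_that("recordings round-trip through the paired CSV files", {
  set.seed(76)
  p <- synth_trace_params(n_events = 10, duration = 300)
  r <- synth_epsp_trace(p)
  path <- file.path(tempdir(), "rec")
  write_recording_csv(r, path)
  tr <- read.csv(paste0(path, "_trace.csv"))
  ev <- read.csv(paste0(path, "_events.csv"))
  expect_equal(tr$v_mV, r$v, tolerance = 1e-9)
  expect_equal(ev$onset_ms[ev$kind == "epsp"], r$events$onset,
               tolerance = 1e-9)
})
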