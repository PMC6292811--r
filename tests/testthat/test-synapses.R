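test_that("dual-exponential kernel peaks at gmax and scale 0 is silent", {
  tp <- log(2 / 0.2) * 0.2 * 2 / (2 - 0.2)
  expect_equal(syn_kernel(tp, 1.5, 0.2, 2), 1.5, tolerance = 1e-9)
  expect_equal(syn_kernel(-1, 1.5, 0.2, 2), 0)

  hd <- make_hdin("monitor")
  rest <- fixture_rest("hdin_monitor")
  syn <- synapse_params(0.25, 0.1)
  s0 <- simulate_cell(hd, 120, syn_events = data.frame(t = 40, scale = 0),
                      synapse = syn, v0 = rest)
  expect_lt(max(abs(s0$v[, 1] - rest)), 0.2)
  expect_equal(max(s0$g_ampa), 0)
})

test_that("unitary hdIN EPSP is in the low-mV range, below the printed maximum", {
  hd <- make_hdin("monitor")
  rest <- fixture_rest("hdin_monitor")
  syn <- synapse_params(0.25, 0.1)
  s <- simulate_cell(hd, 150, syn_events = data.frame(t = 40, scale = 1),
                     synapse = syn, v0 = rest)
  amp <- max(s$v[, 1]) - rest
  expect_gt(amp, 0.5)
  expect_lte(amp, 2.3)
})

test_that("paired activations summate and amplitude grows with scale", {
  hd <- make_hdin("monitor")
  rest <- fixture_rest("hdin_monitor")
  syn <- synapse_params(0.25, 0.1)
  one <- simulate_cell(hd, 150, syn_events = data.frame(t = 40, scale = 0.6),
                       synapse = syn, v0 = rest)
  two <- simulate_cell(hd, 150,
                       syn_events = data.frame(t = c(40, 41),
                                               scale = c(0.6, 0.6)),
                       synapse = syn, v0 = rest)
  expect_gt(max(two$v[, 1]), max(one$v[, 1]))

  amps <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(sc) {
    s <- simulate_cell(hd, 150, syn_events = data.frame(t = 40, scale = sc),
                       synapse = syn, v0 = rest)
    max(s$v[, 1]) - rest
  }, 0)
  expect_true(all(diff(amps) > 0))
})

test_that("NMDA magnesium block is sigmoidal, monotone, in (0, 1)", {
  v <- seq(-100, 20, by = 1)
  b <- mg_block(v)
  expect_true(all(b > 0 & b < 1))
  expect_true(all(diff(b) > 0))
  expect_lt(mg_block(-80), mg_block(-20))
})

test_that("with gmax_nmda = 0 the conductance decays with the AMPA time constant", {
  hd <- make_hdin("monitor")
  rest <- fixture_rest("hdin_monitor")
  syn <- synapse_params(0.5, 0, tau_open_ampa = 0.2, tau_close_ampa = 2)
  s <- simulate_cell(hd, 60, syn_events = data.frame(t = 10, scale = 1),
                     synapse = syn, v0 = rest, out_every = 1L)
  g <- s$g_ampa
  sel <- s$times > 14 & s$times < 24 & g > 1e-6
  fit <- lm(log(g[sel]) ~ s$times[sel])
  tau_fit <- -1 / coef(fit)[2]
  expect_equal(unname(tau_fit), 2, tolerance = 0.05)
  expect_equal(max(s$g_nmda), 0)
})

test_that("synaptic charge scales in proportion to the scale factor", {
  hd <- make_hdin("monitor")
  rest <- fixture_rest("hdin_monitor")
  syn <- synapse_params(0.5, 0)
  q <- vapply(c(0.4, 0.8), function(sc) {
    s <- simulate_cell(hd, 80, syn_events = data.frame(t = 10, scale = sc),
                       synapse = syn, v0 = rest, out_every = 1L)
    sum(s$g_ampa) * 0.025
  }, 0)
  expect_equal(q[2] / q[1], 2, tolerance = 1e-3)
})

test_that("scale draws are i.i.d. uniform over the discrete value set", {
  pol <- scaling_policy("per_trial")
  set.seed(7)
  x <- draw_scale(pol, 1e5)
  freq <- table(factor(x, levels = c(0, 0.2, 0.4, 0.6, 0.8))) / 1e5
  expect_true(all(abs(freq - 0.2) < 0.005))

  single <- scaling_policy("per_trial", value_set = 0.8)
  expect_true(all(draw_scale(single, 100) == 0.8))
  off <- scaling_policy("off")
  expect_true(all(draw_scale(off, 100) == 1))
})

test_that("per-trial draws are fixed within a trial; per-spike draws vary", {
  g <- fixture_graph()
  tr_ps <- run_trial(g, cfg = trial_config(duration = 300),
                     policy = scaling_policy("per_spike"), trial_seed = 11)
  draws <- tr_ps$per_spike_draws
  expect_gt(nrow(draws), 10)
  by_edge <- split(draws[, 3], draws[, 1])
  multi <- by_edge[vapply(by_edge, length, 0L) >= 8]
  expect_true(any(vapply(multi, function(v) length(unique(v)) > 1, TRUE)))

  tr_pt <- run_trial(g, cfg = trial_config(duration = 300),
                     policy = scaling_policy("per_trial"), trial_seed = 11)
  expect_equal(nrow(tr_pt$per_spike_draws), 0L)
  expect_true(all(tr_pt$scales$scale %in% c(0, 0.2, 0.4, 0.6, 0.8, 1)))
})

test_that("gap-junction current is ohmic, symmetric and conserving", {
  expect_equal(unname(gap_current(0.5, -50, -50)), c(0, 0))
  i <- gap_current(0.2, -50, -30)
  expect_equal(unname(i), c(4, -4))
  expect_equal(sum(i), 0)
  expect_error(gap_current(-1, 0, 0), ">= 0")

  # two coupled passive cells relax to the capacitance-weighted mean
  ch <- channel_set(0, 0, 0, 0, e_leak = -50)
  sp <- neuron_spec("motoneuron_reference", ch, cell_kinetics("motoneuron"))
  asm <- hexnet:::.assemble_cells(list(sp, sp), v0 = list(-60, -40))
  res <- hexnet:::cpp_run_network(asm$comp, asm$kinetics,
                                  rbind(c(1, 2, 1)), matrix(0, 0, 11),
                                  integer(0), matrix(0, 0, 2),
                                  matrix(0, 0, 4), integer(0), c(1L, 2L),
                                  dt = 0.025, duration = 100, out_every = 4L,
                                  value_set = numeric(0),
                                  mg_vhalf = -40, mg_slope = 10,
                                  spike_thresh = 0, min_isi = 1,
                                  record_gsyn = FALSE)
  n <- res$n_out
  expect_equal(res$v[n, 1], res$v[n, 2], tolerance = 1e-6)
  expect_equal(res$v[n, 1], -50, tolerance = 1e-6)   # charge conserved
})
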