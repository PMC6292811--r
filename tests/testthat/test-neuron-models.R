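test_that("cells rest at a stable fixed point and small drift only", {
  mn <- make_motoneuron_reference()
  rest <- fixture_rest("motoneuron")
  sim <- simulate_cell(mn, duration = 25, dt = 0.025, v0 = rest,
                       out_every = 1L)
  expect_lt(diff(range(sim$v[, 1])), 0.5)

  # passive limit: all active conductances zero -> rest is exactly e_leak
  passive <- neuron_spec("motoneuron_reference",
                         channel_set(0, 0, 0, 2, e_leak = -60),
                         cell_kinetics("motoneuron"))
  expect_equal(as.numeric(resting_potential(passive)), -60, tolerance = 1e-6)
})

test_that("resting potential equals the root of the steady-state current balance", {
  spec <- make_hdin("monitor")
  kin <- spec$kinetics
  ch <- spec$channels
  rate <- function(v, p) {
    den <- p[3] + exp((p[4] + v) / p[5])
    if (abs(den) < 1e-7) den <- p[3] + exp((p[4] + v + 1e-3) / p[5])
    (p[1] + p[2] * v) / den
  }
  xinf <- function(v, g) {
    a <- rate(v, kin$rates[2 * g - 1, ]); b <- rate(v, kin$rates[2 * g, ])
    a / (a + b)
  }
  balance <- function(v) {
    m <- xinf(v, 1); h <- xinf(v, 2); n <- xinf(v, 3); s <- xinf(v, 4)
    ch$gbar_na * m^kin$powers[1] * h * (ch$e_na - v) +
      ch$gbar_kfast * n^kin$powers[3] * (ch$e_k - v) +
      ch$gbar_kslow * s * (ch$e_k - v) +
      ch$gbar_leak * (ch$e_leak - v)
  }
  root <- uniroot(balance, c(-70, -45))$root
  expect_equal(as.numeric(resting_potential(spec)), root, tolerance = 0.05)
})

test_that("hdIN rest lies in the measured physiological band", {
  rest <- fixture_rest("hdin_monitor")
  expect_gt(rest, -55.8)
  expect_lt(rest, -46.0)
})

test_that("hdIN fires one broad spike to any tested suprathreshold current", {
  hd <- make_hdin("monitor")
  rest <- fixture_rest("hdin_monitor")
  for (amp in c(100, 200, 400)) {
    sim <- simulate_cell(hd, duration = 500, i_inj = amp, v0 = rest)
    expect_equal(nrow(sim$spikes), 1L)
    w <- spike_width_at(sim$times, sim$v[, 1], at = 0)
    expect_gt(w, 1.5)
    expect_lt(w, 2.8)
  }
})

test_that("motoneuron reference fires repetitively to sustained current", {
  mn <- make_motoneuron_reference()
  rest <- fixture_rest("motoneuron")
  sim <- simulate_cell(mn, duration = 500, i_inj = 120, v0 = rest)
  expect_gt(nrow(sim$spikes), 10)
})

test_that("rheobase bisection brackets the threshold current to < 1 pA", {
  mn <- make_motoneuron_reference()
  rb <- rheobase(mn, lo = 0, hi = 200, tol = 1)
  expect_lt(rb$hi - rb$lo, 1 + 1e-9)
  rest <- fixture_rest("motoneuron")
  expect_equal(nrow(simulate_cell(mn, 300, i_inj = rb$lo,
                                  v0 = rest)$spikes), 0L)
  expect_gt(nrow(simulate_cell(mn, 300, i_inj = rb$hi, v0 = rest)$spikes), 0)
})

test_that("hexN axonal compartment carries five-fold active conductances", {
  hx <- make_hexn()
  expect_identical(hx$n_compartments, 2L)
  expect_equal(hx$capacitance, 5)
  expect_equal(hx$link_conductance, 10)
  asm <- hexnet:::.assemble_cells(list(hx))
  expect_equal(asm$comp[2, c("g_na", "g_kf", "g_ks")],
               5 * asm$comp[1, c("g_na", "g_kf", "g_ks")])
  expect_equal(asm$comp[2, "g_leak"], asm$comp[1, "g_leak"])

  sym <- make_hexn(axon_scale = 1)
  asm2 <- hexnet:::.assemble_cells(list(sym))
  expect_equal(asm2$comp[1, 1:8], asm2$comp[2, 1:8])
})

test_that("depolarisation block: 1-compartment stops, hexN axon keeps firing", {
  mn <- make_motoneuron_reference()
  hx <- make_hexn()
  syn <- synapse_params(15, 15)
  ev <- data.frame(t = seq(20, 800, by = 2.5), scale = 1)
  s1 <- simulate_cell(mn, 900, syn_events = ev, synapse = syn,
                      v0 = fixture_rest("motoneuron"))
  s2 <- simulate_cell(hx, 900, syn_events = ev, synapse = syn,
                      v0 = fixture_rest("hexn"))
  ax <- s2$spikes[s2$spikes$compartment == 2, ]
  expect_equal(sum(s1$spikes$t > 400), 0L)   # blocked
  expect_gt(sum(ax$t > 400), 20)             # axon still firing
})

test_that("halving the integration step moves spike times by < 0.1 ms", {
  mn <- make_motoneuron_reference()
  rest <- fixture_rest("motoneuron")
  a <- simulate_cell(mn, 300, dt = 0.025, i_inj = 100, v0 = rest)
  b <- simulate_cell(mn, 300, dt = 0.0125, i_inj = 100, v0 = rest)
  ta <- a$spikes$t; tb <- b$spikes$t
  expect_equal(length(ta), length(tb))
  expect_lt(max(abs(ta - tb)), 0.1)
})

test_that("bounded random input never produces non-finite or runaway state", {
  set.seed(101)
  for (i in 1:6) {
    spec <- if (i %% 2) make_hexn() else make_hdin("monitor")
    inj <- data.frame(amp = runif(4, -150, 350),
                      t_on = sort(runif(4, 0, 1800)))
    inj$t_off <- inj$t_on + runif(4, 10, 250)
    sim <- simulate_cell(spec, duration = 2000, i_inj = inj, out_every = 40L)
    expect_true(sim$ok)
    expect_true(all(is.finite(sim$v)))
    expect_true(all(abs(sim$v) <= 200))
  }
})

test_that("invalid state or step size is rejected with a diagnostic", {
  mn <- make_motoneuron_reference()
  expect_error(simulate_cell(mn, dt = 0), "dt")
  expect_error(simulate_cell(mn, dt = -0.1), "dt")
  expect_error(simulate_cell(mn, v0 = NaN), "finite")
})
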