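test_that("DLC spike times follow the truncated normal stimulus law", {
  set.seed(2)
  d <- generate_dlc_spikes(stimulus_spec())
  expect_equal(nrow(d), 30L)
  expect_true(all(d$t > 5))

  degen <- stimulus_spec(sd = 0, lower_bound = -Inf)
  expect_true(all(generate_dlc_spikes(degen)$t == 5))

  set.seed(3)
  big <- replicate(400, generate_dlc_spikes(stimulus_spec())$t)
  m_target <- 5 + 2 * sqrt(2 / pi)   # mean of a half-normal above its mean
  expect_equal(mean(big), m_target, tolerance = 0.02)
})

test_that("trials replay bit-identically from their seed", {
  g <- fixture_graph()
  t1 <- run_trial(g, cfg = trial_config(duration = 400), trial_seed = 21)
  t2 <- run_trial(g, cfg = trial_config(duration = 400), trial_seed = 21)
  expect_identical(t1$spikes, t2$spikes)
  expect_identical(t1$traces, t2$traces)
  expect_identical(t1$scales, t2$scales)
  expect_identical(t1$dlc_spikes, t2$dlc_spikes)
})

test_that("forcing every scale draw to zero silences the network", {
  g <- fixture_graph()
  pol <- scaling_policy("per_trial", value_set = 0)
  tr <- run_trial(g, cfg = trial_config(duration = 400), policy = pol,
                  trial_seed = 2)
  expect_equal(sum(tr$spikes$population == "HEXN"), 0L)
  rest <- fixture_rest("hdin_monitor")
  mon <- tr$traces[, grepl("HDIN_MON", colnames(tr$traces))]
  expect_lt(max(abs(mon - rest)), 1)
  expect_true(all(is.na(tr$delays)))
})

test_that("pre-reduction coupling strength gives self-sustained firing of all hexNs", {
  cfg <- build_config(conductances = list(
    dlc_hexn = c(ampa = 3.3, nmda = 4.2),   # 3x the reduced values
    hexn_hexn = c(ampa = 1.5, nmda = 1.8),
    hexn_mon = c(ampa = 0.25, nmda = 0.1),
    hexn_pop = c(ampa = 0.125, nmda = 0.15),
    pop_pop = c(ampa = 0.15, nmda = 1.2)))
  g <- build_network(cfg, build_seed = 1)
  tr <- run_trial(g, cfg = trial_config(duration = 600),
                  policy = scaling_policy("off"), trial_seed = 5)
  sp <- tr$spikes[tr$spikes$population == "HEXN", ]
  expect_equal(length(unique(sp$neuron_id)), 30L)
  # every cell that is part of the recurrent web keeps firing to the end of
  # the trial (cells sampled with zero recurrent in-degree cannot be
  # sustained once the sensory conductance has decayed)
  last <- tapply(sp$t, sp$neuron_id, max)
  indeg <- vapply(as.integer(names(last)), function(i)
    sum(g$chemical$post == i & g$chemical$class == "hexn_hexn"), 0)
  expect_true(all(last[indeg >= 1] > 500))
  expect_gt(sum(last > 500), 20)
})

test_that("experiments derive independent per-trial streams from the master seed", {
  g <- fixture_graph()
  ex <- run_experiment(g, n_trials = 2, master_seed = 77,
                       cfg = trial_config(duration = 300))
  solo <- run_trial(g, cfg = trial_config(duration = 300),
                    trial_seed = hexnet:::.derive_seed(77, 1))
  expect_identical(ex$trials[[1]]$spikes, solo$spikes)
  expect_false(identical(ex$trials[[1]]$dlc_spikes,
                         ex$trials[[2]]$dlc_spikes))
})

test_that("monitor delays are defined exactly when summation reached threshold", {
  ex <- fixture_experiment()
  for (tr in ex$trials[1:10]) {
    mon_cols <- grepl("HDIN_MON", colnames(tr$traces))
    fired <- !is.na(tr$delays)
    spikes_mon <- tr$spikes[tr$spikes$population == "HDIN_MON", ]
    expect_equal(sum(fired), length(unique(spikes_mon$neuron_id)))
  }
  frac_silent <- mean(rowSums(!is.na(ex$delays)) == 0)
  expect_gt(frac_silent, 0)
  expect_lt(frac_silent, 1)
})

test_that("direct hexN recruitment grows with sensory synaptic strength", {
  counts <- vapply(c(0.5, 1, 2), function(f) {
    cfg <- build_config(conductances = list(
      dlc_hexn = c(ampa = 1.1 * f, nmda = 1.4 * f),
      hexn_hexn = c(ampa = 1.5, nmda = 1.8),
      hexn_mon = c(ampa = 0.25, nmda = 0.1),
      hexn_pop = c(ampa = 0.125, nmda = 0.15),
      pop_pop = c(ampa = 0.15, nmda = 1.2)))
    g <- build_network(cfg, build_seed = 31)
    tr <- run_trial(g, cfg = trial_config(duration = 60), trial_seed = 13)
    sp <- tr$spikes[tr$spikes$population == "HEXN", ]
    length(unique(sp$neuron_id[sp$t < 30]))
  }, 0)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("population stage input is decoupled from recording options", {
  g <- fixture_graph()
  tr <- run_trial(g, cfg = trial_config(duration = 500), trial_seed = 6)
  hexsp <- tr$spikes[tr$spikes$population == "HEXN", c("neuron_id", "t")]
  pg <- build_hdin_population(build_config(), build_seed = 2)
  a <- run_population_recruitment(hexsp, pg, g, trial_seed = 3,
                                  cfg = trial_config(dt = 0.1, out_dt = 0.5))
  b <- run_population_recruitment(hexsp, pg, g, trial_seed = 3,
                                  cfg = trial_config(dt = 0.1, out_dt = 2))
  expect_equal(a$spikes, b$spikes)
})

test_that("an empty hexN spike train leaves the population silent", {
  g <- fixture_graph()
  pg <- build_hdin_population(build_config(), build_seed = 2)
  empty <- data.frame(neuron_id = integer(0), t = numeric(0))
  r <- run_population_recruitment(empty, pg, g, trial_seed = 1)
  expect_equal(nrow(r$spikes), 0L)
  expect_false(r$recruitment$recruited)
})

test_that("numerical blow-up aborts the trial with a diagnostic", {
  ch <- channel_set(600, 180, 0, 3.5, e_na = 400, e_leak = -57)
  bad <- neuron_spec("motoneuron_reference", ch, cell_kinetics("motoneuron"))
  expect_warning(
    sim <- simulate_cell(bad, 100, i_inj = 5000),
    "blow-up")
  expect_false(sim$ok)
  expect_true(is.finite(sim$abort_time))
})
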