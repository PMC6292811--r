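#!/usr/bin/env Rscript
# Thirty trials of the recurrent network with per-trial synaptic-strength
# noise (the only trial-to-trial variability). Writes the spike tables, the
# pooled hexN firing-time histogram, and the monitor hdIN first-spike delay
# table; prints the headline delay range.

suppressPackageStartupMessages(library(hexnet))
seed <- 1
dir.create("results", showWarnings = FALSE)

graph <- build_network(build_config(), build_seed = seed)
exp30 <- run_experiment(graph, n_trials = 30, master_seed = seed,
                        cfg = trial_config(duration = 1400))

spikes <- spike_table(exp30)
write.csv(spikes, "results/spikes_30_trials.csv", row.names = FALSE)

delays <- data.frame(trial = seq_len(nrow(exp30$delays)), exp30$delays)
write.csv(delays, "results/monitor_delays.csv", row.names = FALSE)

hex <- spikes[spikes$population == "HEXN", ]
h <- latency_raster_and_histogram(data.frame(t = hex$t_ms,
                                             source = hex$neuron_id,
                                             trial = hex$trial),
                                  bin_width = 10, t_range = c(0, 1400))
write.csv(data.frame(bin_mid_ms = h$mids, count = h$counts),
          "results/hexn_firing_histogram.csv", row.names = FALSE)

d <- as.vector(exp30$delays); d <- d[!is.na(d)]
firing <- rowSums(!is.na(exp30$delays)) > 0
cat(sprintf("\n%d/30 trials brought at least one monitor hdIN to threshold.\n",
            sum(firing)))
if (length(d))
  cat(sprintf("Monitor first-spike delays: %.0f-%.0f ms (n = %d monitor spikes).\n",
              min(d), max(d), length(d)))
cat(sprintf("hexN firing concentrates early (mode bin %.0f ms) with a tail to %.0f ms.\n",
            h$mids[which.max(h$counts)], max(hex$t_ms)))
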