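#!/usr/bin/env Rscript
# Step 1 — dynamics of the critical branching network.
#
# Builds the default 60-unit network (out-degree 10, sigma = 1, p_spont =
# 0.005 per unit per bin, 5-bin refractory period), simulates 300,000 bins
# of 4 ms, extracts neuronal avalanches, and writes the avalanche table and
# the avalanche size distribution with its log-log least-squares slope over
# S in [3, 30].

suppressPackageStartupMessages(library(avaclust))
dir.create("results", showWarnings = FALSE)

cfg <- model_config(n_steps = 300000, seed = 101)
net <- build_network(cfg)
cat(sprintf("network: %d units, out-degree %d, B = %g; every sigma_i = %.12f\n",
            cfg$n_units, cfg$out_degree, cfg$exponent_B,
            branching_parameter(net, 1)))

raster <- simulate_network(net, cfg, seed = 102)
cat(sprintf("simulated %d bins (%.0f min of model time): %d events (%.3f per bin)\n",
            cfg$n_steps, cfg$n_steps * cfg$bin_ms / 1000 / 60,
            length(raster$bin), length(raster$bin) / cfg$n_steps))

av <- find_avalanches(raster)
cat(sprintf("avalanches: %d; mean length %.2f, mean size %.2f\n",
            nrow(av), mean(av$length), mean(av$size)))
utils::write.csv(as.data.frame(av), "results/avalanches.csv", row.names = FALSE)

dist <- size_distribution(av)
utils::write.csv(dist, "results/size_distribution.csv", row.names = FALSE)
slope <- powerlaw_slope(dist)
cat(sprintf("log-log LS slope of P(S) over S in [3, 30]: %.3f\n", slope))
cat("(an idealized critical branching cascade gives about -3/2 in this window;\n",
    "at the dense default drive, concatenation of cascades flattens it -- see\n",
    "the methods vignette)\n", sep = "")
utils::write.csv(data.frame(quantity = "powerlaw_slope_S3_30", value = slope),
                 "results/size_distribution_slope.csv", row.names = FALSE)
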