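# avaclust

Critical branching networks, neuronal avalanches, and statistically
significant groups of repeating activity patterns.

## What this package is for

Cortical networks on 60-channel multielectrode arrays produce *neuronal
avalanches* — cascades of suprathreshold local field potentials spanning
consecutive 4-ms bins whose size distribution approximates a power law —
and many avalanches of the same length repeat with above-chance similarity.
`avaclust` implements a tunable-weight branching-network model of this
activity and the full analysis chain used to ask: **which distribution of
connection strengths best fits the observed statistics of repeating
patterns, and which maximizes how many distinct patterns a network
retains?**

The model: 60 binary units, each with fixed connections to 10 random other
units. Connection probabilities follow a rank-exponential weighting
function

    w_r = exp(-B r) / sum_m exp(-B m),   r = 1..10,

scaled so every unit's branching parameter `sigma_i = sum_j p_ij` equals 1
(critical). `B = 0` gives homogeneous weights; larger `B` gives a few
strong and many weak connections. Units fire spontaneously with probability
0.005 per bin, propagate activity via independent Bernoulli transmissions,
and are refractory for 5 bins after firing.

The analysis: avalanches are unfolded into binary vectors (8x8 frames,
corners absent), compared by Boolean (Jaccard) similarity within each
length, ordered by average-linkage dendrogram, and partitioned into the
contiguous box grouping maximizing the contrast `D_in - D_out`. A group is
*significant* (p < 0.05) when its mean pairwise similarity beats every
group of the same length found in 20 constrained-shuffle surrogates
(events move only within their own channel, only into bins where another
channel was active). A sweep over `B in {0.4, ..., 4.0}` then reports each
exponent's group-length distribution `P(L)`, `L = 2..9`, its sum-of-squares
error against a reference distribution (good fit: SSE <= 0.016), the total
number of significant groups, and the group-maximizing exponent.

## Worked example

```r
library(avaclust)

# a critical network and 20 minutes of model time
cfg <- model_config(n_steps = 300000, seed = 101)
net <- build_network(cfg)
branching_parameter(net, 1)    # 1 (critical)
raster <- simulate_network(net, cfg, seed = 102)

av <- find_avalanches(raster)
powerlaw_slope(size_distribution(av))

# significant repeating groups on a raster with planted structure
spec <- plant_spec(n_templates = 3, template_length = 4, n_repeats = 20,
                   flip_prob = 0.02, total_bins = 20000, seed = 201)
pr <- gen_planted_raster(spec)
report <- significant_groups(pr$raster, shuffle_cfg = shuffle_config(20, seed = 202))
sum(report$significant[report$length == 4])
```

The analysis scripts under `analysis/` run these stages as a narrated
workflow and write their tables under `results/`:

```sh
Rscript analysis/01_critical_dynamics.R    # simulate, avalanche statistics
Rscript analysis/02_repeating_groups.R     # planted-template group recovery
Rscript analysis/03_sweep_exponent.R       # the B sweep (use --full for the complete protocol)
```

Output of the first two scripts (seeds as committed):

```
network: 60 units, out-degree 10, B = 0; every sigma_i = 1.000000000000
simulated 300000 bins (20 min of model time): 403858 events (1.346 per bin)
avalanches: 29881; mean length 6.00, mean size 13.51
log-log LS slope of P(S) over S in [3, 30]: -0.743
```

Every unit's branching parameter is exactly 1 (critical); the avalanche
size distribution's least-squares window slope at this dense operating
point sits above the idealized critical-branching value of -3/2 because
concatenation of cascades adds tail mass — the methods vignette quantifies
this against a pure Galton-Watson oracle.

```
planted raster: 20000 bins, 15016 events, 60 copies of 3 templates
significant groups: 10 (of 347 candidate groups)
  length 4: 49 groups, 8 significant (best mean similarity 0.983, shuffle max 0.333)
at the planted length (4): 8 significant groups for 3 planted templates
```

All three planted template families are recovered at their length (the
contrast maximizer splits the three families into eight tight boxes, all
significant against the 20 surrogates), while the background lengths
contribute essentially nothing.

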