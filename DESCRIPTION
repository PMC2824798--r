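Package: avaclust
Title: Critical Branching Networks, Neuronal Avalanches, and Significant
    Repeating Activity Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates a critical branching-process model of multielectrode
    network activity with a tunable (exponentially skewed) distribution of
    outgoing connection strengths, extracts neuronal avalanches from binary
    event rasters, detects statistically significant groups of repeating
    avalanches via Jaccard similarity matrices, dendrogram ordering and
    contrast-maximizing block grouping against constrained-shuffle
    surrogates, and sweeps the weighting exponent to locate the weight
    distributions that best fit a reference group-length distribution and
    that maximize the number of significant groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
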