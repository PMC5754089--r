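Package: ksclock
Title: Kolmogorov-Smirnov Tests for the Molecular Clock on Bayesian Tree Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric goodness-of-fit tests for the molecular clock
    operating on ensembles of Bayesian phylogenetic trees. Implements the
    one-sample Poisson-Kolmogorov-Smirnov (PKS) test of the strict clock,
    which tests whether discretized branch lengths (substitution counts)
    follow a single Poisson law with mean estimated from the data, with a
    seeded parametric-bootstrap null distribution; and the two-sample
    Kolmogorov-Smirnov (2KS) test comparing branch-length distributions of
    unconstrained versus clock-constrained (strict or relaxed) ensembles,
    with asymptotic critical values and p-values. Sample sizes are adjusted
    for MCMC autocorrelation through the effective sample size of the
    tree-length trace. Includes Poisson-mixture expected distributions,
    non-parametric coverage bands, a likelihood-ratio clock test baseline,
    readers and writers for MrBayes-style Nexus and plain Newick tree files,
    and a synthetic posterior-ensemble generator with INAR(1) between-tree
    autocorrelation for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
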