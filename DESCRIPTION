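Package: duplexmsm
Title: Sequence-Dependent Kinetic Models of DNA Duplex Hybridization from
    Trajectory Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds Markov state models of DNA duplex hybridization and
    dehybridization from two-strand trajectory data. Provides a synthetic
    trajectory generator driven by explicit ground-truth kinetic networks
    over hybridized, out-of-register shifted, frayed, and dissociated
    macrostates; rototranslationally and strand-permutation invariant
    featurization by reciprocal interstrand base-center distances; linear
    slow-mode estimation (tICA) with VAMP-2 scoring; reversible maximum
    likelihood transition matrix estimation with implied timescales,
    Chapman-Kolmogorov validation and PCCA+ coarse-graining; transition
    path theory committors, reactive pathway fractions and mean
    first-passage times; nearest-neighbor thermodynamic comparison of
    macrostate free energies; and temperature-jump style relaxation rate
    extraction with two-state kinetic algebra for self-complementary
    oligomers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
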