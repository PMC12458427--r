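Package: rotastat
Title: Rotational-State Statistics for In Situ ATP Synthase Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for per-particle rotational-state analysis of
    mitochondrial ATP synthase from in situ cryo-electron tomography metadata.
    Provides calibrated synthetic particle ensembles and phantom density volumes,
    MRC volume primitives (rotation about the symmetry axis, masked Pearson
    similarity, symmetry imposition, ice-thickness profiling), c-ring symmetry
    order inference from rotational self-correlation, exhaustive rotational
    cross-correlation angle assignment, and the statistical core: binned
    Kolmogorov-Smirnov coupling tests of F1-head angles across central-stalk
    states, tri-periodic sinusoid fitting with permutation inference, chord-based
    angular resolution bounds, detection-power analysis, intradimer independence
    tests, and peripheral-stalk trajectory binning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
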