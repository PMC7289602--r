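Package: axialFCS
Title: Axial Line-Scanning Fluorescence Correlation Spectroscopy Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of dual-color axial line-scanning fluorescence
    correlation spectroscopy (lsFCS) experiments on membranes, from
    time-tagged photon event streams through pulsed-interleaved-excitation
    channel gating, kymograph construction with dwell-time rescaling,
    membrane tracking and quality control, background and photobleaching
    corrections, multi-tau auto- and cross-correlation, diffusion-model
    fitting, and the Gamma(C_L) cross-correlation amplitude statistic, to
    equilibrium dissociation coefficients (K_D) of ligand-receptor pairs.
    Includes a photon-level Monte-Carlo simulator of axial scanning across
    a membrane carrying diffusing labeled receptors and ligand-receptor
    complexes, used as a ground-truth generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'axialFCS-package.R'
    'optics.R'
    'binding.R'
    'config.R'
    'corrections.R'
    'correlation.R'
    'fcsmodels.R'
    'io.R'
    'photonproc.R'
    'membrane.R'
    'pipeline.R'
    'simulate.R'
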