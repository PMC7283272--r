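Package: ppkinetics
Title: Pre-Steady-State Polymerase Kinetics and Nucleotide-Analog Toxicity Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pre-steady-state DNA polymerase kinetics and
    the cellular readouts used to study nucleotide-analog (NRTI) toxicity.
    Fits single-turnover exponential and biphasic burst time courses, infers
    kpol and apparent Kd from nucleotide titrations via quadratic or
    hyperbolic saturation models (including the amplitude-based branch used
    when observed rates are concentration-independent), and derives
    discrimination factors and sequence-context fold differences. Also
    extracts melting temperatures from differential scanning fluorimetry
    curves as derivative minima, computes the standard respirometry
    parameters from injection-phased oxygen consumption rate cycles,
    quantifies relative mitochondrial DNA content from qPCR CT pairs, and
    normalizes plate-based proliferation assays. A seeded synthetic-data
    generator reproduces the statistical structure of each assay for
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
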