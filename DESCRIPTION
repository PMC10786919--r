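Package: stapleSAR
Title: Quantitative Structure-Activity Analysis for Stapled Peptide Libraries
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterization of stapled
    alpha-helical peptide libraries directed at Mdm2/MdmX. Implements the
    exact ternary-equilibrium model for competitive fluorescence anisotropy
    and direct 1:1 binding with nonlinear least-squares dissociation-constant
    fitting and curve-validity checks; four-parameter logistic EC50 fitting
    with control-based normalization and censoring at assay ceilings;
    log-linear stability half-life estimation; a peptide sequence model
    covering non-natural residues, staples, net formal charge, helical-wheel
    geometry, hydrophobic moment and tail helical-propensity classification;
    circular-dichroism mean residue ellipticity and single-wavelength helix
    estimation; library-level structure-activity indices (cell ratio,
    on-target index, serum shift, fold improvement) with explicit propagation
    of censored (">"/"<") assay values; and fully seeded synthetic-data
    generators for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
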