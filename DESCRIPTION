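Package: kyntrace
Title: Quantitative Stable-Isotope Tracing of Kynurenine-Pathway One-Carbon Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative carbon-13 tracer analysis of tryptophan
    catabolism and the folate one-carbon network. Implements a forward
    atom-bookkeeping model of tracer-derived isotopologue distributions
    through the kynurenine pathway and its one-carbon fates (purines, serine,
    methionine), natural-abundance convolution, empirical baseline-subtraction
    correction of LC-MS isotopologue peak areas against unlabeled controls,
    GC-MS formate quantification by deuterated internal standard, per-cell
    medium exchange rates (fmol/cell/h), and a seeded synthetic-experiment
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
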