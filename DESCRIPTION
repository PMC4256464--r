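Package: goldstereo
Title: Quantitative Immunogold Labelling Analysis by Stereological
    Intersection Counting
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies immunogold labelling of membrane compartments on
    annotated electron micrographs of cryo-sections. Membrane profile
    length is estimated stereologically from intersection counts with
    randomly placed square test-line lattices; gold particles are assigned
    to compartments by a nearest-membrane distance rule; labelling
    specificity is corrected with a peptide-inhibition control via
    D(sp) = D(0) - D(-), the specific fraction F(sp) = D(sp)/D(0), and the
    per-compartment distribution of specific gold Ng(sp) = F(sp) x N(0);
    replicate experiments are summarised as mean and standard error.
    Includes a seeded synthetic micrograph-annotation generator emulating
    microsporidian meront sections, so every estimator is testable by
    parameter recovery without real micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, jsonlite, utils, tools, graphics
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
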