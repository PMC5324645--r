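Package: vankrev
Title: Molecular Formula Assignment and Interactive van Krevelen Reports
    for High-Resolution Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns molecular formulae to centroid peak lists from
    high-resolution mass spectrometry of complex mixtures (natural organic
    matter, petroleomics and related samples) by Kendrick mass defect / z*
    homologous-series analysis with a heuristic-rule candidate formula
    generator, annotates 13C isotopologues, reads and writes the three-file
    assignment convention (monoisotopic / isotopologue / unassigned), computes
    double bond equivalents, the modified aromaticity index, elemental ratios,
    heteroatom class distributions and van Krevelen compound-class regions,
    and renders a standalone multi-tab HTML report of four linked interactive
    panels (van Krevelen diagram, centroid spectrum, DBE vs carbon number,
    modified aromaticity index vs carbon number) plus batch publication-quality
    static figures. Includes a deterministic generator of SRFA-like synthetic
    spectra with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
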