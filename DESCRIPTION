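Package: paMRM
Title: Targeted LC-MRM-EPI Lipidomics of Phosphatidic Acid Molecular Species
Version: 0.1.0
Authors@R: person("paMRM", "Developers", email = "pamrm@example.org",
    role = c("aut", "cre"))
Description: Formula-driven analysis of phosphatidic acid (PA) molecular
    species by targeted tandem mass spectrometry. Builds MS1 species/adduct
    and MS/MS fragment databases from the generalized glycerophospholipid
    chemical formula, designs multiple-reaction-monitoring (MRM) transition
    lists, assigns sn-1/sn-2 positional isomers from enhanced-product-ion
    (EPI) fragment intensities with retention-time co-elution checks,
    performs internal-standard quantitation normalized to total lipid
    phosphate, and classifies per-species group differences (restoration to
    wild-type, elevation over mutant). A synthetic-data module simulates MRM
    chromatograms and EPI spectra with known ground truth so that the full
    pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
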