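Package: dryspec
Title: FTIR Band Analysis for Dry Preservation of Nucleic Acids and Sperm Chromatin
Version: 0.1.0
Authors@R: person("Dryspec", "Developers", email = "dryspec@example.org", role = c("aut", "cre"))
Description: Tools for analysing Fourier-transform infrared (FTIR) absorbance
    spectra of dried biomolecular preservation formulations. Implements
    second-derivative (Savitzky-Golay) band analysis of the fingerprint region
    (1500-900 cm-1) to detect the B- to A-form DNA conformational transition
    via marker band shifts and the asymmetric/symmetric phosphate stretching
    intensity ratio; determination of the OH-stretching band position by the
    80 percent peak-height rule and its wavenumber temperature coefficient
    (WTC) for discriminating glassy from liquid matrices; vector-normalised
    covariance PCA of fingerprint spectra for storage-stability monitoring;
    gravimetric water-content and drying-endpoint calculations; and
    grey-value quantification of formazan staining. A synthetic-spectrum
    generator with literature band assignments provides ground-truth inputs
    so the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
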