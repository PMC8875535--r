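Package: haptenms
Title: Hapten Density Estimation for Peptide-Carrier Conjugate Vaccines
    from MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines the average hapten density (peptide-to-carrier
    conjugation ratio) of peptide-carrier conjugate vaccines from linear
    MALDI-TOF mass spectra.  Provides spectrum input/output (mzML and
    two-column text), polynomial mass calibration, Savitzky-Golay
    smoothing, SNIP baseline estimation and subtraction, constrained
    Gaussian-series deconvolution of the carrier + n x peptide charge
    ladder, and peak-area-weighted hapten-density and dispersity
    statistics.  Includes peptide-design utilities (masses from sequence
    with terminal modifications, crosslinker arithmetic, epitope identity)
    and a synthetic-spectrum simulator with known ground truth so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mzR,
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
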