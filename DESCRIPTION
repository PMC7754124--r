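Package: pesiclass
Title: Probe Electrospray Ionization Mass Spectrometry Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of 2-minute probe electrospray ionization
    (PESI) mass-spectrometry acquisitions for liver-tumour classification:
    splitting each acquisition into 10-second fragments, averaging and
    centroiding the continuum spectra, peak alignment within an m/z tolerance,
    normalization on the total ion current, partial least squares discriminant
    analysis (NIPALS), support-vector-machine and random-forest classification
    under patient-grouped K-fold cross-validation, the concordant / false
    positive / false negative / misclassified error taxonomy, and per-specimen
    majority-vote judgements.  Includes a synthetic cohort generator with
    class-dependent peak profiles, patient random effects, scan noise and
    end-of-run signal decay, a daily instrument-calibration check against a
    reference standard, and plain-text readers and writers for acquisitions,
    manifests and feature matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    ranger,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
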