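Package: chromeff
Title: Chromatographic Fingerprint-Efficacy Relationship Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectrum-effect (fingerprint-efficacy) relationship
    studies on herbal-medicine HPLC fingerprints: peak detection and
    cross-sample retention-time matching, simulative median reference
    chromatograms and cosine similarity indices, bioactivity assay
    statistics (radical scavenging, enzyme inhibition, cellular
    antioxidant activity units, four-parameter logistic EC50 fits,
    calibration-line quantification), NIPALS partial least-squares
    regression with variable importance in projection (VIP) screening,
    a single-hidden-layer back-propagation network trained by
    Levenberg-Marquardt with Garson contribution ratios, OPLS-DA with
    permutation testing, S-plot and volcano statistics for untargeted
    metabolomics, and seeded synthetic-data generators providing ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
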