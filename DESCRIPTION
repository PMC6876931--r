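Package: ecgdigitize
Title: Digitization of Paper-Based ECG Records
Version: 0.1.0
Authors@R: person("ECG", "Digitize Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts scanned or printed 12/13-lead electrocardiogram (ECG)
    images into calibrated digital time (ms) / voltage (mV) signals. Lead
    regions are located with sliding standard-deviation masks, each trace is
    extracted by Otsu thresholding, connected-component cleaning, Hough
    centerline estimation and iterative path growth, and the calibration
    pulse printed next to lead aVF fixes the pixel-to-physical scale. PQRST
    fiducials and PR/QRS/QT/RR intervals are derived with a Pan-Tompkins QRS
    detector, and recovered signals are validated against references by
    Pearson correlation after resampling to a common length. A seeded
    synthetic printed-ECG renderer with analytic ground truth makes the full
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jpeg,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
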