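Package: hoxcal
Title: Calibrated BOLD fMRI from a Task Repeated at Normoxia and Hyperoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates task-related changes in venous cerebral blood volume
    (rvCBV), venous deoxyhaemoglobin fraction (q_act) and oxygen metabolism
    (rCMRO2) from BOLD fMRI acquired while the same task is performed at
    normoxia and at isocapnic hyperoxia, without assuming a coupling law
    between blood volume and blood flow.  End-tidal oxygen traces are
    converted to venous oxygenation changes through a haemoglobin oxygen
    dissociation model; rest and active BOLD levels at each gas state are
    regressed against the venous deoxyhaemoglobin change to yield the
    calibration parameters M and M' and, from them, rvCBV and q_act;
    arterial spin labelling perfusion series provide rCBF so that Fick's
    principle gives rCMRO2.  Baseline oxygen extraction fraction can be
    estimated from the hyperoxia:normoxia ratio of extravascular phase
    around a large vein.  A forward simulator with matching paradigms
    supports Monte Carlo precision analysis of the estimators.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
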