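Package: isoselect
Title: Selection and Merging of Partial Serial-Crystallography Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for merging diffraction intensities from ensembles of
    partial microcrystal datasets, as produced by in situ serial
    synchrotron crystallography. Implements iterative isomorphism
    selection by intensity correlation (CC_dataset) with low-resolution
    R_meas presorting and asymptotic-I/sigma (ISa) prefiltering; full
    shell-resolved merging statistics (R_meas, R_pim, CC1/2, I/sigma,
    completeness, multiplicity, R_iso); Bijvoet-difference extraction and
    anomalous-signal estimation for SAD/SIRAS feasibility; and a
    structure-factor simulator that generates labelled microcrystal
    ensembles with realistic scale, B-factor and error structure for
    validating every stage without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
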