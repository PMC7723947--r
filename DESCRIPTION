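Package: hemowk
Title: Patient-Specific Haemodynamic Personalisation with Windkessel Outlet Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order toolkit for patient-specific haemodynamic studies of
    the aorta. Synthesises pulsatile inlet flow waveforms from clinical
    parameters (stroke volume, cycle length, mean flow), simulates a 0D aortic
    network whose outlets are three-element Windkessel models, and calibrates
    the Windkessel parameters to clinical targets (systolic/diastolic pressure
    and branch flow distribution). Includes velocity-field analytics for
    in-vitro/in-silico comparison: phase averaging, normalized-median outlier
    detection, profile extraction, a normalised profile-difference metric and
    axisymmetric flow-rate integration, together with a seeded Womersley-flow
    synthetic-data generator emulating planar PIV acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
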