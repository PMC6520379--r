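Package: cordmotion
Title: Quantification of Cervical Spinal Cord Motion from Cardiac-Gated
    Phase-Contrast MRI
Version: 0.1.0
Authors@R:
    person("cordmotion", "authors", email = "imaging@example.org",
           role = c("aut", "cre"))
Description: Standardized quantification of pulse-synchronous cranio-caudal
    spinal cord motion from cardiac-gated axial phase-contrast MRI. Converts
    region-of-interest mean grey values to velocities via the velocity
    encoding (venc), corrects the scanner-dependent phase-drift baseline
    offset under the zero-net-motion assumption, and derives four motion
    readouts per cervical segment (amplitude, maximum cranial velocity,
    maximum caudal velocity, displacement). Includes a synthetic cohort
    generator emulating the biphasic motion waveform, grey-value
    quantization, phase drift and pixel noise, and the cohort statistics
    layer: exclusion filtering, biometric derivations, segmental summaries,
    Friedman intersegment comparisons with Dunn post-hoc tests, two-way
    mixed absolute-agreement average-measures intraclass correlation
    coefficients, and Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
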