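Package: burstcoupling
Title: Burst-Resolved Cortico-Subthalamic Beta Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects beta (13-30 Hz) bursts from the smoothed Hilbert envelope
    of subthalamic local field potentials and quantifies cortico-subthalamic
    coupling separately inside and outside bursts, using Welch
    magnitude-squared coherence and the debiased weighted phase lag index
    (dwPLI). Non-burst coupling is tested against circular time-shift
    surrogate null distributions, and burst-adjacent and peri-burst
    sliding-window analyses resolve coupling in time around burst onset.
    Includes a synthetic LFP/ECoG generator with known burst structure and
    known (burst-locked, tonic, or absent) phase coupling, so the full
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
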