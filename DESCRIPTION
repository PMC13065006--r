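Package: tenniswork
Title: Mechanical Work and Neuromuscular Fatigue from Tennis Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes whole-body centre-of-mass (CoM) energetics and
    Cavagna-Kaneko external, internal and total mechanical work from
    kinematic time series of on-court tennis trials, together with two
    CoM-proxy approximations (pelvis point and multi-camera bounding-box
    pseudo-CoM reconstructed by least-squares ray intersection). Segments
    trials into groundstroke and sprint phases by event detection on the
    CoM trajectory, extracts peak sprint velocity as a measure of acute
    neuromuscular fatigue, and relates it to cumulative work through
    per-player Pearson correlations pooled by a random-effects Fisher-z
    method, with repeated-measures Bland-Altman agreement between the CoM
    and its proxies. Includes a seeded synthetic motion generator that
    emulates the fatiguing-protocol trial structure with ground-truth
    events for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
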