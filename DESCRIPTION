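Package: seatbeat
Title: Unconstrained Heartbeat Monitoring from a Seat-Mounted Pressure Sensor Array
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unconstrained ballistocardiographic heartbeat monitoring
    with a 16x16 seat-backrest pressure sensor array. Classifies driving
    posture from the static pressure distribution with an extreme learning
    machine trained on nineteen image features (geometry, Hu invariant
    moments, grey-level co-occurrence texture and colour statistics),
    extracts the cardiac component of every sensor channel by frequency-domain
    band-pass filtering in the heart-rate band, and selects the optimal
    monitoring sensor by absolute Pearson correlation against a reference
    electrocardiogram trace. Includes a synthetic-data simulator that
    generates posture-dependent pressure recordings with an embedded
    heartbeat component and a paired ECG-like reference, so the whole
    pipeline can be exercised and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
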