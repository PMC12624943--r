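Package: lickometry
Title: Simulation and Microstructure Analysis of RFID-Gated Home-Cage Drinking Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A digital twin of an RFID-gated, volumetrically metered sipper
    device for group-housed rats, and an analysis library for its
    timestamped bout-level (and lick-level) CSV logs. The simulator draws
    per-rat drinking bouts from an inhomogeneous Poisson process shaped by
    the light cycle and two-bottle fluid preference, passes them through a
    firmware model (RFID gating, exclusive spout occupancy, gamma-rhythm
    lick trains, step-quantized peristaltic pump with mechanical noise),
    and exports ground truth for parameter-recovery testing. The analysis
    side computes drinking microstructure from session logs: daily intake
    in g/kg, two-bottle preference, Zeitgeber-binned hourly profiles,
    light/dark-phase totals, bout-size statistics, volume by lick-count
    range, and lick-level measures (interlick interval, interbout interval,
    bout duration, lick frequency), emitting tidy long-format tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
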