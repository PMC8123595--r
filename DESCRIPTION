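Package: dronelab
Title: Drone Logistics Simulation for Hospital Laboratory Sample Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for assessing whether a fixed-schedule drone
    shuttle can carry the complete analytic sample volume between two hospital
    laboratories under a 60-minute turnaround limit for emergency analyses.
    Provides a seeded synthetic demand generator with diurnal and weekly
    structure, truncated-lognormal service-time components fitted from printed
    quantiles, a time-budget algebra for the pre-drone/drone/post-drone
    decomposition, a fixed-interval batching simulator with payload capacity
    and carry-over, a Monte Carlo end-to-end turnaround study with violation
    reporting, and an empirical ground-transport baseline comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
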