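Package: flytrack
Title: Light-Level Geolocation and Spring Migration Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating migration schedules of small birds from
    archival light-level geolocators. Implements the threshold method of
    solar geolocation (NOAA low-precision solar model, twilight detection,
    in-habitat zenith and twilight-error calibration), a Metropolis sampler
    for daily location posteriors with a log-normal twilight-error model,
    a beta-distributed flight-speed prior and an optional land mask,
    change-point segmentation of the posterior track into stationary
    periods, rule-based delimitation of wintering and spring migration
    (initiation, breeding arrival, great-circle distance, rate, stopover
    use), and the group-level statistics used to compare migration
    strategies between populations (group summaries, Gaussian linear
    models with likelihood-ratio backward elimination, Pearson
    correlation). A ground-truthed track and light-series simulator and a
    packaged reference table of Fork-tailed Flycatcher migration histories
    support testing every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
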