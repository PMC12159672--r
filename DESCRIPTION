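Package: phenoacoustics
Title: Insect Acoustic Phenology from Passive Acoustic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring insect acoustic phenology from long-duration
    passive acoustic monitoring. Computes five band-limited acoustic indices
    (acoustic complexity, acoustic diversity, bioacoustic index, acoustic
    entropy and number of frequency peaks) from one-minute recordings,
    screens out rain-contaminated and malfunctioning files, calibrates
    manually annotated insect activity (spectrogram coverage and sonotype
    counts) against the indices with beta-logit and Poisson regressions
    ranked and averaged by AICc, smooths each index over the daily and
    annual cycles with cyclic cubic regression spline additive models, and
    propagates uncertainty from both model stages by chained Monte Carlo
    simulation. A synthetic-soundscape generator produces audio corpora with
    known diel and seasonal activity cycles so every stage of the pipeline
    can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
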