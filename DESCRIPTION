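Package: swarmecho
Title: Monte-Carlo Simulation of Insect-Swarm Echoes for Echolocating Bats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic 3D insect-swarm generation and an analytic
    complex-phasor model of the swarm echo spectrum heard by an
    echolocating bat. Provides Monte-Carlo analyses of echo level versus
    swarm size, spectral interference troughs and the critical signal
    bandwidth, percentile-guaranteed echo levels as a function of call
    bandwidth, the bandwidth versus pulse-repetition trade-off,
    sonar-equation detection ranges under atmospheric attenuation, and
    temporal-integration gain from echo elongation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
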