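Package: oddballr
Title: Auditory Oddball Go/No-Go Task Simulation and Behavioural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing, simulating and analysing go/no-go auditory
    oddball experiments of the kind used to study deviance detection in
    freely moving rodents. Builds constrained stimulus sequences (classic
    oddball, frequency-contrast and many-deviant variants), scores sessions
    of tone and nose-poke events into HIT/FA/CR/MISS trials with latencies,
    reward and timeout accounting, computes signal-detection sensitivity
    (d-prime) with the Hautus log-linear correction, quantifies behavioural
    adaptation as hit rate versus the number of preceding standard tones
    (with a quadratic trend fit), and models within-session engagement with
    single-term exponential fits and their intersection times. A generative
    synthetic-rat agent produces sessions with the statistical structure the
    analyses assume, so the full pipeline runs without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
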