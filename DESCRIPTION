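Package: gonogo
Title: Go/No-Go Nose-Poke Simulation and Perception Threshold Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hardware-free simulation and analysis of a tiered go/no-go
    nose-poke operant paradigm for estimating stimulation-evoked perception
    thresholds in rats. Provides parameterization of charge-balanced biphasic
    intracortical microstimulation (ICMS) pulse trains and amplitude-scaled
    pure tones, piecewise-constant session schedules, a trial-by-trial session
    engine with lockout, timeout and pause rules, a simulated observer with a
    known psychometric function, a modified up/down staircase controller,
    signal-detection performance metrics with paired zero-count correction,
    and quantal dose-response (Hill equation) ED50 threshold estimation with
    a Hill slope shared across sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
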