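Package: pulsefet
Title: Pulsed-Temperature Binding Kinetics and Extended-Gate FET Signal
    Transduction for Trace Ion Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale modelling chain for pulsed-temperature
    electrochemical ion sensors: tabulated free-energy profiles of a
    probe-ion binding coordinate are converted into diffusion-limited
    association rates (Smoluchowski integral over a potential of mean
    force), reverse rates via detailed balance, and temperature-dependent
    rate laws; two-state binding kinetics are integrated under arbitrary
    temperature protocols including hot-sample injection spikes; bound
    interfacial charge is transduced into drain-current changes through a
    Gouy-Chapman-Stern electric-double-layer capacitance model and a
    small-signal transconductance; serial-dilution bookkeeping,
    log-concentration calibration fits, 3-sigma limit-of-detection
    arithmetic, and real-sample back-calculation close the loop.  A
    seeded synthetic-trace generator emulates sensing runs (stepwise
    additions, drift, temperature-scaled noise, injection artifacts) so
    the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
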