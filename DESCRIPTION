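Package: bciutility
Title: BCI-Utility Metric for Asynchronous P300 Spellers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the BCI-Utility throughput metric (bits per second) for
    event-related-potential brain-computer-interface spellers with
    asynchronous features: dynamic stopping, abstention, and intentional
    trial skips.  Provides closed-form utility and expected-time formulas for
    four speller designs, a discrete-event simulator of speller usage whose
    observed average benefit converges to the closed forms, replication of
    the validating simulation studies (grid validation, mean/SD study, and an
    assumption-violation experiment), estimation of all metric parameters
    from recorded session logs, and parameter-sweep and sensitivity tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
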