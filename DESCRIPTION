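Package: damsleep
Title: Sleep and Circadian Analysis of Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses Trikinetics Drosophila Activity Monitor (DAM) text files
    into Zeitgeber-aligned per-fly activity traces and computes the standard
    behavioral sleep statistics for flies: night and day sleep amount, sleep
    bout number and length, latency to sleep, wake after sleep onset (WASO)
    and the consolidation index, all from the five-minute-inactivity sleep
    definition. Also scores mechanical sleep-deprivation rebound and
    light-pulse arousal assays, assesses free-running rhythmicity with the
    Sokolove-Bushell chi-square periodogram, and provides hypergeometric
    gene-set overlap tests with Benjamini-Hochberg adjustment for companion
    transcriptomic gene lists. A two-state Markov simulator generates
    DAM-format data with known ground truth so every analysis stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
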