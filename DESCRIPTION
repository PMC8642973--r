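Package: fusemble
Title: Ensemble Consensus Calling of Gene Fusions from RNA-Seq Fusion Callers
Version: 0.1.0
Authors@R:
    person("IGM", "Bioinformatics", email = "devnull@example.org", role = c("aut", "cre"))
Description: Harmonizes and overlaps gene-fusion predictions from up to seven
    RNA-Seq fusion-calling algorithms (Arriba, CICERO, FusionMap,
    FusionCatcher, JAFFA, MapSplice, STAR-Fusion) into consensus records
    keyed on unordered gene pairs. Reported gene symbols are normalized to
    approved HGNC symbols by alias matching with cytogenetic-band
    disambiguation. Consensus records are filtered for read-through
    transcripts, recurrent cohort artifacts and low read evidence, with a
    curated known-fusion list used to rescue clinically relevant events and
    to score gene partners by their frequency among known pathogenic
    fusions. Includes a cohort frequency store, a benchmarking module
    (sensitivity/precision against a truth set), a deterministic synthetic
    fixture generator emulating each caller's native output dialect, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
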