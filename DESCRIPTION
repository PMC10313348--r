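Package: fragidx
Title: Partitioned Fragment-Ion Indexing and Spectral Library Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a partitioned, intensity-aware fragment-ion index over a
    peptide-annotated MS/MS spectral library (MSP or MGF) and searches
    experimental spectra against it. Candidate spectra are ranked by a binned
    spectral dot product accumulated through the inverted fragment index, then
    rescored with a Gaussian bias-adjusted similarity and a matched-peaks-only
    reflection score. False discovery rates are controlled by target-decoy
    competition with an orthogonal entrapment estimate, and per-match score
    vectors can be exported in Percolator pin-tab format. A deterministic
    synthetic-data generator (tryptic digestion, b/y-ion spectra, decoy and
    entrapment libraries, noisy query runs with ground truth) makes the whole
    pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
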