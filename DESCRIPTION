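Package: dielcycle
Title: Diel Rhythmic Gene Detection and Peak-Phase Classification for
    Sparse Time-Course Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies diel (day/night) rhythmic gene expression
    from replicated abundance matrices sampled over one light/dark cycle
    followed by one continuous-light cycle (eight conditions, four timepoints
    per 24-h period). Provides abundance filtering, replicate concordance,
    condition averaging and z-score normalization; up/down sign-pattern
    extraction with between-period matching and a 14-class peak/trough
    taxonomy (12 unimodal phase classes plus 2 fluctuating classes); a
    periodicity-test ensemble (Lomb-Scargle periodogram with permutation
    null, a rank-based cosine-template test with an exact enumeration null,
    and cosinor harmonic regression) with consensus, sensitivity filtering,
    between-period correlation tagging, and the final partition into
    statistical-rhythmic, general-rhythm and nonrhythmic genes. Includes a
    ground-truth synthetic data generator so the entire pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
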