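Package: quietscape
Title: Composite Urban Quietness Index from Ecoacoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of candidate urban quiet areas from soundscape
    recordings. Reads and conditions WAV audio, computes magnitude
    spectrograms and the ecoacoustic indices ACI (acoustic complexity),
    NDSI (normalized difference soundscape index), ADI/AEI (acoustic
    diversity and evenness) and relative Leq, and combines per-point ACI
    and NDSI values from a nine-point sampling grid (eight edge points
    plus one core point) into the composite urban quietness index (CUQI)
    used to rank areas. A seeded synthetic-soundscape generator produces
    single clips and complete nine-point surveys with controlled
    biophony, anthropophony and background levels, so the whole pipeline
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
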