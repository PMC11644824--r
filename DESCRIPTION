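Package: triterpenlib
Title: Tandem Mass Spectral Library Construction and Matching for Plant
    Triterpenoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-collision-energy tandem mass spectral libraries for
    pentacyclic triterpenoids and limonoids from reference-compound metadata,
    annotates class-specific fragmentations (neutral losses and
    retro-Diels-Alder diagnostic ions), and identifies compounds in query
    feature lists by combined exact-mass, retention-time and MS2 fragment
    matching with metabolomics identification levels. Includes a
    data-dependent-acquisition (DDA) simulator with dynamic exclusion so the
    whole pipeline can be exercised without an instrument, plus MSP/MGF
    readers and writers and a versioned plain-text archive format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
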