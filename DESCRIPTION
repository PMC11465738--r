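Package: camine
Title: Carbonic Anhydrase Mining from Metagenome Annotations and
    Downstream Process Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate carbonic anhydrases (CAs) in
    predicted-protein sets derived from hot-spring metagenomes, and for
    analysing the downstream biochemistry of purified candidates.  The
    screening cascade consumes standard annotation formats (HMMER3 domain
    tables, tabular BLAST, Phobius topology calls, sample metadata) and
    applies domain-profile and similarity evidence, beta-CA active-site
    motif scanning, gene-boundary and length checks, environmental
    filtering, and identity-based de-duplication.  Companion modules
    convert pH-indicator stopped-flow traces into CO2-hydration rates and
    Michaelis-Menten constants, estimate thermal and alkaline stability
    half-lives from residual-activity series, and evaluate pressurized
    batch-reactor CO2 absorption by an ideal-gas mass balance.  Seeded
    synthetic-data generators emulate every input so the whole pipeline is
    testable without raw metagenomes or instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
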