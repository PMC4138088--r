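Package: coatscreen
Title: Domain-Signature Screening for Vesicle-Coat Homologs in Chloroplast Proteomes
Version: 0.1.0
Authors@R:
    person("coatscreen", "developers", email = "coatscreen@example.org",
           role = c("aut", "cre"))
Description: Screens an annotated chloroplast proteome for putative homologs of
    cytosolic vesicle-coat proteins (clathrin triskelion, adaptor protein
    complexes AP1-5, COPI coatomer subcomplexes, and coat-recruiting Arf/Sar
    GTPases) by matching PROSITE/Pfam domain-architecture signatures derived
    from query subunit proteins. Includes a PROSITE pattern parser and scanner
    for pattern-type accessions, integration of subcellular-localization
    evidence (consensus targeting scores and experimental support flags) into
    per-candidate verdicts, a traffic-light classification of subunits and
    candidate loci, a synthetic-data generator with planted ground truth, and
    packaged Arabidopsis and rice fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    stringi
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
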