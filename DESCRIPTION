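Package: fluopeer
Title: Design and In Silico Verification of Fluorescent Prime Editing Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing fluorescent prime editing and enrichment
    reporters and the editing reagents they test. Enumerates protospacer/PAM
    sites around a target edit for prime-editor variants with flexible PAM
    recognition, designs pegRNAs and epegRNAs (primer binding site, reverse
    transcriptase template, 3' extension) under published length and G/C
    constraints, designs PE3/PE3b nicking guides, builds 45-100 nt
    GFP-insert-Cherry reporter cassettes with stop-codon or frameshift
    disruptions and their SalI/Acc65I cloning oligos, and verifies every
    design by deterministic in-silico prime editing, base editing and
    restriction-ligation simulation. Also quantifies editing outcomes from
    flow-cytometry event tables (Cherry/GFP ratio score, enrichment
    fractions) and merged amplicon reads (intended-edit and indel
    percentages within a comparison window around the nick), and ships
    seeded synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    seqinr
Config/testthat/edition: 3
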