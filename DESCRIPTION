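Package: tmRNAcurator
Title: Curation Pipeline for tmRNA Gene Discovery
Version: 1.0.0
Authors@R:
    person("tmRNAcurator", "Developers", email = "tmrnacurator@example.org",
           role = c("aut", "cre"))
Description: An automated, offline-testable re-implementation of a tmRNA gene
    discovery-and-curation workflow: triage of candidate hits from multiple
    search tools with strong/weak designation, tRNA-overlap and contig-end
    truncation rejection, form-aware segment mapping and center-padded chunk
    alignment, automated structural and ORF sanity checks, group I intron
    boundary determination in the TpsiC-loop with subsite assignment and
    homing-endonuclease flagging, seed-alignment identity filtering,
    smallest-clade taxonomy assignment from reference trees, and a seeded
    synthetic tmRNA generator that exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
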