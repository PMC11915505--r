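# tmRNAcurator

Automated curation of transfer–messenger RNA (tmRNA) gene candidates.

tmRNA rescues stalled bacterial ribosomes through *trans*-translation: its
tRNA-like domain is charged with alanine while its mRNA-like region encodes a
short proteolysis **tag** (resume codon through stop codon). Gene-finding
tools (Aragorn, covariance-model search with Infernal, BLASTN against a
curated database) produce abundant candidate hits, but many are false
positives — most often tRNA genes — and the three gene forms complicate
curation: **standard**, **permuted** (circularly permuted, with an
intervening sequence, IVS, absent from the two-piece mature RNA), and
**intron** (interrupted in the TψC-loop by a self-splicing group I intron).

This package re-implements a database-curation workflow for such candidates
as testable, offline-runnable code, for RNA bioinformaticians who need to
triage hits and prepare covariance-model seed alignments:

* **Hit triage** — parsers for Infernal `--tblout`, BLAST `-outfmt 6`,
  tRNAscan-SE tabular and a minimal Aragorn dialect; strong/weak ("S"/"W")
  designation (Aragorn score > 103, Infernal > 140 bits, Rfind/BLASTN > 90,
  all strict); rejection of candidates overlapped > 5 bp by a tRNA scoring
  > 42 bits (unless permuted and strong); rejection of Rfind-only hits
  truncated at a contig end; the conservative intron screen (≥ 500 bp and
  ≥ 150 bits); under-represented-taxon candidate selection; 250-bp flank
  extraction.
* **Segment mapping & chunk alignment** — boundary transfer from a matched
  reference, and the "chunk alignment" in which each named gene segment
  (tRNA-like-5′, CDS, tRNA-like-3′, CCA, IVS, INTRON) is center-padded with
  dashes to the longest instance so boundaries align as columns; Stockholm
  serialization with a per-column segment annotation line.
* **QC checks** — ambiguous-base blocks (runs of ≥ 2), the 7-bp acceptor
  stem (Watson–Crick + G·U; ≥ 2 mismatches flagged, rescuing ±1..3 shifts
  reported), the three CCA-tail positions, the tag reading frame (internal /
  missing terminal stops, declared frameshifts), internal deletions relative
  to related sequences.
* **Group I intron analysis** — boundary determination from the classical
  rules (−1 exon base U pairing an internal G in P1, 3′-terminal ω = G, with
  the minority C(−1)/A(P1) exception) constrained by reconstitution of the
  TψC-loop; subsite assignment at the loop's 8 internucleotide positions;
  equal-weight sequence-logo matrices; homing-endonuclease (LAGLIDADG)
  flagging from HMMER domtblout evidence or an ORF heuristic; a robustness
  simulator inserting up to 2 kb of random sequence at the two HEG sites.
* **Seed-alignment preparation** — pairwise fractional identity, greedy
  identity filtering (the role `esl-weight` plays in CM seed construction),
  and add-back of flagged (HEG-bearing) rows.
* **Taxonomy** — smallest-clade assignment of query leaves on reference
  trees with GTDB-style lineages, and the `__X<n>` serial labeling of taxa
  new to the reference taxonomy.
* **Synthetic data** — a seeded generator emitting every gene form with
  exact ground truth (segment maps, intron boundaries, HEG sites, tag
  peptides), targeted defect planting for every rejection reason, tRNA
  decoys, and emulated tool-output files, so the whole pipeline is testable
  with no downloads.

## Worked example

```r
library(tmRNAcurator)

# a batch of 4 clean genes, one tRNA decoy, one contig-end truncation
clean <- lapply(1:4, function(s) gen_gene(gen_config(seed = s)))
decoy <- plant_defect(gen_gene(gen_config(seed = 5)), "TRNA_OVERLAP", seed = 5)
trunc <- plant_defect(gen_gene(gen_config(seed = 6)), "CONTIG_END_TRUNCATION")
curate_funnel(c(clean, list(decoy, trunc)))
#> Curation funnel:
#>   hits                   6
#>   after_skip_identical   6
#>   after_trna             5
#>   after_dedup            5
#>   after_truncation       4
#>   after_checks           4
```

Six candidate hits enter the funnel; none matches an existing database
sequence; the tRNA-overlapped candidate is rejected (> 5 bp overlap by a
43+-bit tRNA), all survivors are unique, the Rfind-only truncated hit is
dropped, and the four clean genes pass every automated check.

```r
gi <- gen_gene(gen_config(seed = 11, form = "INTRON", intron_subsite = 3,
                          intron_len = 293))
call <- find_intron_boundaries(gi$sequence)
sprintf("intron %d-%d, subsite %d, -1=%s, omega=%s",
        call$intron_start, call$intron_end, call$subsite,
        call$minus1_base, call$omega_base)
#> "intron 111-403, subsite 3, -1=U, omega=G"
identical(call$spliced_exon, gi$truth$exon)
#> TRUE
```

The planted 293-bp intron is recovered exactly at TψC-loop subsite 3 and
excising it restores the pre-insertion exon byte-for-byte.

```r
asm <- vapply(clean, function(r) r$provenance$assembly[1], character(1))
assign_names(deduplicate(clean),
             setNames(rep(c("Escherichia_coli", "Bacillus_subtilis"), 2), asm))
#>             syn000003             syn000002             syn000001
#>  "Escherichia_coli.1" "Bacillus_subtilis.1"  "Escherichia_coli.2"
#>             syn000004
#> "Bacillus_subtilis.2"
```

Each unique sequence is named `<species>.<serial>` by the species where it
is most frequent and its abundance rank within that species.

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript inst/cli/tmrna-curator curate --hits hits.tsv --trna trna.tsv \
    --refs db.fasta --genome genome.fasta --out accepted.tsv
Rscript inst/cli/tmrna-curator dedup --in db.tsv --out uniq.tsv
Rscript inst/cli/tmrna-curator name --in uniq.tsv --species sp.tsv --out names.tsv
```

Every rejection is logged with its reason code and coordinates; all
thresholds can be overridden with `--config` (key–value TSV).

See `vignettes/tmrna-curation.Rmd` for the model, parameter meanings, and
the design decisions behind the checks and the synthetic generator.
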