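---
title: "Curating tmRNA gene candidates: models, rules, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating tmRNA gene candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmRNAcurator)
```

## The problem

tmRNA is the bacterial RNA that rescues stalled ribosomes by
*trans*-translation: a tRNA-like domain delivers alanine, and an mRNA-like
region encodes a short proteolysis tag read from a resume codon to a stop
codon. Gene finders produce many candidate loci, but false positives
(mostly tRNA genes), truncated assemblies, and three distinct gene forms —
standard, circularly permuted (two-piece mature RNA, with an intervening
sequence, IVS, removed by processing), and group-I-intron-containing — make
automated acceptance unsafe without a curation layer. This package is that
layer: deterministic, rule-based triage and quality control, plus the
comparative "chunk alignment" scaffold that human curators use, implemented
so every rule is unit-testable offline.

## The curation funnel

Candidates flow through stages in a fixed order, and every drop carries a
machine-readable reason code:

1. **Skip identical** — sequences identical (case-insensitive, U≡T) to an
   existing database entry are set aside (`DUPLICATE`).
2. **tRNA rejection** — a candidate overlapped by **> 5 bp** by a tRNA
   annotation scoring **> 42 bits** is rejected (`TRNA_OVERLAP`) — *unless*
   the gene form is permuted and the hit is strong, because permuted genes
   legitimately contain tRNA-like structure and occasionally intact tRNAs in
   their IVS.
3. **Deduplication** — one record per unique sequence; instance counts are
   summed and all provenance retained.
4. **Truncation rejection** — when the *only* evidence is a
   database-match (Rfind/BLASTN) hit and the expected mature span runs off
   a contig end, the candidate cannot be verified complete and is rejected
   (`CONTIG_END_TRUNCATION`).
5. **Automated checks** (below).

Hit strength is designated "S" iff the score strictly exceeds the tool
threshold — Aragorn > 103, Infernal > 140 bits, Rfind > 90 — otherwise "W".
All cutoffs live in a single `tm_thresholds()` record; the strict-vs-
inclusive choices follow the published wording exactly (strength and tRNA
cutoffs exclusive; the intron screen's 500 bp / 150 bits inclusive).

## Automated checks (replacing manual inspection)

* **Ambiguous blocks**: any run of ≥ 2 non-ACGT IUPAC characters rejects;
  isolated ambiguity codes pass. The published workflow distinguished
  "large internal blocks" (manual) from "two or more" (automated); we
  implement only the stricter automated rule.
* **Acceptor stem**: the first 7 bases of the tRNA-like-5′ segment must
  pair, antiparallel, the 7 bases preceding the CCA positions. G·U wobble
  counts as pairing — standard for tRNA-like helices; the source procedure
  does not state this and we chose the permissive convention. Two or more
  mismatches flag the record; shifts of the 5′ segment by ±1..3 nt are
  tried (the published "corrected by shifting"; the search bound is ours)
  and a rescuing shift (≤ 1 mismatch) suppresses rejection.
* **CCA positions**: all three positions equivalent to the tRNA CCA tail
  must be present; the bases need not literally be C,C,A.
* **Tag ORF**: the CDS (resume codon through stop, inclusive) is translated;
  an internal stop or a missing terminal stop flags the record. A declared
  frameshift annotation splits the frame and suppresses the flag when both
  sub-frames are clean; a `retain` annotation reproduces the published
  "noted and retained" path. Whether the original procedure's "corrected by
  shifting the alignment" moved segment boundaries or alignment columns is
  ambiguous; we implement boundary shifts only.
* **Internal deletion**: a TRNA5/TRNA3/CDS segment shorter than a
  configurable fraction (default 0.5 — the source says only "large") of the
  minimum among related same-form records flags the record; without
  relatives the check reports UNEVALUATED.

An unrescued acceptor-stem flag, a tag-ORF flag without a
frameshift/retain annotation, and an internal-deletion flag are escalated
to rejections by `run_qc()`: the published handling was "corrected … or
rejected", and a pipeline without a human in the loop must take the second
branch when no automatic correction exists.

## Chunk alignment

For comparative curation, records of one form are "chunk-aligned": each
named segment is padded with dashes inserted contiguously at its center up
to the longest instance of that segment, rows are ordered by taxonomic
lineage, and labels carry the S/W designation. Padding at the center keeps
both segment boundaries aligned as columns while disturbing the segment
interior least. For odd pad counts the insertion point is after position
⌈L/2⌉, i.e. the extra residue stays left — the convention is arbitrary but
fixed. No substitution scoring is involved: chunk alignment is
boundary-anchored padding only, which is exactly what makes it useful for
eyeballing boundary consistency. `unchunk()` inverts it exactly, also after
external edits to the serialized Stockholm (whose `#=GC SEGMENTS` line
carries the per-column segment code).

## Group I intron boundaries

The classical boundary rules: the exon base immediately 5′ of the intron
(−1) is U and pairs an internal G in the intron's P1 stem; the intron's
3′-terminal base (ω) is G. A minority of sequences instead use C(−1)
paired with A. We apply these rules plus a reconstitution constraint: after
excision the T-stem/loop must match the model — stems with at most one
mismatch, exact 8-base loop length, loop bases identical to the model except
at the −1 position itself (which the boundary rule already fixes). The P1
"stem" is a proxy — the partner must occur within the first 15 intron
bases — because full group I secondary-structure prediction is out of scope;
likewise we fix the loop at 8 bases, matching the subsite numbering 1–8 of
the internucleotide positions (subsite *k* lies after loop base *k*). Among
admissible candidates the one maximizing reconstitution matches wins; ties
break to the smallest intron start, then smallest end. These conventions
(window size, tie-break) are stated choices, not derived facts.

Homing endonuclease genes (HEGs) are flagged from HMMER domain tables
(LAGLIDADG hits below an i-E-value cutoff, default 1e−5), or, lacking
evidence, from a forward-frame ORF of ≥ 150 codons; the insertion site is
reported as the nearer of the two known sites (after stem P9, or in the
P7.1 region). `insert_heg_sim()` reproduces the robustness experiment of
inserting up to 2 kb of random sequence at either site.

## Seed-alignment preparation

`greedy_identity_filter()` emulates the role of identity filtering in CM
seed construction: rows are visited in input order and kept iff their
identity to every kept row is strictly below the threshold. Identity
defaults to matches over mutually non-gap columns; the exact internal
definition of the original tool is not restated in its documentation, so
the denominator is configurable (`min_ungapped`, `alignment`) and we do not
claim bit-compatibility. `add_back_flagged()` reinstates rows (e.g.
HEG-bearing introns removed by a 70% filter) in original order.

## Taxonomy assignment

A query leaf on a reference tree is assigned from the **smallest clade**
containing it and at least one reference leaf — operationally, the first
strict ancestor with a labeled descendant. The assignment is the longest
lineage prefix shared by *all* labeled leaves in that clade; how conflicting
labels inside the smallest clade should be resolved is not specified in the
source procedure, and the longest-common-prefix consensus is our choice.
Unrooted inputs are midpoint-rooted with a warning. Genomes not assignable
at species rank get `<prefix>__X<n>` labels with per-prefix serials.

## The synthetic generator: what it emulates, and what it does not

`gen_gene()` emits genes with exact ground truth: a perfectly complementary
7-bp acceptor stem, 3 CCA positions, a tag CDS opening with the GCA
(alanine) resume codon and ending in TAA — 10 aa by default, the most
frequent tag length; the 2-aa configuration produces the known Ala–Ala
extreme — a canonical 5-bp T-stem with an 8-base loop, and per-form
layouts: the permuted layout places the CDS-bearing half upstream of the
IVS and the tRNA-like-5′ segment downstream, so precursor cleavage yields
the two-piece mature RNA (the exact published layout is figure-only
information; ours is stored in one editable table,
`FORM_SEGMENT_ORDER`). Intron fixtures plant the intron at a chosen
subsite with a rule-conformant boundary (U/G or C/A, ω = G, partner within
the first 15 bases). Spacer lengths (4/30 nt), the tRNA-domain filler
lengths, and the 25-nt IVS are fixed realistic-order-of-magnitude choices;
fixtures validate *rules*, not biology — no pseudoknots, no covariation,
no realistic base composition.

Two stated-world properties deserve emphasis:

* **Ambiguity control.** A uniformly random intron interior occasionally
  contains, by chance, an exact "ω-G + loop-suffix + T-stem" motif that
  reconstitutes the TψC-loop exactly as well as the planted boundary. Under
  the boundary rules alone the planted truth is then formally
  unidentifiable — a CM-based search would not be fooled, but a rule-based
  finder has no further evidence. The generator therefore scrubs exact
  T-stem motifs from its random segments, validates that its planted
  boundary is the unique best call (deterministic rejection sampling on the
  seed), and `insert_heg_sim()` draws its random insert conditioned on not
  recreating an exact stem motif. C/A-rule fixtures additionally require
  that no canonical U/G boundary exists, mirroring the published exception
  sequences, which were identified precisely because the U/G rules failed
  on them.
* **Determinism.** Every stochastic entry point threads an explicit seed
  and runs under a saved/restored RNG state; identical configurations are
  byte-identical, and nothing in the package perturbs the caller's RNG.

Consequently, a green test establishes that the rules are implemented as
stated and are mutually consistent on rule-conformant inputs — not that the
pipeline would reproduce the published database from real genomes, which
requires the external search tools and hundreds of thousands of genomes.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, in code and on disk,
  matching R string semantics and the tabular formats parsed.
* Sequence identity for deduplication is case-insensitive with U read as T;
  naming ties break by lexicographic sequence, then species label, under C
  collation (locale-independent).
* Empty candidate batches yield an all-zero funnel, not an error; an empty
  tRNA table rejects nothing; an intron-free gene yields "no call" rather
  than an error.
* The under-represented-taxon selection rule ("at least 20 genomes with
  failed identification in > 50% of genomes") is ambiguous between ≥ 20
  *failed* genomes (our default) and ≥ 20 genomes *total*; both readings
  are exposed via the `interpretation` argument of `phase2_candidates()`.

## Known limitations

* No secondary-structure prediction: pseudoknots, the P3–P9 intron core,
  and structure drawing are out of scope (delegated to dedicated tools in
  the original workflow).
* The Aragorn parser reads a minimal tab dialect, not Aragorn's free-text
  report; converting the latter is an extension point.
* `flag_heg()`'s ORF heuristic scans forward frames only and cannot
  distinguish LAGLIDADG from other long ORFs without domain evidence.
* The chunk alignment orders rows by lineage string; it does not build or
  use a tree.
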