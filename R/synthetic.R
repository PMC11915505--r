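#' Generator configuration
#'
#' Parameters of the synthetic tmRNA fixture generator.  Defaults state the
#' published conditions: 10-aa tag (the most frequent tag length; the extreme
#' short form is 2 aa, Ala-Ala), 250-bp flanks, a canonical 5-bp T-stem with
#' an 8-base loop, and group I introns inserted at TpsiC-loop subsites with a
#' U(-1)/G(P1)/G(omega) boundary (or the minority C(-1)/A(P1) rule).
#'
#' @param seed integer RNG seed; identical configs are byte-reproducible.
#' @param form one of [GENE_FORMS].
#' @param tag_len_aa tag peptide length in amino acids (>= 2).
#' @param tloop a [tloop_model()].
#' @param intron_subsite TpsiC-loop subsite 1-8 (INTRON form only;
#'   default 7, the historically known site).
#' @param intron_len intron length in bp before any HEG (>= 40).
#' @param heg_len length of a planted homing-endonuclease ORF in bp
#'   (0 = none; rounded down to whole codons).
#' @param minus1_rule `"UG"` (canonical) or `"CA"` (minority exception).
#' @param flank_bp flanking sequence retained in the synthetic contig.
#' @param id,species record identifier and species label.
#' @return list of class `gen_config`.
#' @export
gen_config <- function(seed, form = "STANDARD", tag_len_aa = 10L,
                       tloop = tloop_model(), intron_subsite = NULL,
                       intron_len = 300L, heg_len = 0L,
                       minus1_rule = c("UG", "CA"), flank_bp = 250L,
                       id = sprintf("syn%06d", seed),
                       species = NA_character_) {
  minus1_rule <- match.arg(minus1_rule)
  if (!form %in% GENE_FORMS) stop("gen_config: unknown form '", form, "'")
  if (!is.null(intron_subsite) && form != "INTRON") {
    stop("gen_config: intron_subsite given but form is not INTRON")
  }
  if (form == "INTRON") {
    intron_subsite <- intron_subsite %||% 7L
    if (!intron_subsite %in% 1:8) stop("gen_config: intron_subsite must be 1-8")
    if (intron_len < 40L) stop("gen_config: intron_len must be >= 40")
  }
  if (tag_len_aa < 2L) stop("gen_config: tag_len_aa must be >= 2")
  if (heg_len < 0L || flank_bp < 0L) stop("gen_config: lengths must be non-negative")
  structure(list(seed = as.integer(seed), form = form,
                 tag_len_aa = as.integer(tag_len_aa), tloop = tloop,
                 intron_subsite = intron_subsite,
                 intron_len = as.integer(intron_len),
                 heg_len = as.integer(heg_len), minus1_rule = minus1_rule,
                 flank_bp = as.integer(flank_bp), id = id, species = species),
            class = "gen_config")
}

#' Generate a synthetic tmRNA gene with ground truth
#'
#' Emits a gene with an exact segment map: a perfectly complementary 7-bp
#' acceptor stem, three CCA-tail positions, a tag CDS opening with the GCA
#' resume codon and closing with TAA, and a canonical T-stem/loop.  The
#' INTRON form carries a group I intron at the configured subsite whose
#' boundaries obey the -1/P1/omega rules; the PERMUTED forms carry an IVS
#' between the CCA-bearing half and the downstream tRNA-like-5' segment.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg a [gen_config()].
#' @return a [gene_record()] whose `truth` field holds the generator ground
#'   truth (intron boundaries, subsite, pre-insertion exon, HEG sites, tag
#'   peptide) and whose `hit` field emulates the discovering tool hit.
#' @export
gen_gene <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  # Rejection-validate INTRON fixtures: the planted boundary must be the
  # unique best call under the boundary rules, or the ground-truth
  # annotation would be meaningless.  Deterministic under cfg$seed.
  for (attempt in 0:24) {
    rec <- with_seed(cfg$seed + 7919L * attempt, gen_gene_impl(cfg))
    if (cfg$form != "INTRON") return(rec)
    call <- find_intron_boundaries(rec$sequence, cfg$tloop,
                                   allow_CA = cfg$minus1_rule == "CA")
    if (!is.null(call) && call$intron_start == rec$truth$intron[1] &&
        call$intron_end == rec$truth$intron[2]) {
      # C/A fixtures mirror the published exception sequences, for which no
      # boundary obeying the canonical U/G rules exists
      if (cfg$minus1_rule == "CA" &&
          !is.null(find_intron_boundaries(rec$sequence, cfg$tloop,
                                          allow_CA = FALSE))) next
      return(rec)
    }
  }
  stop("gen_gene: could not generate an unambiguous intron fixture")
}

# random DNA free of exact T-stem motifs, which would plant rule-ambiguous
# alternative splice boundaries in the fixture
random_dna_clean <- function(n, avoid) {
  repeat_until_clean(avoid, function() random_dna(n))
}

repeat_until_clean <- function(avoid, make) {
  repeat {
    s <- make()
    if (!any(vapply(avoid, grepl, logical(1), x = s, fixed = TRUE))) return(s)
  }
}

gen_gene_impl <- function(cfg) {
  tl <- cfg$tloop
  avoid <- unique(c(tl$stem5, tl$stem3))
  acc5 <- random_dna_clean(7L, avoid)
  trna5 <- paste0(acc5, random_dna_clean(18L, avoid))
  spacer1 <- random_dna(4L)
  has_cds <- !grepl("_NO_CDS$", cfg$form)
  cds <- if (has_cds) {
    repeat {
      # the extreme short tag is Ala-Ala; longer tags open with the alanine
      # resume codon followed by arbitrary sense codons
      body <- if (cfg$tag_len_aa == 2L) "GCAGCA" else {
        paste(c("GCA", replicate(cfg$tag_len_aa - 1L, random_codon())),
              collapse = "")
      }
      if (!any(vapply(avoid, grepl, logical(1), x = body, fixed = TRUE))) break
    }
    paste0(body, "TAA")
  } else NULL
  spacer2 <- random_dna_clean(30L, avoid)
  prefix3 <- random_dna_clean(10L, avoid)
  var3 <- random_dna(4L)
  acc3 <- revcomp(acc5)
  loop <- s2c(tl$loop)
  truth <- list(tloop = tl)

  intron <- NULL
  k <- cfg$intron_subsite
  if (cfg$form == "INTRON") {
    if (cfg$minus1_rule == "CA") loop[k] <- "C"
    partner <- if (loop[k] == "T") "G" else "A"
    core <- s2c(random_dna_clean(cfg$intron_len, avoid))
    core[1L] <- "A"                    # forestall a shifted -1 U inside the intron
    core[6L] <- partner                # P1 pairing partner within the first 15 bases
    core[length(core) - 1L] <- "A"     # penultimate base: no shifted omega G
    core[length(core)] <- "G"          # omega
    if (cfg$heg_len >= 6L) {
      codons <- cfg$heg_len %/% 3L
      orf <- repeat_until_clean(avoid, function() {
        paste0("ATG", paste(replicate(codons - 2L, random_codon()),
                            collapse = ""), "TAA")
      })
      at <- length(core) %/% 2L
      core <- c(core[1:at], s2c(orf), core[(at + 1L):length(core)])
    }
    intron <- c2s(core)
  }
  loop <- c2s(loop)
  trna3_full <- paste0(prefix3, tl$stem5, loop, tl$stem3, var3, acc3)
  ivs <- random_dna(25L)

  pieces <- switch(cfg$form,
    STANDARD = list(TRNA5 = trna5, SPACER1 = spacer1, CDS = cds,
                    SPACER2 = spacer2, TRNA3 = trna3_full, CCA = "CCA"),
    STANDARD_NO_CDS = list(TRNA5 = trna5, SPACER1 = spacer1,
                           TRNA3 = trna3_full, CCA = "CCA"),
    PERMUTED = list(CDS = cds, SPACER2 = spacer2, TRNA3 = trna3_full,
                    CCA = "CCA", IVS = ivs, TRNA5 = trna5),
    PERMUTED_NO_CDS = list(TRNA3 = trna3_full, CCA = "CCA", IVS = ivs,
                           TRNA5 = trna5),
    INTRON = {
      t3a <- paste0(prefix3, tl$stem5, substr(loop, 1L, k))
      t3b <- paste0(substr(loop, k + 1L, 8L), tl$stem3, var3, acc3)
      list(TRNA5 = trna5, SPACER1 = spacer1, CDS = cds, SPACER2 = spacer2,
           TRNA3 = t3a, INTRON = intron, TRNA3.2 = t3b, CCA = "CCA")
    })
  seg_names <- sub("\\.[0-9]+$", "", names(pieces))
  lens <- nchar(unlist(pieces, use.names = FALSE))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  gene <- paste(unlist(pieces, use.names = FALSE), collapse = "")
  segments <- segment_map(seg_names, starts, ends)

  if (cfg$form == "INTRON") {
    irow <- which(seg_names == "INTRON")
    truth$intron <- c(starts[irow], ends[irow])
    truth$subsite <- k
    truth$minus1 <- chartr("T", "U", substr(gene, starts[irow] - 1L, starts[irow] - 1L))
    truth$exon <- paste0(substr(gene, 1L, starts[irow] - 1L),
                         substr(gene, ends[irow] + 1L, nchar(gene)))
    truth$heg_sites <- c(in_P7.1 = starts[irow] - 1L + (ends[irow] - starts[irow] + 1L) %/% 2L,
                         after_P9 = ends[irow] - 10L)
  }
  if (has_cds) {
    crow <- which(seg_names == "CDS")
    aa <- translate_frame(substr(gene, starts[crow], ends[crow]))
    truth$tag <- paste(aa[-length(aa)], collapse = "")
  }

  flankL <- random_dna(cfg$flank_bp)
  flankR <- random_dna(cfg$flank_bp)
  contig <- paste0(flankL, gene, flankR)
  gstart <- cfg$flank_bp + 1L
  gend <- cfg$flank_bp + nchar(gene)
  assembly <- sprintf("SYNASM%06d", cfg$seed)
  ctg_name <- sprintf("SYNCTG%06d", cfg$seed)   # unique contig per fixture
  provenance <- data.frame(assembly = assembly, contig = ctg_name,
                           start = gstart, end = gend, strand = "+",
                           stringsAsFactors = FALSE)
  hit <- list(tool = "ARAGORN", tools = c("ARAGORN", "RFIND_BLAST"),
              score = round(runif(1, 104, 135), 1), contig = ctg_name,
              start = gstart, end = gend, strand = "+",
              form_guess = cfg$form, strength = "S",
              contig_length = nchar(contig), mature_span = c(gstart, gend),
              phase = 1L)
  gene_record(id = cfg$id, sequence = gene, form = cfg$form,
              segments = segments, species = cfg$species,
              provenance = provenance, hit = hit, truth = truth,
              contig_seq = contig, cfg = cfg)
}

# remove gene positions a..b, shrinking/dropping segments and keeping the
# provenance end in step
delete_span <- function(record, a, b) {
  n <- nchar(record$sequence)
  w <- b - a + 1L
  record$sequence <- paste0(substr(record$sequence, 1L, a - 1L),
                            substr(record$sequence, b + 1L, n))
  seg <- as.data.frame(record$segments)
  seg$start <- vapply(seg$start, function(p) {
    if (p > b) p - w else if (p >= a) a else p
  }, integer(1))
  seg$end <- vapply(seg$end, function(p) {
    if (p > b) p - w else if (p >= a) a - 1L else p
  }, integer(1))
  keep <- seg$end >= seg$start
  record$segments <- segment_map(seg$segment[keep], seg$start[keep], seg$end[keep])
  record$provenance$end <- record$provenance$end - w
  record
}

#' Plant a curation defect in a clean synthetic gene
#'
#' Minimally mutates a generator record so that exactly the targeted
#' ingest/QC rule fires: an NN block (AMBIGUOUS_BLOCK), a >= 2-mismatch
#' acceptor stem with no rescuing shift (ACCEPTOR_STEM), deleted CCA
#' positions (MISSING_CCA), an internal stop codon (TAG_ORF), an Rfind-only
#' hit whose mature span runs off the contig end (CONTIG_END_TRUNCATION), a
#' high-scoring overlapping tRNA annotation (TRNA_OVERLAP, stored in
#' `$planted_trna`), a sub-cutoff phase-3 intron hit (SIZE_SCORE_CUTOFF), a
#' gutted CDS relative to its relatives (INTERNAL_DELETION), or a sequence
#' identical to an existing database entry (DUPLICATE, marked with
#' `$plant_duplicate` for the caller to mirror into the reference set).
#'
#' @param record a clean [gen_gene()] record.
#' @param reason one of [REJECT_REASONS].
#' @param seed RNG seed for the stochastic plants.
#' @return the mutated record.
#' @export
plant_defect <- function(record, reason, seed = 1L) {
  if (!reason %in% REJECT_REASONS) stop("plant_defect: unknown reason '", reason, "'")
  seg <- function(nm) segment_lookup(record$segments, nm)
  switch(reason,
    AMBIGUOUS_BLOCK = {
      host <- Filter(function(nm) nrow(seg(nm)) > 0L,
                     c("SPACER2", "SPACER1", "IVS"))
      if (!length(host)) stop("plant_defect: no spacer segment to host an N block")
      s <- seg(host[[1L]])
      at <- s$start[1] + (s$end[1] - s$start[1]) %/% 2L
      substr(record$sequence, at, at + 1L) <- "NN"
      record
    },
    ACCEPTOR_STEM = {
      t5 <- seg("TRNA5"); cca <- seg("CCA")
      stopifnot(nrow(t5) == 1L, nrow(cca) == 1L)
      break_pair <- function(rec, idx) {
        # idx: stem position 1..7 (5' side); mutate the paired 3'-side base
        a <- substr(rec$sequence, t5$start + idx - 1L, t5$start + idx - 1L)
        pos3 <- cca$start - idx        # antiparallel partner
        for (b in DNA_BASES) {
          if (!pairs_ok(a, b)) {
            substr(rec$sequence, pos3, pos3) <- b
            return(rec)
          }
        }
        rec
      }
      rec <- break_pair(break_pair(record, 2L), 4L)
      extra <- c(1L, 3L, 5L, 6L, 7L)
      while (length(extra)) {
        ck <- check_acceptor_stem(rec)
        if (ck$outcome == "FLAG" && length(ck$details$rescue_shifts) == 0L) break
        rec <- break_pair(rec, extra[1L])
        extra <- extra[-1L]
      }
      rec
    },
    MISSING_CCA = {
      cca <- seg("CCA")
      stopifnot(nrow(cca) == 1L)
      delete_span(record, cca$start, cca$end)
    },
    TAG_ORF = {
      cds <- seg("CDS")
      if (nrow(cds) == 0L) stop("plant_defect: TAG_ORF needs a CDS segment")
      ncod <- (cds$end - cds$start + 1L) %/% 3L
      at <- cds$start + 3L * (min(3L, ncod - 2L) - 1L)   # an internal codon
      substr(record$sequence, at, at + 2L) <- "TAA"
      record
    },
    CONTIG_END_TRUNCATION = {
      record$hit$tool <- "RFIND_BLAST"
      record$hit$tools <- "RFIND_BLAST"
      record$hit$score <- 95
      record$hit$strength <- "S"
      record$hit$mature_span <- c(record$provenance$start[1],
                                  record$provenance$end[1] + 30L)
      record$hit$contig_length <- record$provenance$end[1]
      record
    },
    TRNA_OVERLAP = {
      record$hit$strength <- "W"       # the permuted+strong exception needs S
      decoy <- gen_trna_decoy(seed, hit = record$hit, score = 80, overlap = 60L)
      record$planted_trna <- decoy$hit
      record
    },
    DUPLICATE = {
      record$plant_duplicate <- TRUE
      record
    },
    SIZE_SCORE_CUTOFF = {
      if (record$form != "INTRON") {
        stop("plant_defect: SIZE_SCORE_CUTOFF applies to intron-form CM hits")
      }
      record$hit$phase <- 3L
      record$hit$tool <- "INFERNAL"
      record$hit$tools <- "INFERNAL"
      record$hit$score <- 149          # just below the 150-bit cutoff
      record
    },
    INTERNAL_DELETION = {
      cds <- seg("CDS")
      if (nrow(cds) == 0L) stop("plant_defect: INTERNAL_DELETION needs a CDS segment")
      # gut the CDS to resume codon + one codon + stop: ORF stays clean but
      # the segment shrinks far below relatives
      delete_span(record, cds$start + 6L, cds$end - 3L)
    })
}

#' Emit a tRNA decoy annotation overlapping a candidate
#'
#' Produces a tRNAscan-style annotation (plus a random tRNA-sized sequence)
#' overlapping the given candidate hit, with configurable score and overlap
#' so both sides of the >5 bp / >42 bit rejection boundary can be exercised.
#'
#' @param seed RNG seed.
#' @param hit candidate hit to overlap (list with contig/start/end); a
#'   default synthetic location is used when omitted.
#' @param score tRNA bit score.
#' @param overlap overlap with the candidate in bp.
#' @return list: `hit` (a one-row `trna_hits` data.frame), `sequence`.
#' @export
gen_trna_decoy <- function(seed, hit = NULL, score = 80, overlap = 60L) {
  if (is.null(hit)) hit <- list(contig = "ctg1", start = 1000L, end = 1350L)
  start <- hit$start
  end <- hit$start + overlap - 1L
  df <- data.frame(contig = hit$contig, start = start, end = end, strand = "+",
                   score = score, isotype = "Ala", stringsAsFactors = FALSE)
  class(df) <- c("trna_hits", "data.frame")
  list(hit = df, sequence = with_seed(seed, random_dna(72L)))
}

#' Emulate tool-output files for synthetic records
#'
#' Writes syntactically valid Infernal `--tblout`, BLAST `-outfmt 6`,
#' tRNAscan-SE tabular, or minimal-Aragorn files describing the records, so
#' that `parse_hits(emit_tool_files(x))` is lossless for the fields both
#' sides carry.  Byte-stable for fixed inputs.
#'
#' @param records list of generator [gene_record()]s (for `trnascan_tab`, a
#'   `trna_hits` data.frame).
#' @param dialect as in [parse_hits()].
#' @param path optional output file.
#' @return the file lines (invisibly when written to `path`).
#' @export
emit_tool_files <- function(records, dialect, path = NULL) {
  fmt_score <- function(x) sprintf("%.1f", x)
  lines <- switch(dialect,
    infernal_tblout = {
      hdr <- c("#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description of target",
               "#------------------- --------- -------------------- --------- --- -------- -------- -------- -------- ------ ----- ---- ---- ----- ------ --------- --- ---------------------")
      rows <- vapply(records, function(r) {
        p <- r$provenance[1, ]
        minus <- p$strand == "-"
        paste(p$contig, "-", "tmRNA", "RF00023", "cm", 1, nchar(r$sequence),
              if (minus) p$end else p$start, if (minus) p$start else p$end,
              p$strand, "no", 1, "0.50", "0.0", fmt_score(r$hit$score),
              "1.0e-20", "!", "-", sep = " ")
      }, character(1))
      c(hdr, rows)
    },
    blast_tab6 = {
      c("#qseqid\tsseqid\tpident\tlength\tmismatch\tgapopen\tqstart\tqend\tsstart\tsend\tevalue\tbitscore",
        vapply(records, function(r) {
        p <- r$provenance[1, ]
        minus <- p$strand == "-"
        n <- nchar(r$sequence)
        paste(r$id, p$contig, "100.000", n, 0, 0, 1, n,
              if (minus) p$end else p$start, if (minus) p$start else p$end,
              "1.0e-50", fmt_score(r$hit$score), sep = "\t")
      }, character(1)))
    },
    aragorn = {
      c("#contig\tstart\tend\tstrand\tscore\tform",
        vapply(records, function(r) {
          p <- r$provenance[1, ]
          paste(p$contig, p$start, p$end, p$strand, fmt_score(r$hit$score),
                r$form, sep = "\t")
        }, character(1)))
    },
    trnascan_tab = {
      df <- records
      c("#Sequence\ttRNA#\tBegin\tEnd\tType\tCodon\tIntronBegin\tIntronEnd\tScore",
        vapply(seq_len(nrow(df)), function(i) {
          minus <- df$strand[i] == "-"
          paste(df$contig[i], i,
                if (minus) df$end[i] else df$start[i],
                if (minus) df$start[i] else df$end[i],
                df$isotype[i], "NNN", 0, 0, fmt_score(df$score[i]), sep = "\t")
        }, character(1)))
    },
    stop("emit_tool_files: unknown dialect '", dialect, "'"))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
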