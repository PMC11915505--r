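#' Strong/weak designation of candidate hits
#'
#' A hit is designated "S" (strong) iff its score strictly exceeds the
#' tool-specific threshold: Aragorn >103, Infernal >140 bits, Rfind (BLASTN)
#' >90; otherwise "W" (weak).  Monotone in score for a fixed tool.
#'
#' @param hits a `candidate_hits` data.frame (or anything with `tool` and
#'   `score` columns).
#' @param thresholds a [tm_thresholds()].
#' @return the hits with the `strength` column set to "S"/"W".
#' @export
designate_strength <- function(hits, thresholds = tm_thresholds()) {
  cut <- c(ARAGORN = thresholds$aragorn_strong,
           INFERNAL = thresholds$infernal_strong,
           RFIND_BLAST = thresholds$rfind_strong)
  if (!all(hits$tool %in% names(cut))) {
    stop("designate_strength: unknown tool kind(s): ",
         paste(setdiff(unique(hits$tool), names(cut)), collapse = ", "))
  }
  hits$strength <- ifelse(hits$score > cut[hits$tool], "S", "W")
  hits
}

#' Extract a hit region with flanks from a genome
#'
#' Returns the hit interval extended by `flank_bp` on each side, clipped at
#' contig ends; minus-strand hits are reverse-complemented.  The offset record
#' maps extracted (plus-orientation of the hit) positions back to contig
#' coordinates.
#'
#' @param hit one row of a `candidate_hits` data.frame (or a list with contig,
#'   start, end, strand).
#' @param genome named character vector of contig sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param flank_bp flank width (default from [tm_thresholds()]: 250).
#' @return list: `sequence`, `contig`, `region_start`, `region_end` (contig
#'   coordinates of the extracted slice), `strand`, and `to_contig(pos)`
#'   mapping extracted positions to contig coordinates.
#' @export
extract_region <- function(hit, genome, flank_bp = tm_thresholds()$flank_bp) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!hit$contig %in% names(genome)) {
    stop("extract_region: contig '", hit$contig, "' absent from genome")
  }
  ctg <- genome[[hit$contig]]
  n <- nchar(ctg)
  if (hit$start < 1L || hit$end > n) stop("extract_region: hit outside contig")
  a <- max(1L, hit$start - flank_bp)
  b <- min(n, hit$end + flank_bp)
  slice <- substr(ctg, a, b)
  minus <- identical(hit$strand, "-")
  seq <- if (minus) revcomp(slice) else slice
  len <- b - a + 1L
  to_contig <- if (minus) function(pos) b - pos + 1L else function(pos) a + pos - 1L
  list(sequence = norm_seq(seq), contig = hit$contig, region_start = a,
       region_end = b, strand = hit$strand, length = len, to_contig = to_contig)
}

overlap_bp <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2) + 1L)

#' Reject candidate hits overlapping tRNA genes
#'
#' A candidate is rejected iff some tRNA on the same contig overlaps it by
#' strictly more than `trna_overlap_bp` bases (default 5) AND that tRNA
#' scores strictly more than `trna_score` bits (default 42) -- unless the gene
#' form is permuted and the hit is strong.  Overlap is computed strand-blind
#' on contig coordinates.
#'
#' @param hit one candidate hit (list/row with contig, start, end, form_guess,
#'   strength).
#' @param trnas a `trna_hits` data.frame.
#' @param thresholds a [tm_thresholds()].
#' @return `TRUE` to keep, or `FALSE` with attribute `reason = "TRNA_OVERLAP"`.
#' @export
filter_trna_overlap <- function(hit, trnas, thresholds = tm_thresholds()) {
  keep <- structure(TRUE, reason = NULL)
  if (is.null(trnas) || nrow(trnas) == 0L) return(keep)
  if (identical(hit$form_guess, "PERMUTED") && identical(hit$strength, "S")) {
    return(keep)
  }
  same <- trnas[trnas$contig == hit$contig, , drop = FALSE]
  for (i in seq_len(nrow(same))) {
    ov <- overlap_bp(hit$start, hit$end, same$start[i], same$end[i])
    if (ov > thresholds$trna_overlap_bp && same$score[i] > thresholds$trna_score) {
      return(structure(FALSE, reason = "TRNA_OVERLAP"))
    }
  }
  keep
}

#' Reject Rfind-only hits truncated at a contig end
#'
#' When the only evidence for a locus is an Rfind (BLASTN) hit and the
#' expected mature tmRNA span, mapped from the reference, extends past a
#' contig end, the assignment is rejected.
#'
#' @param hit candidate hit carrying `tools` (character vector of tool kinds
#'   at the locus; falls back to `tool`) and `contig_length`.
#' @param mature_span length-2 integer vector: expected mature-sequence
#'   interval on the contig, 1-based inclusive.
#' @return `TRUE` to keep, or `FALSE` with attribute
#'   `reason = "CONTIG_END_TRUNCATION"`.
#' @export
filter_contig_end_truncation <- function(hit, mature_span) {
  tools <- hit$tools %||% hit$tool
  if (!identical(sort(unique(unlist(tools))), "RFIND_BLAST")) {
    return(structure(TRUE, reason = NULL))
  }
  n <- hit$contig_length
  if (is.null(n) || is.na(n)) stop("filter_contig_end_truncation: contig_length unset")
  if (mature_span[1] < 1L || mature_span[2] > n) {
    return(structure(FALSE, reason = "CONTIG_END_TRUNCATION"))
  }
  structure(TRUE, reason = NULL)
}

#' Conservative screen for intron-form CM hits
#'
#' Keep iff hit length >= `intron_min_len` (500 bp; the smallest known intron
#' form is 545 bp) AND bit score >= `intron_min_bits` (150; the lowest known
#' intron bit score is 225.3).  Both cutoffs inclusive.
#'
#' @param hit candidate hit with start/end and score (bits).
#' @param thresholds a [tm_thresholds()].
#' @return `TRUE` to keep, or `FALSE` with attribute
#'   `reason = "SIZE_SCORE_CUTOFF"`.
#' @export
filter_intron_phase3 <- function(hit, thresholds = tm_thresholds()) {
  len <- hit$end - hit$start + 1L
  if (len >= thresholds$intron_min_len && hit$score >= thresholds$intron_min_bits) {
    structure(TRUE, reason = NULL)
  } else {
    structure(FALSE, reason = "SIZE_SCORE_CUTOFF")
  }
}

#' Select under-represented taxa and their best per-genome candidates
#'
#' Selects taxa whose tmRNA identification failed broadly -- by default at
#' least 20 genomes with failed identification AND a failure fraction > 0.5
#' (the alternative reading, at least 20 genomes total with > 50 percent
#' failure, is available via `interpretation = "total"`) -- removes any
#' selected taxon nested inside another selected taxon, and returns the single
#' highest-scoring CM hit for each tmRNA-lacking genome in the surviving taxa.
#'
#' @param taxon_stats data.frame: taxon, genomes_total, genomes_with_tmrna.
#' @param nesting named character vector child taxon -> parent taxon (roots
#'   map to `NA`); must be a forest.
#' @param hits data.frame of CM hits for tmRNA-lacking genomes: genome, taxon,
#'   score plus any hit columns.
#' @param interpretation `"failed"` (default) or `"total"`.
#' @return list: `selected_taxa` (character) and `candidates` (one best hit
#'   row per genome, deterministic ties by first occurrence).
#' @export
phase2_candidates <- function(taxon_stats, nesting, hits,
                              interpretation = c("failed", "total")) {
  interpretation <- match.arg(interpretation)
  failed <- taxon_stats$genomes_total - taxon_stats$genomes_with_tmrna
  frac <- failed / taxon_stats$genomes_total
  sel <- if (interpretation == "failed") failed >= 20L & frac > 0.5 else
    taxon_stats$genomes_total >= 20L & frac > 0.5
  selected <- taxon_stats$taxon[sel]
  # drop selected taxa nested inside another selected taxon
  ancestors <- function(tx) {
    out <- character(0)
    cur <- tx
    seen <- tx
    repeat {
      p <- if (cur %in% names(nesting)) nesting[[cur]] else NA_character_
      if (is.na(p)) break
      if (p %in% seen) stop("phase2_candidates: cyclic nesting at '", p, "'")
      out <- c(out, p)
      seen <- c(seen, p)
      cur <- p
    }
    out
  }
  nested <- vapply(selected, function(tx) any(ancestors(tx) %in% selected),
                   logical(1))
  selected <- selected[!nested]
  cand <- hits[hits$taxon %in% selected, , drop = FALSE]
  best <- lapply(split(seq_len(nrow(cand)), cand$genome), function(idx) {
    cand[idx[which.max(cand$score[idx])], , drop = FALSE]
  })
  candidates <- if (length(best)) do.call(rbind, best) else cand
  rownames(candidates) <- NULL
  list(selected_taxa = selected, candidates = candidates)
}

#' Cluster hits from multiple tools into loci
#'
#' Hits overlapping by at least 1 bp on the same contig and strand are merged
#' into one locus carrying the union of tool kinds and the per-tool best
#' scores.
#'
#' @param hits a `candidate_hits` data.frame.
#' @return data.frame: contig, start, end, strand, tools (list column),
#'   best_score per locus.
#' @export
cluster_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      best_score = numeric(0)))
  }
  hits <- hits[order(hits$contig, hits$strand, hits$start, method = "radix"), ,
               drop = FALSE]
  loci <- list()
  cur <- NULL
  flush <- function(cur, loci) { loci[[length(loci) + 1L]] <- cur; loci }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    if (!is.null(cur) && h$contig == cur$contig && h$strand == cur$strand &&
        h$start <= cur$end) {
      cur$end <- max(cur$end, h$end)
      cur$tools <- union(cur$tools, h$tool)
      cur$best_score <- max(cur$best_score, h$score)
    } else {
      if (!is.null(cur)) loci <- flush(cur, loci)
      cur <- list(contig = h$contig, start = h$start, end = h$end,
                  strand = h$strand, tools = h$tool, best_score = h$score)
    }
  }
  loci <- flush(cur, loci)
  out <- data.frame(contig = vapply(loci, `[[`, character(1), "contig"),
                    start = vapply(loci, `[[`, integer(1), "start"),
                    end = vapply(loci, `[[`, integer(1), "end"),
                    strand = vapply(loci, `[[`, character(1), "strand"),
                    best_score = vapply(loci, `[[`, numeric(1), "best_score"),
                    stringsAsFactors = FALSE)
  out$tools <- lapply(loci, `[[`, "tools")
  out
}
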