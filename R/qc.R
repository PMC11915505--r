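#' Automated curation sanity checks
#'
#' These checks replace the manual inspection step of the original workflow
#' with testable rules: ambiguous-base blocks, the 7-bp acceptor stem, the
#' three CCA-tail positions, the tag reading frame, and internal deletions
#' relative to related sequences.
#'
#' @name qc-checks
NULL

qc_outcome <- function(outcome, reason = NULL, ...) {
  list(outcome = outcome, reason = reason, details = list(...))
}

#' @describeIn qc-checks REJECT iff the sequence contains a run of two or more
#'   consecutive ambiguous (non-ACGT IUPAC) bases; isolated ambiguity codes
#'   pass.  Spans of offending blocks are reported.
#' @param seq uppercase nucleotide string.
#' @export
check_ambiguous_blocks <- function(seq) {
  if (!nzchar(seq %||% "")) stop("check_ambiguous_blocks: empty sequence")
  seq <- norm_seq(seq)
  m <- gregexpr("[^ACGT]{2,}", seq)[[1]]
  if (m[1] == -1L) return(qc_outcome("PASS"))
  spans <- cbind(start = as.integer(m),
                 end = as.integer(m) + attr(m, "match.length") - 1L)
  qc_outcome("REJECT", reason = "AMBIGUOUS_BLOCK", spans = spans)
}

acceptor_stem_mismatches <- function(seq, trna5_start, cca_start, shift = 0L) {
  p5 <- trna5_start + shift
  if (p5 < 1L || p5 + 6L > nchar(seq) || cca_start - 7L < 1L) return(NA_integer_)
  s5 <- s2c(substr(seq, p5, p5 + 6L))
  s3 <- s2c(substr(seq, cca_start - 7L, cca_start - 1L))
  # antiparallel: stem position i pairs position 8 - i of the 3' side
  sum(!pairs_ok(s5, rev(s3)))
}

#' @describeIn qc-checks pairs the first 7 bases of the tRNA-like-5' segment
#'   with the 7 bases preceding the CCA positions (antiparallel; Watson-Crick
#'   and G.U count as pairing).  FLAG at >= 2 mismatches; shifts of the TRNA5
#'   segment start by +/-1..3 are tried and any shift achieving <= 1 mismatch
#'   is reported as a correction.
#' @param record a [gene_record()] with TRNA5 and CCA segments.
#' @export
check_acceptor_stem <- function(record) {
  t5 <- segment_lookup(record$segments, "TRNA5")
  cca <- segment_lookup(record$segments, "CCA")
  if (nrow(t5) == 0L || nrow(cca) == 0L) {
    stop("check_acceptor_stem: TRNA5 or CCA segment missing")
  }
  mm <- acceptor_stem_mismatches(record$sequence, t5$start[1], cca$start[1])
  if (is.na(mm)) stop("check_acceptor_stem: stem positions outside sequence")
  if (mm <= 1L) return(qc_outcome("PASS", mismatches = mm))
  shifts <- setdiff(-3:3, 0L)
  rescue <- integer(0)
  for (s in shifts) {
    smm <- acceptor_stem_mismatches(record$sequence, t5$start[1], cca$start[1], s)
    if (!is.na(smm) && smm <= 1L) rescue <- c(rescue, s)
  }
  qc_outcome("FLAG", reason = "ACCEPTOR_STEM", mismatches = mm,
             rescue_shifts = rescue)
}

#' @describeIn qc-checks REJECT iff the CCA segment (the three positions
#'   equivalent to the tRNA CCA tail) is absent or shorter than 3 positions.
#'   The bases need not literally be C,C,A.
#' @export
check_cca_positions <- function(record) {
  cca <- segment_lookup(record$segments, "CCA")
  if (nrow(cca) == 0L || (cca$end[1] - cca$start[1] + 1L) < 3L) {
    return(qc_outcome("REJECT", reason = "MISSING_CCA"))
  }
  qc_outcome("PASS", bases = substr(record$sequence, cca$start[1], cca$end[1]))
}

#' @describeIn qc-checks translates the tag CDS (resume codon through stop
#'   codon inclusive).  FLAG on any internal stop codon or a non-stop terminal
#'   codon.  A declared frameshift annotation on the record
#'   (`record$frameshift = list(position, offset)`: translation reads codons
#'   fully contained in CDS positions 1..position, then resumes at
#'   position + 1 + offset) splits the frame and suppresses the flag when both
#'   sub-frames are clean.  Reports the tag peptide and its length.
#' @param genetic_code named codon table (default the standard code).
#' @export
check_tag_orf <- function(record, genetic_code = Biostrings::GENETIC_CODE) {
  if (grepl("_NO_CDS$", record$form)) {
    return(qc_outcome("PASS", skipped = TRUE))
  }
  cds <- segment_lookup(record$segments, "CDS")
  if (nrow(cds) == 0L) stop("check_tag_orf: CDS segment missing")
  seq <- substr(record$sequence, cds$start[1], cds$end[1])
  fs <- record$frameshift
  pieces <- if (is.null(fs)) list(seq) else {
    p <- fs$position
    list(substr(seq, 1L, p - (p %% 3L)),
         substr(seq, p + 1L + fs$offset, nchar(seq)))
  }
  aa <- unlist(lapply(pieces, translate_frame, code = genetic_code))
  if (length(aa) < 2L) stop("check_tag_orf: CDS shorter than two codons")
  internal_stops <- which(aa[-length(aa)] == "*")
  terminal_ok <- aa[length(aa)] == "*" && nchar(seq) %% 3L == 0L
  if (!is.null(fs)) terminal_ok <- aa[length(aa)] == "*"
  tag <- paste(aa[-length(aa)], collapse = "")
  if (length(internal_stops) || !terminal_ok) {
    return(qc_outcome("FLAG", reason = "TAG_ORF", tag = tag,
                      internal_stop_codons = internal_stops,
                      terminal_stop = terminal_ok))
  }
  qc_outcome("PASS", tag = tag, tag_length = nchar(tag),
             frameshift = !is.null(fs))
}

#' @describeIn qc-checks FLAG iff any of the TRNA5/TRNA3/CDS segments is
#'   shorter than `frac` (default 0.5) of the minimum length of that segment
#'   among related records of the same form; UNEVALUATED without relatives.
#' @param relatives list of gene records of the same form with segment maps.
#' @param frac fraction of the relatives' minimum below which a segment is
#'   called deleted.
#' @export
check_internal_deletion <- function(record, relatives, frac = 0.5) {
  if (length(relatives) == 0L) return(qc_outcome("UNEVALUATED"))
  seg_len <- function(r, nm) {
    s <- segment_lookup(r$segments, nm)
    if (nrow(s) == 0L) return(NA_integer_)
    sum(s$end - s$start + 1L)
  }
  flagged <- list()
  for (nm in c("TRNA5", "TRNA3", "CDS")) {
    own <- seg_len(record, nm)
    if (is.na(own)) next
    rel <- vapply(relatives, seg_len, integer(1), nm = nm)
    rel <- rel[!is.na(rel)]
    if (!length(rel)) next
    if (own < frac * min(rel)) {
      flagged[[nm]] <- c(own = own, relatives_min = min(rel))
    }
  }
  if (length(flagged)) {
    qc_outcome("FLAG", reason = "INTERNAL_DELETION", segments = flagged)
  } else {
    qc_outcome("PASS")
  }
}

#' Run all QC checks on a record
#'
#' Aggregates the per-check outcomes into a QC report and sets the record's
#' status.  An unrescued FLAG from the acceptor-stem check, a TAG_ORF flag on
#' a record without a frameshift/`retain` annotation, and an internal-deletion
#' flag are escalated to rejections, mirroring the published
#' "corrected ... or rejected" handling; any REJECT outcome rejects the
#' record with the matching reason.
#'
#' @param record a [gene_record()] with a segment map.
#' @param relatives optional related records for the internal-deletion check.
#' @param config a [tm_thresholds()].
#' @return list of class `qc_report`: `id`, `checks` (named outcomes),
#'   `reject_reasons`, and the updated `record`.
#' @export
run_qc <- function(record, relatives = list(), config = tm_thresholds()) {
  checks <- list()
  safe <- function(expr) {
    tryCatch(expr, error = function(e) qc_outcome("UNEVALUATED",
                                                  message = conditionMessage(e)))
  }
  checks$ambiguous_blocks <- safe(check_ambiguous_blocks(record$sequence))
  checks$acceptor_stem <- safe(check_acceptor_stem(record))
  checks$cca_positions <- safe(check_cca_positions(record))
  checks$tag_orf <- safe(check_tag_orf(record))
  checks$internal_deletion <- safe(check_internal_deletion(
    record, relatives, frac = config$internal_deletion_frac))

  reasons <- character(0)
  for (nm in names(checks)) {
    ck <- checks[[nm]]
    if (ck$outcome == "REJECT") reasons <- c(reasons, ck$reason)
    if (ck$outcome == "FLAG") {
      escalate <- switch(ck$reason,
        ACCEPTOR_STEM = length(ck$details$rescue_shifts) == 0L,
        TAG_ORF = is.null(record$frameshift) && !isTRUE(record$retain),
        INTERNAL_DELETION = TRUE,
        FALSE)
      if (escalate) reasons <- c(reasons, ck$reason)
    }
  }
  reasons <- unique(reasons)
  if (length(reasons)) {
    record$status <- "REJECTED"
    record$reject_reasons <- reasons
  } else {
    record$status <- "ACCEPTED"
    record$reject_reasons <- character(0)
  }
  structure(list(id = record$id, checks = checks, reject_reasons = reasons,
                 record = record),
            class = "qc_report")
}

#' Serialize QC reports as a tab-separated table
#'
#' @param reports list of `qc_report` objects.
#' @return character vector of lines: id, per-check outcome, reason codes.
#' @export
format_qc_reports <- function(reports) {
  check_names <- c("ambiguous_blocks", "acceptor_stem", "cca_positions",
                   "tag_orf", "internal_deletion")
  header <- paste(c("#id", check_names, "reject_reasons"), collapse = "\t")
  rows <- vapply(reports, function(rp) {
    outs <- vapply(check_names, function(nm) rp$checks[[nm]]$outcome, character(1))
    rr <- if (length(rp$reject_reasons)) paste(rp$reject_reasons, collapse = ",") else "."
    paste(c(rp$id, outs, rr), collapse = "\t")
  }, character(1))
  c(header, rows)
}
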