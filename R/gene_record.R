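#' Gene forms, segment maps and gene records
#'
#' tmRNA genes occur in three main forms: the standard one-piece gene, the
#' circularly permuted gene (whose precursor is cleaved into a two-piece
#' mature RNA, leaving an intervening sequence, IVS, absent from the mature
#' molecule), and the intron form, interrupted in the TpsiC-loop by a
#' self-splicing group I intron.  CDS-less variants of the standard and
#' permuted forms also exist.
#'
#' @name gene-forms
NULL

#' @rdname gene-forms
#' @export
GENE_FORMS <- c("STANDARD", "PERMUTED", "INTRON",
                "STANDARD_NO_CDS", "PERMUTED_NO_CDS")

#' @rdname gene-forms
#' @export
REJECT_REASONS <- c("TRNA_OVERLAP", "CONTIG_END_TRUNCATION", "AMBIGUOUS_BLOCK",
                    "ACCEPTOR_STEM", "MISSING_CCA", "TAG_ORF",
                    "INTERNAL_DELETION", "DUPLICATE", "SIZE_SCORE_CUTOFF")

SEGMENT_NAMES <- c("TRNA5", "CDS", "TRNA3", "CCA", "IVS", "INTRON",
                   "SPACER1", "SPACER2")

# Per-form segment order.  One editable table: the permuted layout places the
# CDS-bearing half upstream of the IVS and the tRNA-like-5' segment downstream
# of it, so that precursor cleavage yields the two-piece mature RNA.  The
# intron form is the standard layout with the TRNA3 segment split by INTRON at
# the TpsiC-loop insertion subsite.
FORM_SEGMENT_ORDER <- list(
  STANDARD        = c("TRNA5", "SPACER1", "CDS", "SPACER2", "TRNA3", "CCA"),
  INTRON          = c("TRNA5", "SPACER1", "CDS", "SPACER2", "TRNA3", "INTRON",
                      "TRNA3", "CCA"),
  PERMUTED        = c("CDS", "SPACER2", "TRNA3", "CCA", "IVS", "TRNA5"),
  STANDARD_NO_CDS = c("TRNA5", "SPACER1", "TRNA3", "CCA"),
  PERMUTED_NO_CDS = c("TRNA3", "CCA", "IVS", "TRNA5")
)

#' Build a segment map
#'
#' A segment map is an ordered set of named, non-overlapping intervals over a
#' gene sequence, 1-based inclusive.  Segment names may repeat (the intron
#' form splits TRNA3 around the INTRON segment).
#'
#' @param segment character vector of segment names.
#' @param start,end integer vectors, 1-based inclusive.
#' @return a `data.frame` of class `segment_map`.
#' @export
segment_map <- function(segment, start, end) {
  stopifnot(length(segment) == length(start), length(start) == length(end))
  segment <- as.character(segment)
  start <- as.integer(start)
  end <- as.integer(end)
  bad <- !segment %in% SEGMENT_NAMES
  if (any(bad)) {
    stop("unknown segment name(s): ", paste(unique(segment[bad]), collapse = ", "))
  }
  if (any(start < 1L) || any(end < start)) {
    stop("segment intervals must satisfy 1 <= start <= end")
  }
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)])) {
    stop("segments must be non-overlapping and in sequence order")
  }
  cca <- segment == "CCA"
  if (any(cca) && any(end[cca] - start[cca] + 1L != 3L)) {
    stop("CCA segment must be exactly 3 positions")
  }
  structure(data.frame(segment = segment, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("segment_map", "data.frame"))
}

segment_lookup <- function(segments, name) {
  segments[segments$segment == name, , drop = FALSE]
}

segment_seq <- function(record, name, part = 1L) {
  seg <- segment_lookup(record$segments, name)
  if (nrow(seg) < part) return(NULL)
  substr(record$sequence, seg$start[part], seg$end[part])
}

#' Construct a gene record
#'
#' The central container of the pipeline: one candidate or accepted tmRNA
#' gene with its sequence, form, segment map, provenance and curation status.
#'
#' @param id unique identifier.
#' @param sequence nucleotide string (IUPAC; U accepted and stored as T).
#' @param form one of [GENE_FORMS].
#' @param segments a [segment_map()] over the sequence, or `NULL`.
#' @param species species label (may be `NA` until naming).
#' @param instance_count number of genomic instances collapsed into this
#'   record (>= 1).
#' @param status one of CANDIDATE, ACCEPTED, REJECTED.
#' @param reject_reasons character vector drawn from [REJECT_REASONS];
#'   non-empty iff status is REJECTED.
#' @param provenance data.frame with columns assembly, contig, start, end
#'   (1-based inclusive), strand; one row per instance.
#' @param ... additional fields (hit metadata, ground-truth annotations from
#'   the generator, frameshift declarations) stored verbatim.
#' @return object of class `gene_record`.
#' @export
gene_record <- function(id, sequence, form, segments = NULL, species = NA_character_,
                        instance_count = 1L, status = "CANDIDATE",
                        reject_reasons = character(0), provenance = NULL, ...) {
  sequence <- norm_seq(sequence)
  if (!nzchar(sequence)) stop("gene_record: sequence must be non-empty")
  if (!form %in% GENE_FORMS) stop("gene_record: unknown form '", form, "'")
  chars <- unique(s2c(sequence))
  if (!all(chars %in% IUPAC_CHARS)) {
    stop("gene_record: non-IUPAC characters in sequence: ",
         paste(setdiff(chars, IUPAC_CHARS), collapse = ""))
  }
  if (!is.null(segments)) {
    if (!inherits(segments, "segment_map")) {
      segments <- segment_map(segments$segment, segments$start, segments$end)
    }
    if (max(segments$end) > nchar(sequence)) {
      stop("gene_record: segment map extends past sequence end")
    }
    if (form == "INTRON" && !"INTRON" %in% segments$segment) {
      stop("gene_record: INTRON form requires an INTRON segment")
    }
    if (grepl("_NO_CDS$", form) && "CDS" %in% segments$segment) {
      stop("gene_record: ", form, " form must not carry a CDS segment")
    }
  }
  if (!status %in% c("CANDIDATE", "ACCEPTED", "REJECTED")) {
    stop("gene_record: bad status '", status, "'")
  }
  if (length(reject_reasons) &&
      !all(reject_reasons %in% REJECT_REASONS)) {
    stop("gene_record: unknown reject reason(s)")
  }
  if ((status == "REJECTED") != (length(reject_reasons) > 0L)) {
    stop("gene_record: status REJECTED iff reject_reasons non-empty")
  }
  if (is.null(provenance)) {
    provenance <- data.frame(assembly = paste0("ASM_", id), contig = "ctg1",
                             start = 1L, end = nchar(sequence), strand = "+",
                             stringsAsFactors = FALSE)
  }
  structure(list(id = id, sequence = sequence, form = form,
                 segments = segments, species = species,
                 instance_count = as.integer(instance_count), status = status,
                 reject_reasons = reject_reasons, provenance = provenance, ...),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record %s> form=%s len=%d status=%s instances=%d\n",
              x$id, x$form, nchar(x$sequence), x$status, x$instance_count))
  if (!is.null(x$segments)) {
    cat(paste(sprintf("  %s:%d-%d", x$segments$segment, x$segments$start,
                      x$segments$end), collapse = " "), "\n")
  }
  if (length(x$reject_reasons)) {
    cat("  reject:", paste(x$reject_reasons, collapse = ","), "\n")
  }
  invisible(x)
}

#' Numeric cutoffs of the curation pipeline
#'
#' All thresholds used across the pipeline, as a single configurable record.
#' Defaults are the published values: strong-hit designation at Aragorn score
#' >103, Infernal >140 bits, Rfind (BLASTN) >90 (all strict); tRNA rejection
#' at >5 bp overlap by a tRNA scoring >42 bits (strict); 250-bp flanks; the
#' conservative intron screen at >=500 bp and >=150 bits (inclusive).
#'
#' @param ... named overrides of the defaults.
#' @return list of class `tm_thresholds`.
#' @export
tm_thresholds <- function(...) {
  t <- list(aragorn_strong = 103, infernal_strong = 140, rfind_strong = 90,
            trna_overlap_bp = 5L, trna_score = 42, flank_bp = 250L,
            intron_min_len = 500L, intron_min_bits = 150,
            max_ambig_block = 1L, max_stem_mismatch = 1L,
            internal_deletion_frac = 0.5)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(t))
  if (length(unknown)) stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  t[names(ov)] <- ov
  if (any(vapply(t, function(v) !is.numeric(v) || v < 0, logical(1)))) {
    stop("thresholds must be non-negative numbers")
  }
  structure(t, class = "tm_thresholds")
}
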