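#' Triage a single candidate record
#'
#' Applies the per-record ingest rules in pipeline order -- identity to an
#' existing database sequence, tRNA overlap, Rfind-only contig-end
#' truncation, the phase-3 intron size/score screen (for phase-3 hits) --
#' and, if the record survives, the full QC check suite.
#'
#' @param record a [gene_record()] carrying hit metadata in `$hit`.
#' @param trnas a `trna_hits` data.frame (or `NULL`).
#' @param references character vector of existing database sequences.
#' @param relatives related records for the internal-deletion check.
#' @param config a [tm_thresholds()].
#' @return the record with status/reject_reasons set; the `qc_report` (when
#'   QC ran) in attribute `qc`.
#' @export
triage_record <- function(record, trnas = NULL, references = character(0),
                          relatives = list(), config = tm_thresholds()) {
  reject <- function(rec, reason) {
    rec$status <- "REJECTED"
    rec$reject_reasons <- unique(c(rec$reject_reasons, reason))
    rec
  }
  if (length(references) && norm_seq(record$sequence) %in% norm_seq(references)) {
    return(reject(record, "DUPLICATE"))
  }
  hit <- record$hit
  if (!is.null(hit)) {
    keep <- filter_trna_overlap(hit, trnas, config)
    if (!keep) return(reject(record, attr(keep, "reason")))
    if (!is.null(hit$mature_span) && !is.null(hit$contig_length) &&
        !is.na(hit$contig_length)) {
      keep <- filter_contig_end_truncation(hit, hit$mature_span)
      if (!keep) return(reject(record, attr(keep, "reason")))
    }
    if (identical(hit$phase, 3L)) {
      keep <- filter_intron_phase3(hit, config)
      if (!keep) return(reject(record, attr(keep, "reason")))
    }
  }
  rep <- run_qc(record, relatives = relatives, config = config)
  structure(rep$record, qc = rep)
}

#' Run the curation funnel over a candidate batch
#'
#' Executes the batch pipeline in published stage order and reports the count
#' surviving each stage: candidate hits, after skipping sequences identical
#' to existing database entries, after rejecting likely tRNAs, after
#' deduplication, after rejecting truncations, and after the automated
#' checks.  Every drop carries a reject reason.
#'
#' @param records list of candidate [gene_record()]s (with `$hit` metadata).
#' @param trnas a `trna_hits` data.frame of tRNA annotations, or `NULL`;
#'   tRNA decoys planted on records (`$planted_trna`) are collected
#'   automatically.
#' @param references character vector of existing database sequences.
#' @param config a [tm_thresholds()].
#' @return list of class `funnel_report`: `funnel` (named stage counts),
#'   `accepted` (surviving records), `rejected` (dropped records with
#'   reasons).
#' @export
curate_funnel <- function(records, trnas = NULL, references = character(0),
                          config = tm_thresholds()) {
  planted <- lapply(records, function(r) r$planted_trna)
  planted <- planted[!vapply(planted, is.null, logical(1))]
  if (length(planted)) {
    trnas <- do.call(rbind, c(list(trnas), planted))
  }
  rejected <- list()
  drop_to <- function(live, test) {
    res <- lapply(live, test)
    dead <- vapply(res, function(r) r$status == "REJECTED", logical(1))
    rejected <<- c(rejected, res[dead])
    res[!dead]
  }
  counts <- c(hits = length(records))
  live <- records
  refs <- norm_seq(references)
  live <- drop_to(live, function(r) {
    if (norm_seq(r$sequence) %in% refs) {
      r$status <- "REJECTED"; r$reject_reasons <- "DUPLICATE"
    }
    r
  })
  counts["after_skip_identical"] <- length(live)
  live <- drop_to(live, function(r) {
    if (!is.null(r$hit)) {
      keep <- filter_trna_overlap(r$hit, trnas, config)
      if (!keep) {
        r$status <- "REJECTED"; r$reject_reasons <- attr(keep, "reason")
      }
    }
    r
  })
  counts["after_trna"] <- length(live)
  live <- deduplicate(live)
  counts["after_dedup"] <- length(live)
  live <- drop_to(live, function(r) {
    h <- r$hit
    if (!is.null(h) && !is.null(h$mature_span) && !is.null(h$contig_length) &&
        !is.na(h$contig_length)) {
      keep <- filter_contig_end_truncation(h, h$mature_span)
      if (!keep) {
        r$status <- "REJECTED"; r$reject_reasons <- attr(keep, "reason")
      }
    }
    r
  })
  counts["after_truncation"] <- length(live)
  forms <- vapply(live, `[[`, character(1), "form")
  qc_done <- lapply(seq_along(live), function(i) {
    relatives <- live[which(forms == forms[i])]
    relatives <- relatives[!vapply(relatives, identical, logical(1), live[[i]])]
    rep <- run_qc(live[[i]], relatives = relatives, config = config)
    rep$record
  })
  dead <- vapply(qc_done, function(r) r$status == "REJECTED", logical(1))
  rejected <- c(rejected, qc_done[dead])
  live <- qc_done[!dead]
  counts["after_checks"] <- length(live)
  structure(list(funnel = counts, accepted = live, rejected = rejected),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Curation funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-22s %d\n", nm, x$funnel[[nm]]))
  invisible(x)
}
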