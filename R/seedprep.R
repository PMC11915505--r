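#' Seed-alignment preparation
#'
#' Utilities mirroring the seed-alignment workflow used when building
#' covariance models: pairwise fractional identity, greedy identity filtering
#' (the role esl-weight plays in the published pipeline), and re-adding
#' flagged rows removed by the filter.
#'
#' @name seedprep
NULL

#' Construct an alignment object
#'
#' @param ids unique row identifiers.
#' @param seqs aligned sequences of equal length ('-' gaps).
#' @param gc named character vector of `#=GC` annotation lines (e.g.
#'   `SS_cons`), preserved verbatim by Stockholm round-trips.
#' @return list of class `tm_alignment`.
#' @export
tm_alignment <- function(ids, seqs, gc = character(0)) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("tm_alignment: duplicate row ids")
  if (length(seqs) && length(unique(nchar(seqs))) > 1L) {
    stop("tm_alignment: rows of unequal length")
  }
  structure(list(ids = as.character(ids), seqs = toupper(as.character(seqs)),
                 gc = gc),
            class = "tm_alignment")
}

#' Fractional identity of two aligned rows
#'
#' Identities divided by the number of columns where both rows are non-gap
#' (0 when there is no such column).  Alternative denominators used by other
#' tools are available: `"min_ungapped"` (shorter ungapped length) and
#' `"alignment"` (full alignment length).
#'
#' @param a,b aligned rows of equal length.
#' @param denominator identity convention; default mutually non-gap columns.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, denominator = c("mutual", "min_ungapped",
                                                    "alignment")) {
  denominator <- match.arg(denominator)
  if (nchar(a) != nchar(b)) stop("pairwise_identity: length mismatch")
  ca <- s2c(toupper(a)); cb <- s2c(toupper(b))
  both <- ca != "-" & cb != "-"
  idn <- sum(ca[both] == cb[both])
  den <- switch(denominator,
                mutual = sum(both),
                min_ungapped = min(sum(ca != "-"), sum(cb != "-")),
                alignment = length(ca))
  if (den == 0L) return(0)
  idn / den
}

#' Greedy identity filtering of an alignment
#'
#' Rows are visited in input order; a row is kept iff its identity to every
#' already-kept row is strictly below `threshold`.  The output preserves input
#' order, no kept pair has identity >= threshold, and the operation is
#' idempotent.
#'
#' @param aln a [tm_alignment()].
#' @param threshold identity fraction in (0, 1].
#' @param denominator passed to [pairwise_identity()].
#' @return the filtered `tm_alignment`; kept indices in attribute `kept`.
#' @export
greedy_identity_filter <- function(aln, threshold,
                                   denominator = "mutual") {
  stopifnot(threshold > 0, threshold <= 1)
  kept <- integer(0)
  for (i in seq_along(aln$ids)) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(aln$seqs[i], aln$seqs[j], denominator) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- tm_alignment(aln$ids[kept], aln$seqs[kept], aln$gc)
  attr(out, "kept") <- kept
  out
}

#' Reinstate flagged rows removed by filtering
#'
#' Returns the filtered rows plus any flagged rows not already present,
#' restored in original row order -- the "add the HEG-bearing sequences back"
#' step of seed preparation.
#'
#' @param original the pre-filter [tm_alignment()].
#' @param filtered the filtered alignment (subset of `original`).
#' @param flagged_ids ids that must be present in the result.
#' @return a `tm_alignment` in original row order.
#' @export
add_back_flagged <- function(original, filtered, flagged_ids) {
  unknown <- setdiff(flagged_ids, original$ids)
  if (length(unknown)) {
    stop("add_back_flagged: unknown id(s): ", paste(unknown, collapse = ", "))
  }
  want <- original$ids %in% union(filtered$ids, flagged_ids)
  tm_alignment(original$ids[want], original$seqs[want], original$gc)
}

#' Read / write Stockholm alignments
#'
#' Handles single-block and interleaved Stockholm; `#=GC` annotation lines
#' (notably `SS_cons`) are preserved untouched, other markup is ignored.
#'
#' @param lines character vector of lines, or use `path`.
#' @param path optional file.
#' @return `read_stockholm`: a [tm_alignment()].
#' @export
read_stockholm <- function(lines, path = NULL) {
  if (!is.null(path)) lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L])) {
    stop("read_stockholm: missing '# STOCKHOLM 1.0' header")
  }
  seqs <- list()
  gc <- list()
  order_seen <- character(0)
  for (ln in lines[-1L]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GC\\s", ln)) {
      m <- regmatches(ln, regexec("^#=GC\\s+(\\S+)\\s+(\\S+)$", ln))[[1]]
      gc[[m[2]]] <- paste0(gc[[m[2]]] %||% "", m[3])
      next
    }
    if (grepl("^#", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1]]
    if (length(m) != 3L) stop("read_stockholm: malformed row: ", ln)
    if (!m[2] %in% order_seen) order_seen <- c(order_seen, m[2])
    seqs[[m[2]]] <- paste0(seqs[[m[2]]] %||% "", m[3])
  }
  tm_alignment(order_seen, unlist(seqs[order_seen], use.names = FALSE),
               gc = unlist(gc) %||% character(0))
}

#' @rdname read_stockholm
#' @param aln a [tm_alignment()].
#' @return `write_stockholm`: the lines (invisibly when written to `path`).
#' @export
write_stockholm <- function(aln, path = NULL) {
  gc_names <- if (length(aln$gc)) paste("#=GC", names(aln$gc)) else character(0)
  width <- max(nchar(c(aln$ids, gc_names, "")), 10L)
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", width, aln$ids, aln$seqs),
             if (length(aln$gc)) sprintf("%-*s %s", width, gc_names, unname(aln$gc)),
             "//")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
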