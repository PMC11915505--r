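#' Transfer segment boundaries from a reference through a match
#'
#' Each reference segment boundary is carried through the offset of the
#' aligned block containing it.  Boundaries falling outside every aligned
#' block are extrapolated linearly from the nearest matched position and
#' flagged as provisional.
#'
#' @param candidate candidate nucleotide string.
#' @param ref a [gene_record()] with a segment map.
#' @param match data.frame of gap-free aligned blocks with columns
#'   `ref_start`, `ref_end`, `cand_start`, `cand_end` (1-based inclusive,
#'   equal lengths per block).
#' @return a [segment_map()] with a logical attribute `provisional` per
#'   segment row.
#' @export
map_segments_by_reference <- function(candidate, ref, match) {
  if (is.null(ref$segments)) {
    stop("map_segments_by_reference: reference lacks a segment map")
  }
  stopifnot(all(c("ref_start", "ref_end", "cand_start", "cand_end") %in%
                  names(match)), nrow(match) >= 1L)
  if (any(match$ref_end - match$ref_start != match$cand_end - match$cand_start)) {
    stop("map_segments_by_reference: aligned blocks must be gap-free (equal lengths)")
  }
  n_cand <- nchar(candidate)
  transfer <- function(b) {
    inside <- which(match$ref_start <= b & b <= match$ref_end)
    if (length(inside)) {
      blk <- inside[1L]
      list(pos = match$cand_start[blk] + (b - match$ref_start[blk]),
           provisional = FALSE)
    } else {
      # extrapolate from the nearest matched reference position
      edges <- c(match$ref_start, match$ref_end)
      cand_edges <- c(match$cand_start, match$cand_end)
      nearest <- which.min(abs(edges - b))
      list(pos = cand_edges[nearest] + (b - edges[nearest]), provisional = TRUE)
    }
  }
  starts <- lapply(ref$segments$start, transfer)
  ends <- lapply(ref$segments$end, transfer)
  pos_s <- pmin(pmax(vapply(starts, `[[`, numeric(1), "pos"), 1L), n_cand)
  pos_e <- pmin(pmax(vapply(ends, `[[`, numeric(1), "pos"), 1L), n_cand)
  sm <- segment_map(ref$segments$segment, pos_s, pos_e)
  attr(sm, "provisional") <- vapply(starts, `[[`, logical(1), "provisional") |
    vapply(ends, `[[`, logical(1), "provisional")
  sm
}

center_pad <- function(seq, width) {
  L <- nchar(seq)
  if (L > width) stop("center_pad: sequence longer than block width")
  if (L == width) return(seq)
  # pads inserted after position ceiling(L/2): the extra residue of an odd
  # segment stays attached to the left of the pad block
  cut <- ceiling(L / 2)
  paste0(substr(seq, 1L, cut), strrep("-", width - L),
         substr(seq, cut + 1L, L))
}

#' Build a center-padded chunk alignment
#'
#' For each named segment (in the shared per-form order), every instance is
#' padded with dashes inserted contiguously at the segment's center up to the
#' length of the longest instance of that segment, so that preliminary
#' segment boundaries line up as columns.  Rows are sorted by taxonomic
#' lineage string (stable) and labels are prefixed with the hit's "S" or "W"
#' designation when known.
#'
#' @param records list of [gene_record()]s sharing one gene form, each with a
#'   complete segment map tiling its sequence.
#' @param taxonomy optional named character vector id -> lineage string used
#'   as the row order key.
#' @return object of class `chunk_alignment`: `labels`, `ids`, `rows` (padded
#'   sequences), `blocks` (segment, width, start, end), `form`, `meta`
#'   (the input records, original order, for lossless unchunking).
#' @export
chunk_align <- function(records, taxonomy = NULL) {
  if (!length(records)) stop("chunk_align: no records")
  forms <- unique(vapply(records, `[[`, character(1), "form"))
  if (length(forms) != 1L) {
    stop("chunk_align: mixed gene forms: ", paste(forms, collapse = ", "))
  }
  seg_names <- lapply(records, function(r) r$segments$segment)
  ref_names <- seg_names[[1L]]
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$segments)) stop("chunk_align: record ", r$id, " lacks a segment map")
    if (!identical(seg_names[[i]], ref_names)) {
      missing <- setdiff(ref_names, seg_names[[i]])
      stop("chunk_align: record ", r$id, " segment layout differs",
           if (length(missing)) paste0(" (missing ", paste(missing, collapse = ","), ")"))
    }
    if (r$segments$start[1L] != 1L || max(r$segments$end) != nchar(r$sequence) ||
        (nrow(r$segments) > 1L &&
         any(r$segments$start[-1L] != r$segments$end[-nrow(r$segments)] + 1L))) {
      stop("chunk_align: record ", r$id, " segments must tile the sequence")
    }
    if (grepl("-", r$sequence, fixed = TRUE)) {
      stop("chunk_align: record ", r$id, " contains the reserved pad character '-'")
    }
  }
  seg_lens <- vapply(records, function(r) r$segments$end - r$segments$start + 1L,
                     integer(length(ref_names)))
  seg_lens <- matrix(seg_lens, nrow = length(ref_names))
  widths <- apply(seg_lens, 1L, max)
  rows <- vapply(records, function(r) {
    paste(vapply(seq_along(ref_names), function(b) {
      center_pad(substr(r$sequence, r$segments$start[b], r$segments$end[b]),
                 widths[b])
    }, character(1)), collapse = "")
  }, character(1))
  ids <- vapply(records, `[[`, character(1), "id")
  lineage <- if (is.null(taxonomy)) rep("", length(ids)) else {
    ifelse(is.na(taxonomy[ids]), "", taxonomy[ids])
  }
  ord <- order(lineage, method = "radix")   # stable for equal lineage keys
  strength <- vapply(records, function(r) {
    s <- r$hit$strength %||% NA_character_
    if (is.null(s) || is.na(s)) "" else paste0(s, " ")
  }, character(1))
  blocks <- data.frame(segment = ref_names, width = widths,
                       start = cumsum(c(1L, widths[-length(widths)])),
                       end = cumsum(widths), stringsAsFactors = FALSE)
  structure(list(labels = paste0(strength[ord], ids[ord]), ids = ids[ord],
                 rows = unname(rows[ord]), blocks = blocks, form = forms,
                 meta = records[ord]),
            class = "chunk_alignment")
}

#' Recover gene records from a chunk alignment
#'
#' Strips pad characters and rebuilds each record's sequence and segment map
#' from the (possibly edited) block boundaries.  Zero-length segments created
#' by an edit are dropped from the recovered map.
#'
#' @param aln a `chunk_alignment` (from [chunk_align()] or
#'   [read_chunk_stockholm()]).
#' @return list of [gene_record()]s in alignment row order.
#' @export
unchunk <- function(aln) {
  widths <- nchar(aln$rows)
  if (length(unique(widths)) > 1L) stop("unchunk: rows of unequal length")
  if (widths[1L] != sum(aln$blocks$width)) {
    stop("unchunk: row length does not match block widths")
  }
  lapply(seq_along(aln$rows), function(i) {
    row <- aln$rows[i]
    bad <- setdiff(unique(s2c(row)), c(IUPAC_CHARS, "-"))
    if (length(bad)) {
      stop("unchunk: row ", aln$ids[i], " contains non-IUPAC character(s): ",
           paste(bad, collapse = ""))
    }
    seg_seqs <- substring(row, aln$blocks$start, aln$blocks$end)
    seg_seqs <- gsub("-", "", seg_seqs, fixed = TRUE)
    lens <- nchar(seg_seqs)
    keep <- lens > 0L
    ends <- cumsum(lens[keep])
    starts <- ends - lens[keep] + 1L
    sm <- segment_map(aln$blocks$segment[keep], starts, ends)
    base <- if (!is.null(aln$meta)) aln$meta[[i]] else {
      gene_record(id = aln$ids[i], sequence = paste(seg_seqs, collapse = ""),
                  form = aln$form)
    }
    base$sequence <- paste(seg_seqs, collapse = "")
    base$segments <- sm
    base
  })
}

# One stable single-character code per segment name, for the #=GC column
# annotation of serialized chunk alignments.
SEGMENT_CODES <- c(TRNA5 = "5", CDS = "C", TRNA3 = "3", CCA = "A", IVS = "I",
                   INTRON = "G", SPACER1 = "s", SPACER2 = "m")

#' Serialize / parse a chunk alignment as Stockholm
#'
#' The per-column segment annotation travels on a `#=GC SEGMENTS` line using
#' the single-character codes of the `#=GF SEGKEY` header, so the alignment
#' can be edited in external alignment editors and read back.
#'
#' @param aln a `chunk_alignment`.
#' @param path optional output file.
#' @return `write_chunk_stockholm`: the lines (invisibly when written).
#' @export
write_chunk_stockholm <- function(aln, path = NULL) {
  names_stk <- gsub(" ", "_", aln$labels, fixed = TRUE)
  width <- max(nchar(names_stk), nchar("#=GC SEGMENTS"))
  segcol <- paste(rep(SEGMENT_CODES[aln$blocks$segment], aln$blocks$width),
                  collapse = "")
  lines <- c("# STOCKHOLM 1.0",
             paste0("#=GF SEGKEY ", paste(sprintf("%s=%s", SEGMENT_CODES[aln$blocks$segment],
                                                  aln$blocks$segment), collapse = " ")),
             paste0("#=GF FORM ", aln$form),
             sprintf("%-*s %s", width, names_stk, aln$rows),
             sprintf("%-*s %s", width, "#=GC SEGMENTS", segcol),
             "//")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_chunk_stockholm
#' @param lines character vector of Stockholm lines, or use `path`.
#' @export
read_chunk_stockholm <- function(lines, path = NULL) {
  if (!is.null(path)) lines <- readLines(path)
  if (!grepl("^# STOCKHOLM", lines[1L])) {
    stop("read_chunk_stockholm: not a Stockholm file")
  }
  keyline <- grep("^#=GF SEGKEY ", lines, value = TRUE)
  formline <- grep("^#=GF FORM ", lines, value = TRUE)
  segline <- grep("^#=GC SEGMENTS ", lines, value = TRUE)
  if (!length(keyline) || !length(segline)) {
    stop("read_chunk_stockholm: missing SEGKEY/SEGMENTS annotation")
  }
  pairs <- strsplit(strsplit(sub("^#=GF SEGKEY ", "", keyline[1L]), " +")[[1]], "=")
  key <- setNames(vapply(pairs, `[`, character(1), 2L),
                  vapply(pairs, `[`, character(1), 1L))
  form <- if (length(formline)) sub("^#=GF FORM ", "", formline[1L]) else "STANDARD"
  segcol <- s2c(sub("^#=GC SEGMENTS +", "", segline[1L]))
  rl <- grep("^[^#/]", lines, value = TRUE)
  rl <- rl[nzchar(trimws(rl))]
  parts <- regmatches(rl, regexec("^(\\S+)\\s+(\\S+)$", rl))
  labels <- vapply(parts, `[`, character(1), 2L)
  rows <- vapply(parts, `[`, character(1), 3L)
  runs <- rle(segcol)
  widths <- runs$lengths
  blocks <- data.frame(segment = unname(key[runs$values]), width = widths,
                       start = cumsum(c(1L, widths[-length(widths)])),
                       end = cumsum(widths), stringsAsFactors = FALSE)
  labels <- sub("^([SW])_", "\\1 ", labels)   # undo the space mangling of the prefix
  ids <- sub("^[SW] ", "", labels)
  structure(list(labels = labels, ids = ids, rows = unname(rows),
                 blocks = blocks, form = form, meta = NULL),
            class = "chunk_alignment")
}
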