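#' Flat-file database format
#'
#' Tab-separated, one row per unique sequence, with a `#`-prefixed header:
#' name, form, sequence, segment boundaries (1-based inclusive,
#' `SEG:start-end` joined by `;`), instance count, provenance
#' (`assembly|contig|start-end|strand` joined by `,`).
#' `read_flatfile(write_flatfile(x))` restores these fields exactly.
#'
#' @param records list of [gene_record()]s.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return `write_flatfile`: the lines, invisibly when written to a file.
#' @export
write_flatfile <- function(records, path = NULL) {
  header <- "#name\tform\tsequence\tsegments\tinstance_count\tprovenance"
  rows <- vapply(records, function(r) {
    segs <- if (is.null(r$segments) || nrow(r$segments) == 0L) "." else {
      paste(sprintf("%s:%d-%d", r$segments$segment, r$segments$start,
                    r$segments$end), collapse = ";")
    }
    prov <- paste(sprintf("%s|%s|%d-%d|%s", r$provenance$assembly,
                          r$provenance$contig, r$provenance$start,
                          r$provenance$end, r$provenance$strand),
                  collapse = ",")
    paste(r$id, r$form, r$sequence, segs, r$instance_count, prov, sep = "\t")
  }, character(1))
  lines <- c(header, rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_flatfile
#' @param lines character vector of flat-file lines, or a file `path`.
#' @return `read_flatfile`: list of gene records.
#' @export
read_flatfile <- function(lines, path = NULL) {
  if (!is.null(path)) lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  records <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    lineno <- keep[i]
    f <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L) {
      stop("flat file line ", lineno, ": expected 6 tab-separated fields, got ",
           length(f))
    }
    if (!f[2] %in% GENE_FORMS) {
      stop("flat file line ", lineno, ": unknown form token '", f[2], "'")
    }
    segments <- NULL
    if (f[4] != ".") {
      parts <- strsplit(f[4], ";", fixed = TRUE)[[1]]
      m <- regmatches(parts, regexec("^([A-Z0-9]+):([0-9]+)-([0-9]+)$", parts))
      if (any(vapply(m, length, integer(1)) != 4L)) {
        stop("flat file line ", lineno, ": malformed segment field '", f[4], "'")
      }
      segments <- segment_map(
        vapply(m, `[`, character(1), 2L),
        as.integer(vapply(m, `[`, character(1), 3L)),
        as.integer(vapply(m, `[`, character(1), 4L)))
    }
    pv <- strsplit(f[6], ",", fixed = TRUE)[[1]]
    pm <- regmatches(pv, regexec("^([^|]+)\\|([^|]+)\\|([0-9]+)-([0-9]+)\\|([+-])$", pv))
    if (any(vapply(pm, length, integer(1)) != 6L)) {
      stop("flat file line ", lineno, ": malformed provenance field")
    }
    provenance <- data.frame(
      assembly = vapply(pm, `[`, character(1), 2L),
      contig = vapply(pm, `[`, character(1), 3L),
      start = as.integer(vapply(pm, `[`, character(1), 4L)),
      end = as.integer(vapply(pm, `[`, character(1), 5L)),
      strand = vapply(pm, `[`, character(1), 6L),
      stringsAsFactors = FALSE)
    records[[i]] <- gene_record(id = f[1], sequence = f[3], form = f[2],
                                segments = segments,
                                instance_count = as.integer(f[5]),
                                provenance = provenance)
  }
  records
}
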