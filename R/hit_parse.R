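#' Parse candidate and tRNA hit tables
#'
#' Supported dialects:
#' \describe{
#'   \item{aragorn}{minimal tab dialect: contig, start, end, strand, score,
#'     form (Aragorn's free-text report is version-dependent; converting it to
#'     this dialect is a documented extension point).}
#'   \item{infernal_tblout}{Infernal `--tblout` (space-aligned, `#` comments);
#'     seq-from > seq-to encodes the minus strand.}
#'   \item{blast_tab6}{BLAST tabular `-outfmt 6`; subject coordinates,
#'     sstart > send encodes the minus strand; bit score from column 12.}
#'   \item{trnascan_tab}{tRNAscan-SE v2 tabular output (begin > end encodes
#'     the minus strand).}
#' }
#' Coordinates are normalized to `start <= end` with the strand recorded.
#'
#' @param lines character vector of file lines, or use `path`.
#' @param dialect one of `aragorn`, `infernal_tblout`, `blast_tab6`,
#'   `trnascan_tab`.
#' @param path optional file to read.
#' @return for candidate dialects a data.frame of class `candidate_hits`
#'   (tool, score, contig, start, end, strand, form_guess, strength,
#'   contig_length); for `trnascan_tab` a data.frame of class `trna_hits`
#'   (contig, start, end, strand, score, isotype).
#' @export
parse_hits <- function(lines, dialect, path = NULL) {
  if (!is.null(path)) lines <- readLines(path)
  dialects <- c("aragorn", "infernal_tblout", "blast_tab6", "trnascan_tab")
  if (length(dialect) != 1L || !dialect %in% dialects) {
    stop("unknown dialect '", paste(dialect, collapse = ","), "'; expected one of ",
         paste(dialects, collapse = ", "))
  }
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  split_row <- function(lineno, n_min) {
    f <- strsplit(trimws(lines[lineno]), "[ \t]+")[[1]]
    if (length(f) < n_min) {
      stop("parse_hits(", dialect, ") line ", lineno, ": expected >= ", n_min,
           " fields, got ", length(f))
    }
    f
  }
  num <- function(x, lineno) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("parse_hits(", dialect, ") line ", lineno,
                       ": non-numeric field '", x[is.na(v)][1], "'")
    v
  }
  rows <- lapply(keep, function(ln) {
    switch(dialect,
      aragorn = {
        f <- split_row(ln, 6L)
        a <- num(f[2], ln); b <- num(f[3], ln)
        if (!f[4] %in% c("+", "-")) {
          stop("parse_hits(aragorn) line ", ln, ": bad strand '", f[4], "'")
        }
        form <- toupper(f[6])
        if (!form %in% c(GENE_FORMS, "UNKNOWN")) {
          stop("parse_hits(aragorn) line ", ln, ": bad form '", f[6], "'")
        }
        data.frame(tool = "ARAGORN", score = num(f[5], ln), contig = f[1],
                   start = min(a, b), end = max(a, b), strand = f[4],
                   form_guess = form, stringsAsFactors = FALSE)
      },
      infernal_tblout = {
        f <- split_row(ln, 18L)
        a <- num(f[8], ln); b <- num(f[9], ln)
        data.frame(tool = "INFERNAL", score = num(f[15], ln), contig = f[1],
                   start = min(a, b), end = max(a, b),
                   strand = if (a <= b) "+" else "-",
                   form_guess = "UNKNOWN", stringsAsFactors = FALSE)
      },
      blast_tab6 = {
        f <- split_row(ln, 12L)
        a <- num(f[9], ln); b <- num(f[10], ln)
        data.frame(tool = "RFIND_BLAST", score = num(f[12], ln), contig = f[2],
                   start = min(a, b), end = max(a, b),
                   strand = if (a <= b) "+" else "-",
                   form_guess = "UNKNOWN", stringsAsFactors = FALSE)
      },
      trnascan_tab = {
        f <- split_row(ln, 9L)
        a <- num(f[3], ln); b <- num(f[4], ln)
        data.frame(contig = f[1], start = min(a, b), end = max(a, b),
                   strand = if (a <= b) "+" else "-", score = num(f[9], ln),
                   isotype = f[5], stringsAsFactors = FALSE)
      })
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    if (dialect == "trnascan_tab") {
      data.frame(contig = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), score = numeric(0),
                 isotype = character(0), stringsAsFactors = FALSE)
    } else {
      data.frame(tool = character(0), score = numeric(0), contig = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0),
                 form_guess = character(0), stringsAsFactors = FALSE)
    }
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (dialect == "trnascan_tab") {
    class(out) <- c("trna_hits", "data.frame")
  } else {
    out$strength <- rep(NA_character_, nrow(out))
    out$contig_length <- rep(NA_integer_, nrow(out))
    class(out) <- c("candidate_hits", "data.frame")
  }
  rownames(out) <- NULL
  out
}

#' Parse a HMMER domtblout table
#'
#' Whitespace-aligned with `#` comment lines; used for homing endonuclease
#' (LAGLIDADG) evidence on intron sequences.
#'
#' @inheritParams parse_hits
#' @return data.frame: target, target_acc, query, query_acc, full_evalue,
#'   i_evalue, score, env_from, env_to.
#' @export
parse_domtblout <- function(lines, path = NULL) {
  if (!is.null(path)) lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(ln) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 22L) {
      stop("parse_domtblout line ", ln, ": expected >= 22 fields, got ", length(f))
    }
    data.frame(target = f[1], target_acc = f[2], query = f[4], query_acc = f[5],
               full_evalue = as.numeric(f[7]), i_evalue = as.numeric(f[13]),
               score = as.numeric(f[14]), env_from = as.integer(f[20]),
               env_to = as.integer(f[21]), stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(target = character(0), target_acc = character(0),
                      query = character(0), query_acc = character(0),
                      full_evalue = numeric(0), i_evalue = numeric(0),
                      score = numeric(0), env_from = integer(0),
                      env_to = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
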