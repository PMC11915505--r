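#' Collapse records with identical sequences
#'
#' Identity is case-insensitive on the DNA alphabet (U read as T).  One record
#' is kept per unique sequence; `instance_count` is summed and provenance rows
#' of all collapsed instances are retained.  Output order is deterministic:
#' lexicographic by sequence (C collation).
#'
#' @param records list of [gene_record()]s, trimmed to gene boundaries.
#' @return list of gene records, one per unique sequence.
#' @export
deduplicate <- function(records) {
  if (length(records) == 0L) return(list())
  keys <- vapply(records, function(r) norm_seq(r$sequence), character(1))
  groups <- split(seq_along(records), keys)
  out <- lapply(groups, function(idx) {
    rep <- records[[idx[1L]]]
    rep$instance_count <- sum(vapply(records[idx], function(r) r$instance_count,
                                     integer(1)))
    rep$provenance <- do.call(rbind, lapply(records[idx], function(r) r$provenance))
    rownames(rep$provenance) <- NULL
    rep
  })
  out[lex_order(names(groups))]
}

#' Name unique sequences by most-frequent species and abundance rank
#'
#' Each unique sequence is named `<species>.<k>`: the species in which the
#' sequence was observed most often, then the 1-based rank of the sequence by
#' descending instance count among sequences assigned to that species.  Ties
#' are broken by lexicographic sequence order, then lexicographic species
#' label (the published scheme is silent on ties).
#'
#' @param records list of deduplicated [gene_record()]s whose provenance rows
#'   identify instances by assembly.
#' @param species_of_instance named character vector mapping assembly ids to
#'   species labels.
#' @return named character vector: record id -> assigned name.
#' @export
assign_names <- function(records, species_of_instance) {
  if (length(records) == 0L) return(setNames(character(0), character(0)))
  info <- lapply(records, function(r) {
    asm <- r$provenance$assembly
    sp <- species_of_instance[asm]
    if (anyNA(sp)) {
      stop("assign_names: no species label for instance(s): ",
           paste(asm[is.na(sp)], collapse = ", "))
    }
    tab <- sort(table(sp), decreasing = TRUE)
    top <- max(tab)
    # tie across species -> lexicographically smallest species label
    species <- sort(names(tab)[tab == top], method = "radix")[1L]
    list(id = r$id, seq = norm_seq(r$sequence), species = species,
         count = r$instance_count)
  })
  df <- data.frame(id = vapply(info, `[[`, character(1), "id"),
                   seq = vapply(info, `[[`, character(1), "seq"),
                   species = vapply(info, `[[`, character(1), "species"),
                   count = vapply(info, `[[`, numeric(1), "count"),
                   stringsAsFactors = FALSE)
  out <- character(nrow(df))
  for (sp in unique(df$species)) {
    idx <- which(df$species == sp)
    ord <- idx[order(-df$count[idx], df$seq[idx], method = "radix")]
    out[ord] <- sprintf("%s.%d", sp, seq_along(ord))
  }
  setNames(out, df$id)
}
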