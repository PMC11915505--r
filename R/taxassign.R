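#' Smallest-clade taxonomic assignment
#'
#' An unlabeled query placed on a reference tree is assigned from the
#' smallest clade containing it and at least one reference (labeled) leaf:
#' walking from the query tip toward the root, the first ancestor whose clade
#' contains a labeled leaf supplies the assignment, namely the longest
#' lineage prefix shared by ALL labeled leaves in that clade, together with
#' its rank.  Unrooted trees are midpoint-rooted first (with a warning).
#'
#' @param tree an `ape::phylo` tree (or a Newick string / file readable by
#'   `ape::read.tree`).
#' @param query_leaf tip label of the query.
#' @param lineages named character vector: labeled leaf -> semicolon-delimited
#'   lineage (GTDB style, `domain;phylum;class;order;family;genus;species`).
#' @return list: `lineage` (character vector of shared ranks, possibly empty),
#'   `lineage_string`, `rank` (name of the deepest shared rank or `NA`),
#'   `clade_size`, `n_reference`.
#' @export
smallest_clade_assign <- function(tree, query_leaf, lineages) {
  tree <- as_phylo(tree)
  if (!query_leaf %in% tree$tip.label) {
    stop("smallest_clade_assign: query '", query_leaf, "' not in tree")
  }
  ref_tips <- intersect(names(lineages), setdiff(tree$tip.label, query_leaf))
  if (!length(ref_tips)) {
    stop("smallest_clade_assign: tree has no labeled reference leaf")
  }
  if (!ape::is.rooted(tree)) {
    warning("smallest_clade_assign: unrooted input tree; midpoint-rooting")
    tree <- phangorn::midpoint(tree)
  }
  qi <- match(query_leaf, tree$tip.label)
  anc <- phangorn::Ancestors(tree, qi, type = "all")  # parent first, root last
  for (node in anc) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
    refs <- intersect(tips, ref_tips)
    if (length(refs)) {
      shared <- lineage_common_prefix(lineages[refs])
      return(list(lineage = shared,
                  lineage_string = paste(shared, collapse = ";"),
                  rank = if (length(shared)) TAX_RANKS[min(length(shared),
                                                           length(TAX_RANKS))]
                         else NA_character_,
                  clade_size = length(tips), n_reference = length(refs)))
    }
  }
  stop("smallest_clade_assign: no ancestor clade with a reference leaf")
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

lineage_common_prefix <- function(lins) {
  parts <- strsplit(unname(lins), ";", fixed = TRUE)
  k <- min(lengths(parts))
  shared <- character(0)
  for (i in seq_len(k)) {
    vals <- unique(vapply(parts, `[`, character(1), i))
    if (length(vals) != 1L) break
    shared <- c(shared, vals)
  }
  shared
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("expected an ape::phylo object, a Newick string, or a file path")
}

#' Serial "__X" labels for taxa new to the reference taxonomy
#'
#' Genomes that could not be assigned at species rank receive the shared
#' lineage prefix with `__X<n>` appended, where `n` is a per-prefix serial
#' starting at 1 (deterministic in insertion order).
#'
#' @param lineage_prefix lineage string of the assignment (rank above
#'   species).
#' @param rank assigned rank; must not be `"species"`.
#' @param counter an environment from [new_x_counter()] holding the serials.
#' @return the label, e.g. `"g__Foo__X1"`.
#' @export
label_unassigned <- function(lineage_prefix, rank, counter) {
  if (identical(rank, "species")) {
    stop("label_unassigned: species-rank assignments are named directly")
  }
  n <- (counter$counts[[lineage_prefix]] %||% 0L) + 1L
  counter$counts[[lineage_prefix]] <- n
  sprintf("%s__X%d", lineage_prefix, n)
}

#' @rdname label_unassigned
#' @export
new_x_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- list()
  e
}
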