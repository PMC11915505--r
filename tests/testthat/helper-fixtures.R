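# Shared fixtures and independent brute-force oracles.

clean_gene <- function(seed, form = "STANDARD", ...) {
  gen_gene(gen_config(seed = seed, form = form, ...))
}

intron_gene <- function(seed, subsite = 7L, len = 300L, rule = "UG") {
  gen_gene(gen_config(seed = seed, form = "INTRON", intron_subsite = subsite,
                      intron_len = len, minus1_rule = rule))
}

# --- independent oracle: greedy identity filter ------------------------------
# Enumerates all subsets; keeps independent (no kept pair >= threshold),
# maximal subsets; returns the one preferring earlier rows. This equals the
# spec's "maximal-independent-set-by-input-order" characterization.
oracle_greedy_filter <- function(seqs, threshold) {
  n <- length(seqs)
  stopifnot(n <= 12L)
  conf <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) conf[i, j] <- pairwise_identity(seqs[i], seqs[j]) >= threshold
  }
  mask <- vapply(seq_len(n), function(i) sum(2^(which(conf[i, ]) - 1L)), numeric(1))
  best <- NULL; best_w <- -1
  for (S in 0:(2^n - 1)) {
    members <- which(bitwAnd(S, 2^(seq_len(n) - 1L)) > 0)
    if (any(vapply(members, function(i) bitwAnd(S, mask[i]) > 0, logical(1)))) next
    outside <- setdiff(seq_len(n), members)
    if (any(vapply(outside, function(i) bitwAnd(S, mask[i]) == 0, logical(1)))) next
    w <- sum(2^(n - members))          # prefer inclusion of earlier rows
    if (w > best_w) { best_w <- w; best <- members }
  }
  sort(best)
}

# --- independent oracle: smallest clade --------------------------------------
# Scans every clade of the tree; among clades containing the query and at
# least one labeled reference leaf, takes the one of minimum size.
oracle_smallest_clade <- function(tree, query, lineages) {
  ntip <- length(tree$tip.label)
  best <- NULL
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    refs <- intersect(tips, setdiff(names(lineages), query))
    if (query %in% tips && length(refs)) {
      if (is.null(best) || length(tips) < best$size) {
        best <- list(size = length(tips), refs = refs)
      }
    }
  }
  parts <- strsplit(unname(lineages[best$refs]), ";", fixed = TRUE)
  k <- min(lengths(parts))
  shared <- character(0)
  for (i in seq_len(k)) {
    v <- unique(vapply(parts, `[`, character(1), i))
    if (length(v) != 1L) break
    shared <- c(shared, v)
  }
  list(size = best$size, lineage = shared)
}

# random rooted tree with a query tip and lineage labels on a random subset
random_labeled_tree <- function(n_tips, lineage_pool) {
  tree <- ape::rtree(n_tips, br = NULL)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  n_lab <- sample(seq_len(n_tips - 1L), 1L)
  labeled <- sample(tree$tip.label, n_lab)
  lineages <- setNames(sample(lineage_pool, n_lab, replace = TRUE), labeled)
  query <- sample(setdiff(tree$tip.label, labeled), 1L)
  list(tree = tree, lineages = lineages, query = query)
}

LINEAGE_POOL <- c(
  "d__B;p__P1;c__C1;o__O1;f__F1;g__G1;s__S1",
  "d__B;p__P1;c__C1;o__O1;f__F1;g__G1;s__S2",
  "d__B;p__P1;c__C1;o__O1;f__F2;g__G2;s__S3",
  "d__B;p__P1;c__C2;o__O2;f__F3;g__G3;s__S4",
  "d__B;p__P2;c__C3;o__O3;f__F4;g__G4;s__S5",
  "d__A;p__P3;c__C4;o__O4;f__F5;g__G5;s__S6")

# --- independent oracle: species.serial naming -------------------------------
# Plain nested-loop rank computation over (sequence, per-species counts).
oracle_names <- function(records, species_of_instance) {
  seqs <- vapply(records, function(r) toupper(r$sequence), character(1))
  ids <- vapply(records, `[[`, character(1), "id")
  major <- character(length(records))
  counts <- integer(length(records))
  for (i in seq_along(records)) {
    sp <- unname(species_of_instance[records[[i]]$provenance$assembly])
    tab <- table(sp)
    cand <- names(tab)[tab == max(tab)]
    major[i] <- sort(cand, method = "radix")[1L]
    counts[i] <- records[[i]]$instance_count
  }
  out <- setNames(character(length(records)), ids)
  for (sp in unique(major)) {
    idx <- which(major == sp)
    ranked <- idx[order(-counts[idx], seqs[idx], method = "radix")]
    for (r in seq_along(ranked)) out[ids[ranked[r]]] <- sprintf("%s.%d", sp, r)
  }
  out
}

# random gapped alignment rows with tunable similarity
random_alignment_rows <- function(n, width = 24L, mut = 0.25) {
  base <- s2c(random_dna(width))
  vapply(seq_len(n), function(i) {
    row <- base
    flip <- runif(width) < mut
    row[flip] <- sample(c("A", "C", "G", "T", "-"), sum(flip), replace = TRUE)
    c2s(row)
  }, character(1))
}
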