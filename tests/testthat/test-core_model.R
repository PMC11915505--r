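test_that("deduplicate collapses identical sequences and conserves counts", {
  a <- gene_record("a", "ACGTACGT", "STANDARD")
  b <- gene_record("b", "acgtacgt", "STANDARD")   # case-insensitive
  c <- gene_record("c", "ACGUACGU", "STANDARD")   # U == T
  d <- gene_record("d", "ACGTACGA", "STANDARD")   # one base off
  out <- deduplicate(list(a, b, c, d))
  expect_length(out, 2L)
  counts <- vapply(out, `[[`, integer(1), "instance_count")
  expect_identical(sum(counts), 4L)
  merged <- out[[which(counts == 3L)]]
  expect_identical(nrow(merged$provenance), 3L)
  expect_identical(deduplicate(list()), list())
})

test_that("deduplicate output order is deterministic under input reordering", {
  recs <- lapply(1:6, function(s) clean_gene(400 + s))
  o1 <- deduplicate(recs)
  o2 <- deduplicate(rev(recs))
  expect_identical(vapply(o1, `[[`, character(1), "sequence"),
                   vapply(o2, `[[`, character(1), "sequence"))
  # property: total instance count conserved for random batches with dups
  batch <- c(recs, recs[c(2, 2, 5)])
  expect_identical(
    sum(vapply(deduplicate(batch), `[[`, integer(1), "instance_count")),
    length(batch))
})

test_that("assign_names follows most-frequent species and abundance rank", {
  mk <- function(id, seq, asms) {
    gene_record(id, seq, "STANDARD",
                provenance = data.frame(assembly = asms, contig = "c",
                                        start = 1L, end = nchar(seq),
                                        strand = "+"),
                instance_count = length(asms))
  }
  sp <- c(a1 = "SpA", a2 = "SpA", a3 = "SpA", a4 = "SpA", a5 = "SpA",
          a6 = "SpA", a7 = "SpA", b1 = "SpB")
  # SpA has two unique sequences with counts 5 and 2
  r1 <- mk("r1", "AAAA", c("a1", "a2", "a3", "a4", "a5"))
  r2 <- mk("r2", "CCCC", c("a6", "a7"))
  nm <- assign_names(list(r1, r2), sp)
  expect_identical(unname(nm[c("r1", "r2")]), c("SpA.1", "SpA.2"))
  # seen 3x in SpA, 1x in SpB -> named under SpA
  r3 <- mk("r3", "GGGG", c("a1", "a2", "a3", "b1"))
  expect_identical(unname(assign_names(list(r3), sp)["r3"]), "SpA.1")
  # single record, single species
  expect_identical(unname(assign_names(list(mk("r4", "TTTT", "b1")), sp)),
                   "SpB.1")
  # missing species label errors with the instance named
  expect_error(assign_names(list(mk("r5", "TTTT", "zz")), sp), "zz")
})

test_that("assign_names matches the brute-force oracle and is stable", {
  set.seed(61)
  for (trial in 1:50) {
    n <- sample(2:7, 1)
    species_pool <- paste0("Sp", LETTERS[1:sample(2:4, 1)])
    asm_sp <- setNames(sample(species_pool, 30, replace = TRUE),
                       sprintf("asm%02d", 1:30))
    recs <- lapply(seq_len(n), function(i) {
      k <- sample(1:6, 1)
      asms <- sample(names(asm_sp), k)
      gene_record(sprintf("r%d", i), random_dna(12),
                  "STANDARD",
                  provenance = data.frame(assembly = asms, contig = "c",
                                          start = 1L, end = 12L, strand = "+"),
                  instance_count = k)
    })
    got <- assign_names(recs, asm_sp)
    want <- oracle_names(recs, asm_sp)
    expect_identical(got[names(want)], want)
    expect_false(anyDuplicated(got) > 0)
    # stable under record reordering
    perm <- sample(n)
    got2 <- assign_names(recs[perm], asm_sp)
    expect_identical(got2[names(want)], want)
  }
})

test_that("flat-file round-trip is the identity on generator output fields", {
  recs <- c(lapply(1:3, clean_gene),
            list(clean_gene(11, form = "PERMUTED"), intron_gene(12)))
  recs <- lapply(recs, function(r) {
    r[c("id", "sequence", "form", "segments", "instance_count", "provenance")]
  })
  recs <- lapply(recs, function(f) do.call(gene_record, f))
  lines <- write_flatfile(recs)
  back <- read_flatfile(lines)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$sequence, recs[[i]]$sequence)
    expect_identical(back[[i]]$form, recs[[i]]$form)
    expect_identical(as.data.frame(back[[i]]$segments),
                     as.data.frame(recs[[i]]$segments))
    expect_identical(back[[i]]$provenance, recs[[i]]$provenance)
    expect_identical(back[[i]]$instance_count, recs[[i]]$instance_count)
  }
  # INTRON segment boundaries recovered exactly
  gi <- back[[5]]
  expect_identical(segment_lookup(gi$segments, "INTRON")$start,
                   recs[[5]]$truth$intron[1] %||% segment_lookup(recs[[5]]$segments, "INTRON")$start)
})

test_that("flat-file read errors carry the offending line number", {
  recs <- list(clean_gene(1), clean_gene(2))
  lines <- write_flatfile(recs)
  bad <- lines
  bad[3] <- sub("STANDARD", "BOGUS", bad[3])
  expect_error(read_flatfile(bad), "line 3.*BOGUS")
  bad2 <- lines
  bad2[2] <- paste(bad2[2], "extra", sep = "\t")
  expect_error(read_flatfile(bad2), "line 2")
})

test_that("curate_funnel reports the published stage order on a planted batch", {
  clean <- lapply(1:10, clean_gene)
  decoys <- lapply(11:13, function(s) plant_defect(clean_gene(s), "TRNA_OVERLAP",
                                                   seed = s))
  trunc <- lapply(14:15, function(s) plant_defect(clean_gene(s),
                                                  "CONTIG_END_TRUNCATION"))
  out <- curate_funnel(c(clean, decoys, trunc))
  expect_identical(unname(out$funnel),
                   c(15L, 15L, 12L, 12L, 10L, 10L))
  expect_identical(names(out$funnel),
                   c("hits", "after_skip_identical", "after_trna",
                     "after_dedup", "after_truncation", "after_checks"))
  expect_true(all(diff(unname(out$funnel)) <= 0))   # non-increasing
  reasons <- unlist(lapply(out$rejected, `[[`, "reject_reasons"))
  expect_identical(sort(unique(reasons)),
                   c("CONTIG_END_TRUNCATION", "TRNA_OVERLAP"))
})

test_that("curate_funnel drops everything already in the database, and empty in -> zero out", {
  recs <- lapply(1:4, clean_gene)
  refs <- vapply(recs, `[[`, character(1), "sequence")
  out <- curate_funnel(recs, references = refs)
  expect_identical(unname(out$funnel), c(4L, 0L, 0L, 0L, 0L, 0L))
  expect_true(all(vapply(out$rejected, function(r)
    identical(r$reject_reasons, "DUPLICATE"), logical(1))))
  empty <- curate_funnel(list())
  expect_identical(unname(empty$funnel), rep(0L, 6L) + c(0L, 0L, 0L, 0L, 0L, 0L))
})

test_that("gene_record validates its invariants", {
  expect_error(gene_record("x", "", "STANDARD"), "non-empty")
  expect_error(gene_record("x", "ACGT", "WEIRD"), "unknown form")
  expect_error(gene_record("x", "AC-GT", "STANDARD"), "non-IUPAC")
  expect_error(gene_record("x", "ACGT", "STANDARD", status = "REJECTED"),
               "reject_reasons")
  expect_error(segment_map("CCA", 1, 4), "exactly 3")
  expect_error(segment_map(c("TRNA5", "CDS"), c(1, 5), c(6, 9)),
               "non-overlapping")
  expect_error(tm_thresholds(bogus = 1), "unknown threshold")
  expect_identical(tm_thresholds()$aragorn_strong, 103)
  expect_identical(tm_thresholds()$flank_bp, 250L)
})
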