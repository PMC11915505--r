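test_that("parse_hits normalizes coordinates and strand per dialect", {
  tbl <- c("#target name accession query ...",
           "ctgA - tmRNA RF00023 cm 1 350 300 120 - no 1 0.50 0.0 151.2 1e-30 ! -")
  h <- parse_hits(tbl, "infernal_tblout")
  expect_identical(h$start, 120L)
  expect_identical(h$end, 300L)
  expect_identical(h$strand, "-")
  expect_identical(h$score, 151.2)
  expect_identical(h$tool, "INFERNAL")

  b6 <- "db.1\tctgB\t98.5\t360\t4\t0\t1\t360\t5000\t5359\t2e-100\t512"
  hb <- parse_hits(b6, "blast_tab6")
  expect_identical(hb$score, 512)       # bit score from column 12
  expect_identical(hb$contig, "ctgB")
  expect_identical(hb$strand, "+")

  ts <- "ctgC\t1\t900\t829\tAla\tAGC\t0\t0\t55.3"
  ht <- parse_hits(ts, "trnascan_tab")
  expect_s3_class(ht, "trna_hits")
  expect_identical(ht$start, 829L)
  expect_identical(ht$strand, "-")
  expect_identical(ht$isotype, "Ala")

  expect_identical(nrow(parse_hits(character(0), "aragorn")), 0L)
  expect_identical(nrow(parse_hits("# only a comment", "blast_tab6")), 0L)
  expect_error(parse_hits("x", "nonsense"), "unknown dialect")
  expect_error(parse_hits("ctg\tone\ttwo", "blast_tab6"), "line 1")
})

test_that("designate_strength applies the published strict cutoffs", {
  cases <- data.frame(
    tool = c("ARAGORN", "ARAGORN", "ARAGORN", "INFERNAL", "INFERNAL",
             "RFIND_BLAST", "RFIND_BLAST", "RFIND_BLAST"),
    score = c(104, 103, 103.1, 140.0, 140.1, 90.5, 90, 89),
    want = c("S", "W", "S", "W", "S", "S", "W", "W"),
    stringsAsFactors = FALSE)
  got <- designate_strength(cases)
  expect_identical(got$strength, cases$want)
  # monotone in score for fixed tool
  for (tool in c("ARAGORN", "INFERNAL", "RFIND_BLAST")) {
    sc <- sort(runif(20, 50, 200))
    st <- designate_strength(data.frame(tool = tool, score = sc))$strength
    expect_true(all(diff(st == "S") >= 0))
  }
})

test_that("extract_region flanks, clips, reverse-complements and back-maps", {
  set.seed(5)
  ctg <- random_dna(10000)
  genome <- c(big = ctg)
  hit <- list(contig = "big", start = 1000L, end = 1500L, strand = "+")
  reg <- extract_region(hit, genome, flank_bp = 250L)
  expect_identical(c(reg$region_start, reg$region_end), c(750L, 1750L))
  expect_identical(reg$sequence, substr(ctg, 750, 1750))
  # clipped at contig start
  reg2 <- extract_region(list(contig = "big", start = 100L, end = 400L,
                              strand = "+"), genome, flank_bp = 250L)
  expect_identical(reg2$region_start, 1L)
  # minus strand: reverse complement of the plus-strand slice
  reg3 <- extract_region(list(contig = "big", start = 1000L, end = 1500L,
                              strand = "-"), genome, flank_bp = 0L)
  expect_identical(reg3$sequence, revcomp(substr(ctg, 1000, 1500)))
  # back-mapping is the identity on the hit interval
  expect_identical(reg$to_contig(1L), 750L)
  expect_identical(reg$to_contig(251L), 1000L)
  expect_identical(reg3$to_contig(1L), 1500L)
  expect_identical(reg3$to_contig(501L), 1000L)
  expect_error(extract_region(list(contig = "nope", start = 1, end = 2,
                                   strand = "+"), genome), "absent")
})

test_that("filter_trna_overlap applies >5 bp / >42 bit with the permuted+strong exception", {
  t <- tm_thresholds()
  hit <- list(contig = "c", start = 100L, end = 400L, form_guess = "STANDARD",
              strength = "W")
  trna <- function(s, e, score) {
    data.frame(contig = "c", start = s, end = e, strand = "+", score = score,
               isotype = "Ala")
  }
  expect_false(as.logical(filter_trna_overlap(hit, trna(95, 105, 43), t)))    # 6 bp, 43 bits
  expect_true(filter_trna_overlap(hit, trna(96, 104, 43), t))     # 5 bp exactly
  expect_true(filter_trna_overlap(hit, trna(95, 105, 42), t))     # 42 bits exactly
  expect_true(filter_trna_overlap(hit, trna(96, 195, 100), t) == FALSE)  # 100 bp
  perm <- modifyList(hit, list(form_guess = "PERMUTED", strength = "S"))
  expect_true(filter_trna_overlap(perm, trna(100, 159, 80), t))   # exception
  permW <- modifyList(perm, list(strength = "W"))
  expect_false(as.logical(filter_trna_overlap(permW, trna(100, 159, 80), t)))
  # invariant under reordering of the tRNA list
  set.seed(9)
  trnas <- do.call(rbind, lapply(1:8, function(i)
    trna(sample(50:450, 1), sample(460:600, 1), runif(1, 30, 60))))
  expect_identical(as.logical(filter_trna_overlap(hit, trnas, t)),
                   as.logical(filter_trna_overlap(hit, trnas[sample(8), ], t)))
})

test_that("filter_contig_end_truncation fires only for Rfind-only truncated hits", {
  h <- list(tools = "RFIND_BLAST", contig_length = 2000L)
  expect_false(as.logical(filter_contig_end_truncation(h, c(1800L, 2030L))))
  expect_true(filter_contig_end_truncation(
    modifyList(h, list(tools = c("ARAGORN", "RFIND_BLAST"))), c(1800L, 2030L)))
  expect_true(filter_contig_end_truncation(h, c(500L, 900L)))
  expect_false(as.logical(filter_contig_end_truncation(h, c(0L, 900L))))  # off 5' end too
})

test_that("filter_intron_phase3 applies inclusive 500 bp / 150 bit cutoffs", {
  mk <- function(len, bits) list(start = 1L, end = len, score = bits)
  expect_true(filter_intron_phase3(mk(545L, 225.3)))   # smallest known intron form
  expect_true(filter_intron_phase3(mk(500L, 150)))     # boundary inclusive
  expect_false(as.logical(filter_intron_phase3(mk(499L, 300))))
  expect_false(as.logical(filter_intron_phase3(mk(600L, 149))))
  expect_identical(attr(filter_intron_phase3(mk(499L, 300)), "reason"),
                   "SIZE_SCORE_CUTOFF")
})

test_that("phase2_candidates selects non-nested failing taxa and one hit per genome", {
  stats <- data.frame(
    taxon = c("famA", "genA1", "famB", "famC"),
    genomes_total = c(40L, 25L, 25L, 30L),
    genomes_with_tmrna = c(10L, 2L, 13L, 5L))
  nesting <- c(genA1 = "famA", famA = NA, famB = NA, famC = NA)
  hits <- data.frame(
    genome = c("g1", "g1", "g2", "g3", "g4"),
    taxon = c("famA", "famA", "genA1", "famB", "famC"),
    score = c(50, 80, 60, 70, 65))
  out <- phase2_candidates(stats, nesting, hits)
  # famA: 30 failed, 75% -> selected; famB: 12 failed 48% -> no;
  # famC: 25 failed 83% -> yes; genA1 selected but nested in famA -> dropped
  expect_setequal(out$selected_taxa, c("famA", "famC"))
  expect_identical(nrow(out$candidates), 2L)          # at most one per genome
  expect_identical(out$candidates$score[out$candidates$genome == "g1"], 80)
  # alternative interpretation: >= 20 genomes total
  out2 <- phase2_candidates(stats, nesting, hits, interpretation = "total")
  expect_true("famC" %in% out2$selected_taxa)
  # cycles error
  expect_error(phase2_candidates(stats, c(famA = "genA1", genA1 = "famA"),
                                 hits), "cyclic")
})

test_that("cluster_hits merges same-strand overlapping hits with tool union", {
  hits <- data.frame(
    tool = c("ARAGORN", "RFIND_BLAST", "INFERNAL"),
    score = c(110, 95, 160),
    contig = c("c1", "c1", "c1"),
    start = c(100L, 350L, 2000L),
    end = c(400L, 700L, 2300L),
    strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  loci <- cluster_hits(hits)
  expect_identical(nrow(loci), 2L)
  expect_setequal(loci$tools[[1]], c("ARAGORN", "RFIND_BLAST"))
  expect_identical(loci$end[1], 700L)
})
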