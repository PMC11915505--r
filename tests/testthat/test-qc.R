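test_that("check_ambiguous_blocks rejects only runs of >= 2 ambiguous bases", {
  r <- check_ambiguous_blocks("ACGNNACG")
  expect_identical(r$outcome, "REJECT")
  expect_identical(r$reason, "AMBIGUOUS_BLOCK")
  expect_identical(r$details$spans[1, ], c(start = 4L, end = 5L))
  expect_identical(check_ambiguous_blocks("ACGNACGNACG")$outcome, "PASS")
  expect_identical(check_ambiguous_blocks("ACGT")$outcome, "PASS")
  expect_identical(check_ambiguous_blocks("ACGRYSACG")$outcome, "REJECT")
  expect_error(check_ambiguous_blocks(""), "empty")
})

test_that("check_acceptor_stem counts pairs (incl. G.U), flags >= 2 mismatches, tries shifts", {
  mk_stem_gene <- function(stem5, stem3) {
    # minimal STANDARD-shaped record whose acceptor stem we control
    seq <- paste0(stem5, strrep("A", 18), "CAGT", "GCAGCAGCATAA",
                  strrep("A", 10), stem3, "CCA")
    n <- nchar(seq)
    gene_record("s", seq, "STANDARD",
                segments = segment_map(
                  c("TRNA5", "SPACER1", "CDS", "SPACER2", "TRNA3", "CCA"),
                  c(1, 26, 30, 42, 52, n - 2),
                  c(25, 29, 41, 51, n - 3 + 0, n)))
  }
  # perfect reverse complement: GGGGCTA / TAGCCCC
  ck <- check_acceptor_stem(mk_stem_gene("GGGGCTA", "TAGCCCC"))
  expect_identical(ck$outcome, "PASS")
  expect_identical(ck$details$mismatches, 0L)
  # one G.U wobble (G paired with T) still counts as pairing
  ck2 <- check_acceptor_stem(mk_stem_gene("GGGGCTA", "TAGCCCT"))
  expect_identical(ck2$details$mismatches, 0L)
  # two mismatches flag
  ck3 <- check_acceptor_stem(mk_stem_gene("GGGGCTA", "TAGCCAA"))
  expect_identical(ck3$outcome, "FLAG")
  expect_gte(ck3$details$mismatches, 2L)
  expect_error(check_acceptor_stem(gene_record("x", "ACGT", "STANDARD")),
               "missing")
})

test_that("check_acceptor_stem reports rescuing shifts and ignores flanks", {
  g <- clean_gene(71)
  # shift the annotated TRNA5 start 2 right: stem breaks but shift -2 rescues
  seg <- as.data.frame(g$segments)
  g2 <- g
  g2$segments <- segment_map(seg$segment, pmax(seg$start, c(3L, seg$start[-1])),
                             seg$end)
  ck <- check_acceptor_stem(g2)
  if (ck$outcome == "FLAG") expect_true(-2L %in% ck$details$rescue_shifts)
  # invariance under appended flanking sequence beyond the gene:
  # the check only reads segment-addressed positions
  ck0 <- check_acceptor_stem(g)
  g3 <- g
  g3$sequence <- paste0(g$sequence, strrep("G", 40))
  g3$segments <- g$segments
  ck1 <- check_acceptor_stem(g3)
  expect_identical(ck0$details$mismatches, ck1$details$mismatches)
})

test_that("check_cca_positions requires three CCA-equivalent positions, not literal CCA", {
  g <- clean_gene(72)
  expect_identical(check_cca_positions(g)$outcome, "PASS")
  # bases need not be C,C,A
  g2 <- g
  n <- nchar(g2$sequence)
  substr(g2$sequence, n - 2, n) <- "TCA"
  expect_identical(check_cca_positions(g2)$outcome, "PASS")
  g3 <- plant_defect(g, "MISSING_CCA")
  ck <- check_cca_positions(g3)
  expect_identical(ck$outcome, "REJECT")
  expect_identical(ck$reason, "MISSING_CCA")
})

test_that("check_tag_orf validates resume-to-stop frames, tags and frameshifts", {
  g <- clean_gene(73)                       # 10-aa tag
  ck <- check_tag_orf(g)
  expect_identical(ck$outcome, "PASS")
  expect_identical(ck$details$tag_length, 10L)
  expect_identical(substr(ck$details$tag, 1, 1), "A")   # alanine resume
  # 2-aa Ala-Ala tag
  g2 <- clean_gene(74, tag_len_aa = 2L)
  ck2 <- check_tag_orf(g2)
  expect_identical(ck2$details$tag, "AA")
  # internal stop flags
  g3 <- plant_defect(g, "TAG_ORF")
  ck3 <- check_tag_orf(g3)
  expect_identical(ck3$outcome, "FLAG")
  expect_identical(ck3$reason, "TAG_ORF")
  expect_length(ck3$details$internal_stop_codons, 1L)
  # a declared frameshift splitting two clean sub-frames suppresses the flag
  cds <- segment_lookup(g$segments, "CDS")
  fsg <- g
  # delete one base inside codon 5 of the CDS (frameshift), then declare it
  at <- cds$start + 13L
  fsg$sequence <- paste0(substr(g$sequence, 1, at - 1),
                         substr(g$sequence, at + 1, nchar(g$sequence)))
  fsg$segments <- segment_map(g$segments$segment,
                              g$segments$start - (g$segments$start > at),
                              g$segments$end - (g$segments$end >= at))
  expect_identical(check_tag_orf(fsg)$outcome, "FLAG")
  fsg$frameshift <- list(position = 12L, offset = 2L)
  ck4 <- check_tag_orf(fsg)
  expect_identical(ck4$outcome, "PASS")
  expect_true(ck4$details$frameshift)
  # *_NO_CDS skips
  expect_true(isTRUE(check_tag_orf(clean_gene(75, form = "STANDARD_NO_CDS"))$details$skipped))
})

test_that("check_internal_deletion compares segments against relatives", {
  g <- clean_gene(76)
  rel <- lapply(77:79, clean_gene)
  expect_identical(check_internal_deletion(g, rel)$outcome, "PASS")
  bad <- plant_defect(g, "INTERNAL_DELETION")
  ck <- check_internal_deletion(bad, rel)
  expect_identical(ck$outcome, "FLAG")
  expect_identical(ck$reason, "INTERNAL_DELETION")
  expect_true("CDS" %in% names(ck$details$segments))
  expect_identical(check_internal_deletion(g, list())$outcome, "UNEVALUATED")
})

test_that("run_qc aggregates outcomes, sets status, and serializes", {
  g <- clean_gene(81)
  rep <- run_qc(g)
  expect_s3_class(rep, "qc_report")
  expect_identical(rep$record$status, "ACCEPTED")
  # two planted defects give two reasons
  bad <- plant_defect(plant_defect(g, "AMBIGUOUS_BLOCK"), "ACCEPTOR_STEM")
  rep2 <- run_qc(bad)
  expect_identical(rep2$record$status, "REJECTED")
  expect_setequal(rep2$reject_reasons, c("AMBIGUOUS_BLOCK", "ACCEPTOR_STEM"))
  # *_NO_CDS forms: ORF check skipped, the others run
  nc <- run_qc(clean_gene(82, form = "PERMUTED_NO_CDS"))
  expect_identical(nc$record$status, "ACCEPTED")
  expect_true(isTRUE(nc$checks$tag_orf$details$skipped))
  # a TAG_ORF flag with a retain annotation is not escalated
  noted <- plant_defect(g, "TAG_ORF")
  noted$retain <- TRUE
  expect_identical(run_qc(noted)$record$status, "ACCEPTED")
  # serialization
  lines <- format_qc_reports(list(rep, rep2))
  expect_length(lines, 3L)
  expect_match(lines[3], "AMBIGUOUS_BLOCK")
})
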