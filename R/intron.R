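#' TpsiC stem/loop model
#'
#' The post-splicing (and pre-modification) T-stem/loop of the tRNA-like
#' domain: a 5-bp stem, an 8-base loop, and the complementary 3' stem side.
#' Group I introns interrupt the loop at one of its 8 internucleotide
#' positions (subsite k = between loop base k and the following base; subsite
#' 8 lies between loop base 8 and the first 3' stem base).
#'
#' @param stem5 5' stem-side sequence (default 5 bp).
#' @param loop loop sequence; must be exactly 8 bases for subsite numbering.
#' @param stem3 3' stem-side sequence; must pair `stem5` antiparallel with at
#'   most one mismatch.
#' @return list of class `tloop_model`.
#' @export
tloop_model <- function(stem5 = "GGGGG", loop = "TTTCGATT", stem3 = "CCCCC") {
  stem5 <- norm_seq(stem5); loop <- norm_seq(loop); stem3 <- norm_seq(stem3)
  if (nchar(stem5) != nchar(stem3)) stop("tloop_model: stem sides differ in length")
  if (nchar(loop) != 8L) {
    stop("tloop_model: loop must be exactly 8 bases for subsite numbering 1-8, got ",
         nchar(loop))
  }
  mm <- sum(!pairs_ok(s2c(stem5), rev(s2c(stem3))))
  if (mm > 1L) stop("tloop_model: stem sides do not pair (", mm, " mismatches)")
  structure(list(stem5 = stem5, loop = loop, stem3 = stem3),
            class = "tloop_model")
}

# Positions p where the window seq[p..p+k-1] matches `motif` with mismatch
# counts; returns data.frame(pos, mm).  Vectorized over the whole sequence.
motif_scan <- function(chars, motif, max_mm) {
  k <- length(motif)
  n <- length(chars)
  if (n < k) return(data.frame(pos = integer(0), mm = integer(0)))
  m <- n - k + 1L
  mm <- integer(m)
  for (j in seq_len(k)) {
    mm <- mm + (chars[j:(m + j - 1L)] != motif[j])
  }
  keep <- which(mm <= max_mm)
  data.frame(pos = keep, mm = mm[keep])
}

#' Determine group I intron boundaries within the TpsiC-loop
#'
#' Applies the classical group I intron boundary rules: the exon base
#' immediately 5' of the intron (-1 position) is a U that can pair an internal
#' G within the first `p1_window` intron bases (a proxy for the P1 stem), the
#' intron's 3'-terminal (omega) base is a G, and excising the intron must
#' reconstitute a T-stem/loop matching `tloop`: at most one stem mismatch,
#' exact loop length, and loop bases identical to the model except at the -1
#' position itself (whose base the boundary rule already fixes as U or C).
#' A minority C(-1)/A(P1) rule is enabled with
#' `allow_CA`.  Among candidates the reconstitution match (identical positions
#' over the 18-nt stem/loop window) is maximized; ties break to the smallest
#' intron start, then smallest end.
#'
#' @param gene nucleotide string suspected of the intron form.
#' @param tloop a [tloop_model()].
#' @param allow_CA also admit the C(-1)/A(P1) exception rule.
#' @param min_intron_len smallest intron considered (default 20 bp).
#' @param p1_window how deep into the intron the -1 base may find its pairing
#'   partner (default 15 bases).
#' @param omega_override accept a non-G omega base (off by default; no such
#'   exception is known).
#' @return an `intron_call` (list: intron_start, intron_end 1-based inclusive,
#'   minus1_base, omega_base, p1_partner, subsite, match_score, spliced_exon)
#'   or `NULL` when no candidate satisfies the rules.
#' @export
find_intron_boundaries <- function(gene, tloop = tloop_model(), allow_CA = FALSE,
                                   min_intron_len = 20L, p1_window = 15L,
                                   omega_override = FALSE) {
  gene <- norm_seq(gene)
  g <- s2c(gene)
  n <- length(g)
  m5 <- s2c(tloop$stem5); m3 <- s2c(tloop$stem3); ml <- s2c(tloop$loop)
  s5 <- length(m5); s3 <- length(m3); L <- length(ml)
  a5 <- motif_scan(g, m5, 1L)
  a3 <- motif_scan(g, m3, 1L)
  if (nrow(a5) == 0L || nrow(a3) == 0L) return(NULL)
  minus1_ok <- if (allow_CA) c("T", "C") else "T"
  best <- NULL
  for (ii in seq_len(nrow(a5))) {
    p5 <- a5$pos[ii]; e5 <- p5 + s5 - 1L
    for (k in 1:L) {
      i <- e5 + k                      # -1 position (last left-exon base)
      if (i > n || !g[i] %in% minus1_ok) next
      # loop reconstitution is strict except at the -1 position itself,
      # whose base is governed by the U/G (or C/A) boundary rule
      if (k > 1L && any(g[(e5 + 1L):(i - 1L)] != ml[1:(k - 1L)])) next
      left_match <- k                  # -1 position satisfies the rule, counts as match
      partner <- if (g[i] == "T") "G" else "A"
      win <- g[(i + 1L):min(n, i + p1_window)]
      if (!partner %in% win) next
      p1_pos <- i + which(win == partner)[1L]
      for (jj in seq_len(nrow(a3))) {
        p3 <- a3$pos[jj]
        if (a5$mm[ii] + a3$mm[jj] > 1L) next
        j <- p3 - (L - k) - 1L         # omega position (last intron base)
        if (j - i < min_intron_len) next
        if (!omega_override && g[j] != "G") next
        if (k < L && any(g[(j + 1L):(j + L - k)] != ml[(k + 1L):L])) next
        right_match <- L - k
        score <- (s5 - a5$mm[ii]) + left_match + right_match + (s3 - a3$mm[jj])
        cand <- list(intron_start = i + 1L, intron_end = j,
                     minus1_base = chartr("T", "U", g[i]), omega_base = g[j],
                     p1_partner = partner, p1_position = p1_pos - i,
                     subsite = k, match_score = score)
        if (is.null(best) || score > best$match_score ||
            (score == best$match_score &&
             (cand$intron_start < best$intron_start ||
              (cand$intron_start == best$intron_start &&
               cand$intron_end < best$intron_end)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$spliced_exon <- paste0(substr(gene, 1L, best$intron_start - 1L),
                              substr(gene, best$intron_end + 1L, n))
  structure(best, class = "intron_call")
}

#' Assign the TpsiC-loop subsite of an intron call
#'
#' Recomputes, from the spliced exon, the internucleotide loop position
#' (1-8) at which the intron interrupts the reconstituted T-loop.  Errors
#' when the boundary does not fall within the loop.
#'
#' @param call an `intron_call` (needs `intron_start` and `spliced_exon`).
#' @param tloop a [tloop_model()].
#' @return integer subsite in 1..8.
#' @export
assign_subsite <- function(call, tloop = tloop_model()) {
  exon <- s2c(norm_seq(call$spliced_exon))
  junction <- call$intron_start - 1L   # last left-exon base, exon coordinates
  m5 <- s2c(tloop$stem5); m3 <- s2c(tloop$stem3); ml <- s2c(tloop$loop)
  s5 <- length(m5); s3 <- length(m3); L <- length(ml)
  best_k <- NA_integer_; best_score <- -1L
  for (k in 1:L) {
    ws <- junction - s5 - k + 1L
    we <- ws + s5 + L + s3 - 1L
    if (ws < 1L || we > length(exon)) next
    win <- exon[ws:we]
    mm_stem <- sum(win[1:s5] != m5) + sum(win[(s5 + L + 1L):(s5 + L + s3)] != m3)
    if (mm_stem > 1L) next
    score <- sum(win == c(m5, ml, m3))
    if (score > best_score) { best_score <- score; best_k <- k }
  }
  if (is.na(best_k)) {
    stop("assign_subsite: intron not in TpsiC-loop")
  }
  best_k
}

#' Base-frequency logo matrix for T-stem/loop sequences
#'
#' Unique sequences are weighted equally; per-column base frequencies sum to
#' 1 and the per-column information content is reported on the log2 scale
#' (IC = 2 - H for the 4-letter alphabet, so a 0.5/0.5 two-base column
#' carries exactly 1 bit).
#'
#' @param loops character vector of equal-length stem/loop sequences (ACGT/U).
#' @return list: `freq` (4 x L matrix, rows A,C,G,T), `ic` (length-L vector,
#'   bits), `n_unique`.
#' @export
subsite_logo <- function(loops) {
  loops <- vapply(loops, norm_seq, character(1), USE.NAMES = FALSE)
  if (!length(loops)) stop("subsite_logo: no sequences")
  lens <- nchar(loops)
  if (length(unique(lens)) != 1L) stop("subsite_logo: mixed sequence lengths")
  uniq <- unique(loops)
  bad <- grepl("[^ACGT]", uniq)
  if (any(bad)) stop("subsite_logo: non-ACGT characters in input")
  mat <- do.call(rbind, strsplit(uniq, "", fixed = TRUE))
  L <- ncol(mat)
  freq <- vapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = DNA_BASES))
    as.numeric(counts) / nrow(mat)
  }, numeric(4))
  rownames(freq) <- DNA_BASES
  ic <- vapply(seq_len(L), function(j) {
    p <- freq[, j]; p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
  list(freq = freq, ic = ic, n_unique = length(uniq))
}

#' Flag homing endonuclease genes within introns
#'
#' With HMMER domtblout evidence, an intron is flagged when a
#' LAGLIDADG-family hit (query name or accession) passes the e-value
#' inclusion cutoff; the insertion site is taken from the annotated site
#' nearest the hit envelope.  Without evidence a fallback heuristic flags
#' introns containing a forward-frame ORF of at least `min_orf_codons`
#' codons, localized to the configured site nearest the ORF.
#'
#' @param intron_seq intron nucleotide string.
#' @param domtbl parsed [parse_domtblout()] table for this intron, or `NULL`.
#' @param sites named integer vector of candidate insertion points within the
#'   intron (defaults: `in_P7.1` at mid-intron, `after_P9` near the 3' end).
#' @param min_orf_codons ORF-length cutoff for the heuristic (default 150).
#' @param max_ievalue inclusion threshold for domain evidence (default 1e-5).
#' @return `"none"`, `"after_P9"`, or `"in_P7.1"`.
#' @export
flag_heg <- function(intron_seq, domtbl = NULL, sites = NULL,
                     min_orf_codons = 150L, max_ievalue = 1e-5) {
  intron_seq <- norm_seq(intron_seq)
  n <- nchar(intron_seq)
  if (is.null(sites)) {
    sites <- c(in_P7.1 = max(1L, n %/% 2L), after_P9 = max(1L, n - 10L))
  }
  nearest_site <- function(pos) names(sites)[which.min(abs(sites - pos))]
  if (!is.null(domtbl) && nrow(domtbl) > 0L) {
    lag <- grepl("LAGLIDADG", paste(domtbl$query, domtbl$query_acc,
                                    domtbl$target, domtbl$target_acc),
                 ignore.case = TRUE) & domtbl$i_evalue <= max_ievalue
    if (any(lag)) {
      row <- domtbl[which(lag)[1L], ]
      mid <- (row$env_from + row$env_to) / 2
      return(nearest_site(mid))
    }
    return("none")
  }
  # heuristic: longest forward-frame ORF (ATG .. stop)
  for (frame in 0:2) {
    aa <- translate_frame(substr(intron_seq, 1L + frame, n))
    if (!length(aa)) next
    starts <- which(aa == "M")
    stops <- which(aa == "*")
    for (st in starts) {
      nxt <- stops[stops > st]
      if (!length(nxt)) next
      orf_codons <- nxt[1L] - st
      if (orf_codons >= min_orf_codons) {
        mid_nt <- frame + ((st + nxt[1L]) / 2) * 3
        return(nearest_site(mid_nt))
      }
    }
  }
  "none"
}

# Uniform random DNA of `len` bases, built chunk-wise so that neither the
# insert nor its junctions with the flanking context contain any of the
# `avoid` motifs; each chunk is redrawn on a motif hit.
build_clean_insert <- function(len, avoid, left_ctx = "", right_ctx = "") {
  hits <- function(s) any(vapply(avoid, grepl, logical(1), x = s, fixed = TRUE))
  out <- left_ctx
  remaining <- len
  while (remaining > 0L) {
    take <- min(64L, remaining)
    repeat {
      chunk <- random_dna(take)
      tail_part <- substr(out, max(1L, nchar(out) - 7L), nchar(out))
      probe <- paste0(tail_part, chunk,
                      if (take == remaining) right_ctx else "")
      if (!hits(probe)) break
    }
    out <- paste0(out, chunk)
    remaining <- remaining - take
  }
  substr(out, nchar(left_ctx) + 1L, nchar(left_ctx) + len)
}

#' Simulate a HEG insertion within an intron-form gene
#'
#' Inserts `length` uniform-random ACGT bases at one of the two known HEG
#' insertion sites (after stem P9 or in the P7.1 region), shifting the
#' segment map and any ground-truth annotations accordingly.  Deterministic
#' under `seed`; bases outside the insertion point are untouched.
#'
#' @param record an INTRON-form [gene_record()] carrying
#'   `truth$heg_sites` (named gene positions for `after_P9` and `in_P7.1`).
#' @param site `"after_P9"` or `"in_P7.1"`.
#' @param length insertion length in bp (0..2000 typical).
#' @param seed RNG seed.
#' @return the modified gene record.
#' @export
insert_heg_sim <- function(record, site, length, seed = 1L) {
  if (record$form != "INTRON") stop("insert_heg_sim: record is not INTRON form")
  sites <- record$truth$heg_sites
  if (is.null(sites) || !site %in% names(sites)) {
    stop("insert_heg_sim: unknown site '", site, "'")
  }
  length <- as.integer(length)
  if (length < 0L) stop("insert_heg_sim: negative insertion length")
  if (length == 0L) return(record)
  pos <- sites[[site]]                  # insert after this gene position
  tl <- record$truth$tloop %||% tloop_model()
  avoid <- unique(c(tl$stem5, tl$stem3))
  # random insert, conditioned on not recreating an exact T-stem motif at or
  # around the insertion point (which would plant a rule-ambiguous
  # alternative splice boundary; see the methods vignette)
  left_ctx <- substr(record$sequence, max(1L, pos - 7L), pos)
  right_ctx <- substr(record$sequence, pos + 1L,
                      min(nchar(record$sequence), pos + 8L))
  ins <- with_seed(seed, build_clean_insert(length, avoid, left_ctx, right_ctx))
  record$sequence <- paste0(substr(record$sequence, 1L, pos), ins,
                            substr(record$sequence, pos + 1L,
                                   nchar(record$sequence)))
  seg <- record$segments
  grow <- seg$start <= pos & seg$end > pos
  seg$end[grow] <- seg$end[grow] + length
  shift <- seg$start > pos
  seg$start[shift] <- seg$start[shift] + length
  seg$end[shift] <- seg$end[shift] + length
  record$segments <- segment_map(seg$segment, seg$start, seg$end)
  if (!is.null(record$truth)) {
    tr <- record$truth
    if (!is.null(tr$intron) && tr$intron[2] > pos) tr$intron[2] <- tr$intron[2] + length
    tr$heg_sites[tr$heg_sites > pos] <- tr$heg_sites[tr$heg_sites > pos] + length
    # keep the original site position usable for repeat insertions at the other site
    tr$heg_sites[[site]] <- pos
    record$truth <- tr
  }
  record
}
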