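# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic entry points thread an explicit seed through
# this so nothing in the package disturbs (or depends on) global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Locale-independent lexicographic order (C collation via radix sort).
lex_order <- function(x, ...) order(x, ..., method = "radix")

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# DNA alphabet normalization: uppercase, RNA U -> T.
norm_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", toupper(s))
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

random_dna <- function(n) {
  if (n <= 0) return("")
  c2s(sample(DNA_BASES, n, replace = TRUE))
}

# Base pairing in RNA-like stems: Watson-Crick plus G.U wobble (on DNA
# alphabet: G.T).  `a` and `b` are single characters on opposite strands.
pairs_ok <- function(a, b) {
  key <- paste0(a, b)
  key %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# Random non-stop codon (standard code); used by the generator for tag CDSs.
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codon <- function() {
  repeat {
    cod <- random_dna(3)
    if (!cod %in% STOP_CODONS) return(cod)
  }
}

# Translate a nucleotide string in frame 1 using a genetic-code table
# (named character vector codon -> single-letter aa, "*" for stop).
translate_frame <- function(seq, code = Biostrings::GENETIC_CODE) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - (n %% 3L), by = 3L)
  starts <- starts[starts + 2L <= n]
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

`%||%` <- function(a, b) if (is.null(a)) b else a
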