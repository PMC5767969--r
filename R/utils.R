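# Shared constants and small helpers used across modules.

#' The twenty standard amino acids (one-letter codes)
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue categories used by the profile HMMs and the naive Bayes
# classifier: the 20 amino acids plus the gap symbol.
AA_GAP <- c(AA20, "-")

# Legal protein alphabet on parse: 20 aa + ambiguity X and stop *.
AA_VALID <- c(AA20, "X", "*")

NT_VALID <- c("A", "C", "G", "T", "N")

#' Bacterial genetic code (translation table 11)
#'
#' Identical to the standard code for translation; differs only in the
#' initiation codons (ATG/GTG/TTG), which the ORF caller honours.
#' @keywords internal
genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

# Most-used E. coli codon per amino acid; fixed so that back-translation in
# the synthetic-genome generator is deterministic.
ECOLI_CODON <- c(
  A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGC", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAT"
)

STOP_CODON <- "TAA"

#' Reverse complement of a nucleotide string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string with table 11, N -> X
#' @keywords internal
translate11 <- function(nt) {
  if (nchar(nt) < 3L) return("")
  nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = genetic_code_11(),
    if.fuzzy.codon = "X"
  ))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Draw a reproducible RNG substream without disturbing the global seed
#'
#' All stochastic generators take an integer `seed`; generation is a pure
#' function of the spec including its seed.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
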