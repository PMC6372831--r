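# Shared low-level helpers: genetic code, scoring matrices, DNA utilities.

.pkg_env <- new.env(parent = emptyenv())

# 64-entry codon table ordered by index 16a + 4b + c with A=0,C=1,G=2,T=3,
# matching the C++ kernels. Values come from the standard genetic code.
codon_table <- function() {
  if (is.null(.pkg_env$codon_table)) {
    bases <- c("A", "C", "G", "T")
    codons <- character(64)
    k <- 1L
    for (a in bases) for (b in bases) for (cc in bases) {
      codons[k] <- paste0(a, b, cc)
      k <- k + 1L
    }
    gc <- Biostrings::GENETIC_CODE
    .pkg_env$codon_table <- unname(gc[codons])
  }
  .pkg_env$codon_table
}

# 128x128 integer score lookup indexed by ASCII code, built from BLOSUM62.
# Policy: 'X' (and any unknown character) scores 0 against everything;
# '*' keeps its BLOSUM62 scores.
score_matrix128 <- function() {
  if (is.null(.pkg_env$score128)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b62 <- e$BLOSUM62
    letters62 <- rownames(b62)
    S <- matrix(0L, 128, 128)
    for (i in seq_along(letters62)) for (j in seq_along(letters62)) {
      S[utf8ToInt(letters62[i]) + 1L, utf8ToInt(letters62[j]) + 1L] <-
        as.integer(b62[i, j])
    }
    S[utf8ToInt("X") + 1L, ] <- 0L
    S[, utf8ToInt("X") + 1L] <- 0L
    .pkg_env$score128 <- S
  }
  .pkg_env$score128
}

# BLOSUM62 as a standard matrix (for identity/score bookkeeping in R).
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a DNA string in frame +1 (floor(n/3) residues, N-codons -> X,
# stops -> '*').
translate_dna <- function(dna) {
  cpp_translate(dna, codon_table())
}

# longest run of 'N' in a sequence (0 if none)
max_n_run <- function(seq) {
  if (!grepl("N", seq, fixed = TRUE)) return(0L)
  runs <- regmatches(seq, gregexpr("N+", seq))[[1]]
  max(nchar(runs))
}

# random DNA at a given GC fraction
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
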