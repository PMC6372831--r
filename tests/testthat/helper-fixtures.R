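# Shared builders for the test suite. Everything is generated in code;
# the only stored fixtures are the plain-text group catalog and
# timetree under inst/extdata.

fixture_timetree <- function() {
  read_newick_with_ages(
    system.file("extdata", "host_timetree.nwk", package = "circomine"),
    age_ranges = utils::read.table(
      system.file("extdata", "host_timetree_age_ranges.tsv",
                  package = "circomine"),
      header = TRUE, stringsAsFactors = FALSE))
}

fixture_reference <- function(seed = 3) synth_reference(seed = seed)

# Mutate a CDS at codon level to an exact target amino-acid divergence:
# a fraction `d` of codons is rewritten to a codon of a different
# (non-stop) amino acid, so protein p-distance equals d by construction.
mutate_cds_divergence <- function(cds, d) {
  n_codon <- nchar(cds) %/% 3
  n_mut <- round(d * n_codon)
  if (n_mut == 0) return(cds)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  v <- substring(cds, 3 * (seq_len(n_codon) - 1) + 1, 3 * seq_len(n_codon))
  at <- sample.int(n_codon, n_mut)
  for (k in at) {
    aa <- gc[[v[k]]]
    alt <- sense[gc[sense] != aa & gc[sense] != "*"]
    v[k] <- sample(alt, 1)
  }
  paste(v, collapse = "")
}

# Independent six-frame exhaustive Smith-Waterman oracle built on
# Biostrings::pairwiseAlignment: best local score of any frame of `dna`
# against `protein` at the package's default gap costs.
sw_oracle_best <- function(dna, protein, gap_open = 11, gap_extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  frames <- six_frame_translate(dna)
  best <- 0
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    if (nchar(pep) < 1) next
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pep), Biostrings::AAString(protein),
      type = "local", substitutionMatrix = e$BLOSUM62,
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
    if (sc > best) best <- sc
  }
  best
}

# Independent plain-R rewrite of the frameshift-aware DP (score only),
# used as an oracle on small instances.
fs_align_score_R <- function(dna, prot, go = 12, ge = 2, fs = 15) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- e$BLOSUM62
  sc <- function(aa, p) {
    if (aa == "X" || p == "X") return(0)
    b62[aa, p]
  }
  gc_tab <- Biostrings::GENETIC_CODE
  aa_at <- function(i) { # codon ending at 1-based position i
    cod <- substring(dna, i - 2, i)
    if (grepl("[^ACGT]", cod)) "X" else unname(gc_tab[[cod]])
  }
  n <- nchar(dna)
  m <- nchar(prot)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  pv <- strsplit(prot, "")[[1]]
  for (i in 0:n) for (j in 0:m) {
    if (j >= 1) {
      v <- -Inf
      for (len in c(3, 2, 4, 1, 5)) {
        if (i < len) next
        prev <- c(M[i - len + 1, j], X[i - len + 1, j], Y[i - len + 1, j])
        prev_best <- max(prev, if (len == 3) 0 else -Inf)
        if (!is.finite(prev_best)) next
        aa <- if (len >= 3) aa_at(i) else "X"
        v <- max(v, prev_best + sc(aa, pv[j]) - if (len == 3) 0 else fs)
      }
      M[i + 1, j + 1] <- v
      if (is.finite(v) && v > best) best <- v
    }
    if (i >= 3) {
      X[i + 1, j + 1] <- max(M[i - 2, j + 1] - go - ge,
                             X[i - 2, j + 1] - ge)
    }
    if (j >= 1) {
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    }
  }
  best
}

# Small three-species simulation used by several orthology/dating tests.
sister_pair_sim <- function(seed, sub = 0.001, scenario_branch = "ab",
                            contig_len = 12000) {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,(C:25,D:25)cd:5)root;")
  sc <- list(insertion_scenario("S1", scenario_branch,
                                rates = decay_rates(sub = sub,
                                                    indel = 1e-5)))
  simulate_assembly(tt, sc, n_contigs = 2, contig_len = contig_len,
                    seed = seed)
}
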