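# Ancestral ORF reconstruction: frameshift-aware alignment of locus DNA
# to the closest reference protein, counting reading-frame disruptions
# (frameshifting indels, premature stop codons) and flagging intact ORFs.

#' ORF reconstruction parameters
#'
#' @param gap_open,gap_extend affine codon gap penalties (per codon).
#' @param frameshift_penalty cost of a 1-2 nt frame slip; set above
#'   `gap_open` so the alignment prefers clean codon gaps over spurious
#'   slips. Equal-score ties resolve toward fewer frameshifts.
#' @param min_score score floor below which a locus is reported
#'   unalignable.
#' @param intact_min_fraction minimum aligned fraction of the reference
#'   CDS for an intact call.
#' @return named list of parameters.
#' @export
orf_params <- function(gap_open = 12, gap_extend = 2,
                       frameshift_penalty = 15, min_score = 40,
                       intact_min_fraction = 0.95) {
  list(gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
       frameshift_penalty = as.integer(frameshift_penalty),
       min_score = min_score, intact_min_fraction = intact_min_fraction)
}

#' Codon-aware alignment of DNA to a reference protein
#'
#' Dynamic-programming local alignment in which each reference residue
#' is matched by a "codon" of 1-5 nucleotides; every non-triplet codon is
#' one frameshift event (so adjacent 1-2 nt slips each count). Stop
#' codons on the optimal path aligned to a non-terminal reference
#' position are premature stops.
#'
#' @param dna locus DNA (locus orientation).
#' @param protein reference protein.
#' @param params [orf_params()].
#' @return list: `alignable`, `score`, `dna_start`, `dna_end`,
#'   `prot_start`, `prot_end` (0-based half-open), `n_frameshifts`,
#'   `n_premature_stops`, `aligned_fraction`, `peptide` (reconstructed,
#'   `!` marking frameshifts), `steps` (per-step table).
#' @export
codon_aware_align <- function(dna, protein, params = orf_params()) {
  stopifnot(nchar(dna) >= 1, nchar(protein) >= 1)
  res <- cpp_frameshift_align(dna, protein, score_matrix128(),
                              codon_table(), params$gap_open,
                              params$gap_extend,
                              params$frameshift_penalty)
  if (res$score < params$min_score) {
    return(list(alignable = FALSE, score = res$score,
                dna_start = NA_integer_, dna_end = NA_integer_,
                prot_start = NA_integer_, prot_end = NA_integer_,
                n_frameshifts = NA_integer_,
                n_premature_stops = NA_integer_,
                aligned_fraction = NA_real_, peptide = NA_character_,
                steps = res$steps))
  }
  st <- res$steps
  m <- nchar(protein)
  match_steps <- st$state == 1
  n_fs <- sum(match_steps & st$nt_len != 3)
  n_stop <- sum(match_steps & st$aa == "*" & st$prot_pos < m)
  pieces <- character(nrow(st))
  for (i in seq_len(nrow(st))) {
    pieces[i] <- if (st$state[i] == 1) {
      paste0(if (st$nt_len[i] != 3) "!" else "", st$aa[i])
    } else if (st$state[i] == 2) {
      "" # extra codons in the locus: omitted from the peptide
    } else {
      "-" # reference residue deleted in the locus
    }
  }
  list(alignable = TRUE, score = res$score, dna_start = res$dna_start,
       dna_end = res$dna_end, prot_start = res$prot_start,
       prot_end = res$prot_end, n_frameshifts = n_fs,
       n_premature_stops = n_stop,
       aligned_fraction = (res$prot_end - res$prot_start) / m,
       peptide = paste(pieces, collapse = ""), steps = st)
}

#' ORF reports for classified loci
#'
#' Aligns each classified locus to the protein of its closest reference
#' (for `rep+cap` loci, to both in turn) and reports disruption counts.
#' A locus is intact when it has no frameshifts, no premature stops, and
#' covers at least `intact_min_fraction` of the reference CDS.
#'
#' @param loci locus table with `locus_id`, `locus_seq`.
#' @param classifications [classify_loci()] output.
#' @param refs reference library (list of [viral_reference()]).
#' @param params [orf_params()].
#' @return data.frame: `locus_id`, `gene`, `reference`, `n_frameshifts`,
#'   `n_premature_stops`, `aligned_fraction`, `intact`, `peptide`.
#' @export
orf_report <- function(loci, classifications, refs, params = orf_params()) {
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  rows <- list()
  for (i in seq_len(nrow(classifications))) {
    cls <- classifications[i, ]
    if (cls$gene == "unknown") {
      message("orf_report: skipping unclassified locus ", cls$locus_id)
      next
    }
    dna <- loci$locus_seq[match(cls$locus_id, loci$locus_id)]
    genes <- if (cls$gene == "rep+cap") c("rep", "cap") else cls$gene
    for (g in genes) {
      ref <- refs[[cls$best_ref]]
      if (!g %in% names(ref$proteins)) next
      aln <- codon_aware_align(dna, ref$proteins[[g]], params)
      intact <- isTRUE(aln$alignable) && aln$n_frameshifts == 0 &&
        aln$n_premature_stops == 0 &&
        aln$aligned_fraction >= params$intact_min_fraction
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = cls$locus_id, gene = g, reference = ref$name,
        alignable = aln$alignable,
        n_frameshifts = if (aln$alignable) aln$n_frameshifts else NA_integer_,
        n_premature_stops = if (aln$alignable) aln$n_premature_stops else NA_integer_,
        aligned_fraction = aln$aligned_fraction, intact = intact,
        peptide = aln$peptide, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(0), gene = character(0),
                      reference = character(0), alignable = logical(0),
                      n_frameshifts = integer(0),
                      n_premature_stops = integer(0),
                      aligned_fraction = numeric(0), intact = logical(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
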