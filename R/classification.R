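# Second screening step: classify each extracted locus by best match
# against a virus reference library and map its footprint onto
# reference-genome coordinates.

#' Construct a viral reference
#'
#' A circovirus-style reference: a ~2 kb genome with a `rep` and a `cap`
#' CDS (0-based half-open coordinates; `cap` is typically on the minus
#' strand of the ambisense genome). CDS must translate without internal
#' stop codons.
#'
#' @param name reference ID.
#' @param genome DNA string.
#' @param cds_table data.frame with `gene` (`rep`/`cap`), `start`, `end`,
#'   `strand`.
#' @return a `ViralReference` (list with `name`, `genome`, `cds_table`,
#'   `proteins`).
#' @export
viral_reference <- function(name, genome, cds_table) {
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(cds_table)),
            all(cds_table$gene %in% c("rep", "cap")),
            all(cds_table$end <= nchar(genome)))
  proteins <- character(nrow(cds_table))
  for (i in seq_len(nrow(cds_table))) {
    dna <- substring(genome, cds_table$start[i] + 1, cds_table$end[i])
    if (cds_table$strand[i] == "-") dna <- revcomp(dna)
    aa <- translate_dna(dna)
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) {
      stop("internal stop codon in ", name, " ", cds_table$gene[i], " CDS")
    }
    proteins[i] <- aa
  }
  names(proteins) <- cds_table$gene
  structure(list(name = name, genome = genome, genome_len = nchar(genome),
                 cds_table = cds_table, proteins = proteins),
            class = "ViralReference")
}

#' Build a probe set from a reference library
#'
#' @param refs list of [viral_reference()] objects.
#' @param genes which genes to take probes from.
#' @return a [probe_set()] with probe IDs `<ref>_<gene>`.
#' @export
probes_from_references <- function(refs, genes = c("rep", "cap")) {
  rows <- list()
  for (r in refs) {
    for (g in intersect(genes, names(r$proteins))) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = paste(r$name, g, sep = "_"), ref = r$name, gene = g,
        protein = unname(r$proteins[[g]]), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  probe_set(df$probe_id, df$ref, df$gene, df$protein)
}

# best local alignments of a DNA sequence against one protein across all
# six frames; returns hits at or above min_score with probe intervals
six_frame_hits <- function(dna, protein, params, min_score = 1L) {
  S <- score_matrix128()
  frames <- six_frame_translate(dna)
  out <- list()
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    if (nchar(pep) < 1) next
    h <- cpp_seeded_hits(pep, protein, S, 1L, params$gap_open,
                         params$gap_extend, as.integer(min_score),
                         nchar(protein))
    if (nrow(h) > 0) {
      h$frame <- frames$frame[i]
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Classify loci against a reference library
#'
#' Each locus is translated in all six frames and locally aligned to
#' every reference polypeptide. The highest bit score assigns the gene
#' and closest reference; ties break by higher reference coverage, then
#' lexicographic reference ID. A locus matching both `rep` and `cap`
#' references above the significance threshold is assigned `rep+cap`;
#' one matching nothing is `unknown`.
#'
#' @param loci locus table with `locus_id` and `locus_seq` columns.
#' @param refs list of [viral_reference()] objects.
#' @param params [screen_params()] (threshold and gap costs are reused).
#' @return data.frame: `locus_id`, `gene`, `best_ref`, `best_bit`,
#'   `second_ref`, `margin`, `ref_cov`, plus list-column `ref_intervals`
#'   (per assigned gene: reference-protein intervals, 0-based half-open).
#' @export
classify_loci <- function(loci, refs, params = screen_params()) {
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    dna <- loci$locus_seq[i]
    stopifnot(nzchar(dna))
    per <- list() # per (ref, gene): score, intervals
    for (r in refs) {
      for (g in names(r$proteins)) {
        prot <- r$proteins[[g]]
        ms <- min_raw_score(nchar(prot), floor(nchar(dna) / 3), params)
        h <- six_frame_hits(dna, prot, params, min_score = ms)
        if (is.null(h) || nrow(h) == 0) next
        iv <- IRanges::reduce(IRanges::IRanges(h$pstart + 1L, h$pend))
        per[[length(per) + 1L]] <- list(
          ref = r$name, gene = g, score = max(h$score),
          cov = sum(IRanges::width(iv)) / nchar(prot),
          intervals = data.frame(gene = g, ref = r$name,
                                 pstart = IRanges::start(iv) - 1L,
                                 pend = IRanges::end(iv),
                                 stringsAsFactors = FALSE))
      }
    }
    if (length(per) == 0) {
      row <- data.frame(locus_id = loci$locus_id[i], gene = "unknown",
                        best_ref = NA_character_, best_bit = NA_real_,
                        second_ref = NA_character_, margin = NA_real_,
                        ref_cov = NA_real_, stringsAsFactors = FALSE)
      row$ref_intervals <- I(list(NULL))
      rows[[length(rows) + 1L]] <- row
      next
    }
    sc <- vapply(per, function(x) x$score, numeric(1))
    cv <- vapply(per, function(x) x$cov, numeric(1))
    rf <- vapply(per, function(x) x$ref, character(1))
    gn <- vapply(per, function(x) x$gene, character(1))
    ord <- order(-sc, -cv, rf)
    best <- per[[ord[1]]]
    genes <- sort(unique(gn))
    gene <- if (all(c("rep", "cap") %in% genes)) "rep+cap" else genes[1]
    # margin against the best-scoring different reference
    other <- sc[rf != best$ref]
    margin <- if (length(other) > 0) {
      bit_score(best$score, params) - bit_score(max(other), params)
    } else {
      bit_score(best$score, params)
    }
    second <- if (length(other) > 0) {
      rf[rf != best$ref][which.max(other)]
    } else NA_character_
    # report intervals for the best reference per assigned gene
    ivs <- list()
    for (g in intersect(c("rep", "cap"), genes)) {
      cand <- per[gn == g]
      cscore <- sc[gn == g]
      ivs[[g]] <- cand[[which.max(cscore)]]$intervals
    }
    row <- data.frame(locus_id = loci$locus_id[i], gene = gene,
                      best_ref = best$ref,
                      best_bit = bit_score(best$score, params),
                      second_ref = second, margin = margin,
                      ref_cov = best$cov, stringsAsFactors = FALSE)
    row$ref_intervals <- I(list(do.call(rbind, ivs)))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map a classified locus onto reference-genome coordinates
#'
#' Converts reference-protein intervals to nucleotide intervals on the
#' reference genome via its CDS table and reports the fraction of the
#' genome covered, enabling genome-structure summaries.
#'
#' @param classification one row of [classify_loci()] output.
#' @param reference the matching [viral_reference()].
#' @return list with `intervals` (data.frame `gene`, `start`, `end` on
#'   the reference genome, 0-based half-open, unioned) and `coverage`
#'   (fraction of the reference genome).
#' @export
map_to_reference <- function(classification, reference) {
  stopifnot(nrow(classification) == 1)
  if (classification$gene == "unknown") {
    stop("cannot map an unclassified locus")
  }
  iv <- classification$ref_intervals[[1]]
  iv <- iv[iv$ref == classification$best_ref |
             iv$ref %in% reference$name, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    cds <- reference$cds_table[reference$cds_table$gene == iv$gene[i], ]
    if (nrow(cds) == 0) next
    if (cds$strand[1] == "+") {
      g0 <- cds$start[1] + 3L * iv$pstart[i]
      g1 <- cds$start[1] + 3L * iv$pend[i]
    } else {
      g0 <- cds$end[1] - 3L * iv$pend[i]
      g1 <- cds$end[1] - 3L * iv$pstart[i]
    }
    rows[[length(rows) + 1L]] <- data.frame(gene = iv$gene[i], start = g0,
                                            end = g1,
                                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  red <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
  out <- data.frame(start = IRanges::start(red) - 1L,
                    end = IRanges::end(red))
  list(intervals = df, merged = out,
       coverage = min(1, sum(out$end - out$start) / reference$genome_len))
}
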