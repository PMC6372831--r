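# First screening step: seeded six-frame translated similarity search of
# an assembly with protein probes, hit merging, and locus extraction with
# genomic flanks.

#' Screening parameters
#'
#' Defaults for the translated search. The significance threshold is an
#' E-value computed from the raw Smith-Waterman score with ungapped
#' Karlin-Altschul constants for BLOSUM62 (lambda = 0.318, K = 0.13), a
#' documented approximation for gapped scores. All values are recorded in
#' run manifests.
#'
#' @param word_size exact-match seed length in residues; `1` degenerates
#'   to exhaustive Smith-Waterman.
#' @param gap_open,gap_extend affine gap penalties (BLAST-style 11/1).
#' @param e_max significance threshold on the E-value.
#' @param lambda,K Karlin-Altschul constants for the bit-score transform.
#' @param max_gap maximum nucleotide gap between same-strand hits merged
#'   into one locus; the default (1000) lets a ~2 kb circovirus genome
#'   split by one deletion still merge.
#' @param flank_len flank length extracted either side of a locus.
#' @param pad seed window padding in residues beyond the projected
#'   probe extent; 64 covers far more diagonal drift than the gap
#'   penalties ever make favourable.
#' @return a named list of parameters.
#' @export
screen_params <- function(word_size = 4, gap_open = 11, gap_extend = 1,
                          e_max = 1e-5, lambda = 0.318, K = 0.13,
                          max_gap = 1000, flank_len = 1000, pad = 64) {
  list(word_size = as.integer(word_size), gap_open = as.integer(gap_open),
       gap_extend = as.integer(gap_extend), e_max = e_max, lambda = lambda,
       K = K, max_gap = as.integer(max_gap),
       flank_len = as.integer(flank_len), pad = pad)
}

#' Build a probe set
#'
#' @param probe_id,ref,gene,protein equal-length vectors describing each
#'   probe: unique ID, source reference, gene (`rep` or `cap`), protein
#'   sequence.
#' @return data.frame of class `ProbeSet`.
#' @export
probe_set <- function(probe_id, ref, gene, protein) {
  stopifnot(!anyDuplicated(probe_id), all(gene %in% c("rep", "cap")))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", protein)
  if (any(bad)) stop("invalid protein alphabet in probe: ", probe_id[bad][1])
  structure(data.frame(probe_id = probe_id, ref = ref, gene = gene,
                       protein = protein, stringsAsFactors = FALSE),
            class = c("ProbeSet", "data.frame"))
}

# raw-score threshold equivalent to E <= e_max for search space m x n
min_raw_score <- function(m, n, p) {
  bits_min <- log2(m * n / p$e_max)
  as.integer(ceiling((bits_min * log(2) + log(p$K)) / p$lambda))
}

bit_score <- function(raw, p) (p$lambda * raw - log(p$K)) / log(2)

#' Seeded translated search
#'
#' For every probe and reading frame, exact `word_size`-mer seeds are
#' located in the translated contig, seed neighbourhoods are merged into
#' windows, and gapped local alignment recovers all non-overlapping hits
#' above the significance threshold. E-values are `m * n * 2^-S'` with
#' bit score `S' = (lambda*S - ln K)/ln 2`.
#'
#' @param assembly an [assembly()].
#' @param probes a [probe_set()].
#' @param params [screen_params()].
#' @return data.frame of hits: `contig`, `start`, `end` (0-based
#'   half-open nt), `strand`, `frame`, `probe_id`, `gene`, `raw_score`,
#'   `bit_score`, `e_value`, `probe_start`, `probe_end` (0-based aa).
#' @export
seeded_search <- function(assembly, probes, params = screen_params()) {
  stopifnot(inherits(assembly, "Assembly"))
  if (any(nchar(probes$protein) < params$word_size)) {
    stop("probe shorter than seed word size: ",
         probes$probe_id[nchar(probes$protein) < params$word_size][1])
  }
  S <- score_matrix128()
  rows <- list()
  for (ci in seq_along(assembly$contigs)) {
    contig <- names(assembly$contigs)[ci]
    dna <- assembly$contigs[[ci]]
    L <- nchar(dna)
    if (L < 3) next
    strands <- list(`+` = dna, `-` = revcomp(dna))
    for (st in names(strands)) {
      sdna <- strands[[st]]
      for (off in 0:2) {
        pep <- translate_dna(substring(sdna, off + 1))
        if (nchar(pep) < 1) next
        for (pi in seq_len(nrow(probes))) {
          probe <- probes$protein[pi]
          m <- nchar(probe)
          pad <- params$pad %||% 64
          ms <- min_raw_score(m, nchar(pep), params)
          h <- cpp_seeded_hits(pep, probe, S, params$word_size,
                               params$gap_open, params$gap_extend, ms, pad)
          if (nrow(h) == 0) next
          nt_start <- off + 3L * h$sstart
          nt_end <- off + 3L * h$send
          if (st == "-") {
            tmp <- L - nt_end
            nt_end <- L - nt_start
            nt_start <- tmp
          }
          bits <- bit_score(h$score, params)
          rows[[length(rows) + 1L]] <- data.frame(
            contig = contig, start = nt_start, end = nt_end, strand = st,
            frame = (off + 1L) * ifelse(st == "+", 1L, -1L),
            probe_id = probes$probe_id[pi], gene = probes$gene[pi],
            raw_score = h$score, bit_score = bits,
            e_value = m * nchar(pep) * 2^(-bits),
            probe_start = h$pstart, probe_end = h$pend,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), probe_id = character(0),
                      gene = character(0), raw_score = integer(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      probe_start = integer(0), probe_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[out$e_value <= params$e_max, , drop = FALSE]
  out <- drop_frame_shadows(out)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# The per-frame search is exhaustive within each frame, so a hit split
# by a frameshift reappears as a weaker, genomically overlapping hit in
# another frame. Keep, per contig/strand/probe, a best-first set of
# hits with at most marginal genomic overlap.
drop_frame_shadows <- function(hits, max_overlap = 30, max_frac = 0.25) {
  if (nrow(hits) <= 1) return(hits)
  keep <- logical(nrow(hits))
  for (kk in unique(paste(hits$contig, hits$strand, hits$probe_id))) {
    at <- which(paste(hits$contig, hits$strand, hits$probe_id) == kk)
    at <- at[order(-hits$raw_score[at])]
    taken <- at[0]
    for (i in at) {
      ov <- pmin(hits$end[i], hits$end[taken]) -
        pmax(hits$start[i], hits$start[taken])
      shorter <- pmin(hits$end[i] - hits$start[i],
                      hits$end[taken] - hits$start[taken])
      if (length(ov) == 0 ||
          all(ov <= pmin(max_overlap, max_frac * shorter))) {
        taken <- c(taken, i)
      }
    }
    keep[taken] <- TRUE
  }
  hits[keep, , drop = FALSE]
}

#' Merge hits into loci
#'
#' Hits on the same contig and strand whose nucleotide gap is at most
#' `max_gap` are merged into one locus (intervals from overlapping probes
#' are unioned). A locus whose merged hits cover the same probe region
#' two or more times in series is flagged as a tandem array.
#'
#' @param hits data.frame from [seeded_search()].
#' @param params [screen_params()] (uses `max_gap`).
#' @return data.frame of loci sorted by contig and start: `locus_id`,
#'   `contig`, `start`, `end`, `strand`, `n_hits`, `genes`, `tandem`,
#'   plus a `hits` list-column.
#' @export
merge_hits <- function(hits, params = screen_params()) {
  if (nrow(hits) == 0) {
    return(data.frame(locus_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      genes = character(0), tandem = logical(0),
                      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$contig, hits$strand, hits$start), , drop = FALSE]
  key <- paste(hits$contig, hits$strand)
  loci <- list()
  for (kk in unique(key)) {
    hh <- hits[key == kk, , drop = FALSE]
    grp <- integer(nrow(hh))
    g <- 1L
    grp[1] <- g
    cur_end <- hh$end[1]
    for (i in seq_len(nrow(hh))[-1]) {
      if (hh$start[i] - cur_end <= params$max_gap) {
        grp[i] <- g
        cur_end <- max(cur_end, hh$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        cur_end <- hh$end[i]
      }
    }
    for (gi in seq_len(g)) {
      sub <- hh[grp == gi, , drop = FALSE]
      tandem <- FALSE
      # same probe region hit repeatedly in genomic series -> tandem
      for (gene in unique(sub$gene)) {
        sg <- sub[sub$gene == gene, , drop = FALSE]
        if (nrow(sg) < 2) next
        sg <- sg[order(sg$start), , drop = FALSE]
        for (i in seq_len(nrow(sg) - 1)) {
          ov <- min(sg$probe_end[i], sg$probe_end[i + 1]) -
            max(sg$probe_start[i], sg$probe_start[i + 1])
          shorter <- min(sg$probe_end[i] - sg$probe_start[i],
                         sg$probe_end[i + 1] - sg$probe_start[i + 1])
          if (shorter > 0 && ov / shorter >= 0.5) tandem <- TRUE
        }
      }
      loci[[length(loci) + 1L]] <- data.frame(
        contig = sub$contig[1], start = min(sub$start), end = max(sub$end),
        strand = sub$strand[1], n_hits = nrow(sub),
        genes = paste(sort(unique(sub$gene)), collapse = "+"),
        tandem = tandem, stringsAsFactors = FALSE)
      loci[[length(loci)]]$hits <- I(list(sub))
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out <- cbind(locus_id = sprintf("L%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract locus and flank sequences
#'
#' Sequences are reported in locus orientation: for a minus-strand locus
#' the locus sequence is reverse complemented and the upstream flank is
#' the reverse complement of the 3' genomic neighbourhood. A flank is
#' flagged incomplete when truncated by the contig edge or when it
#' contains a run of 50 or more undetermined (N) bases.
#'
#' @param assembly the screened [assembly()].
#' @param loci data.frame from [merge_hits()].
#' @param flank_len flank length (nt).
#' @param n_run_min N-run length that marks a flank undetermined.
#' @return `loci` with columns `locus_seq`, `flank_up`, `flank_down`,
#'   `flank_up_complete`, `flank_down_complete` added.
#' @export
extract_locus <- function(assembly, loci, flank_len = 1000, n_run_min = 50) {
  if (nrow(loci) == 0) {
    loci$locus_seq <- character(0)
    loci$flank_up <- character(0)
    loci$flank_down <- character(0)
    loci$flank_up_complete <- logical(0)
    loci$flank_down_complete <- logical(0)
    return(loci)
  }
  seqs <- flk_up <- flk_dn <- character(nrow(loci))
  up_ok <- dn_ok <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    contig <- loci$contig[i]
    if (!contig %in% names(assembly$contigs)) {
      stop("locus contig not in assembly: ", contig)
    }
    dna <- assembly$contigs[[contig]]
    L <- nchar(dna)
    s <- loci$start[i]
    e <- loci$end[i]
    if (s < 0 || e > L) stop("locus outside contig: ", loci$locus_id[i])
    core <- substring(dna, s + 1, e)
    left <- substring(dna, max(0, s - flank_len) + 1, s)
    right <- substring(dna, e + 1, min(L, e + flank_len))
    if (loci$strand[i] == "+") {
      up <- left
      dn <- right
    } else {
      core <- revcomp(core)
      up <- revcomp(right)
      dn <- revcomp(left)
    }
    seqs[i] <- core
    flk_up[i] <- up
    flk_dn[i] <- dn
    up_ok[i] <- nchar(up) >= flank_len && max_n_run(up) < n_run_min
    dn_ok[i] <- nchar(dn) >= flank_len && max_n_run(dn) < n_run_min
  }
  loci$locus_seq <- seqs
  loci$flank_up <- flk_up
  loci$flank_down <- flk_dn
  loci$flank_up_complete <- up_ok
  loci$flank_down_complete <- dn_ok
  loci
}

#' Screen an assembly end to end
#'
#' Convenience wrapper: [seeded_search()] + [merge_hits()] +
#' [extract_locus()], attaching the assembly's species label.
#'
#' @inheritParams seeded_search
#' @return extracted locus table.
#' @export
screen_assembly <- function(assembly, probes, params = screen_params()) {
  hits <- seeded_search(assembly, probes, params)
  loci <- merge_hits(hits, params)
  loci <- extract_locus(assembly, loci, flank_len = params$flank_len)
  if (!"hits" %in% names(loci)) loci$hits <- I(list())
  loci <- cbind(species = rep(assembly$species, nrow(loci)),
                assembly = rep(assembly$name, nrow(loci)),
                loci, stringsAsFactors = FALSE)
  if (nrow(loci) > 0) {
    loci$locus_id <- paste0(assembly$species, ".", loci$locus_id)
  }
  loci
}
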