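# Readers/writers for FASTA, BED, GFF3 and newick timetrees, plus basic
# sequence utilities shared by all pipeline stages.
#
# Coordinate conventions: BED and everything internal are 0-based
# half-open; GFF3 is 1-based inclusive.

#' Construct an assembly object
#'
#' An assembly is a set of named contigs (uppercase A/C/G/T/N) with an
#' optional soft-mask track recording which input bases were lowercase.
#'
#' @param contigs named character vector of contig sequences.
#' @param name assembly name.
#' @param species species label.
#' @param mask optional named list of logical vectors (one per contig,
#'   TRUE where the input base was lowercase-masked).
#' @return an object of class `"Assembly"`.
#' @export
assembly <- function(contigs, name = "assembly", species = NA_character_,
                     mask = NULL) {
  if (length(contigs) > 0 && is.null(names(contigs))) {
    stop("contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    dup <- names(contigs)[duplicated(names(contigs))][1]
    stop("duplicate contig ID: ", dup)
  }
  if (any(nchar(contigs) == 0)) {
    stop("empty contig: ", names(contigs)[nchar(contigs) == 0][1])
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("non-IUPAC (non-ACGTN) characters in contig: ",
         names(contigs)[bad][1])
  }
  structure(list(contigs = contigs, name = name, species = species,
                 mask = mask),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("<Assembly> %s (%s): %d contigs, %s bp\n", x$name,
              x$species, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Read a FASTA file into an Assembly
#'
#' Lowercase (soft-masked) bases are uppercased and recorded in the mask
#' track. Duplicate record IDs and non-IUPAC characters are errors; an
#' empty file yields an empty assembly with a warning.
#'
#' @param path FASTA file.
#' @param name,species passed to [assembly()]; `name` defaults to the
#'   file name.
#' @return an `Assembly`.
#' @export
read_fasta <- function(path, name = NULL, species = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  name <- name %||% basename(path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(assembly(setNames(character(0), character(0)), name = name,
                    species = species))
  }
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ID: ", ids[duplicated(ids)][1])
  }
  seqs <- as.character(recs)
  mask <- lapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    v %in% c("a", "c", "g", "t", "n")
  })
  up <- toupper(seqs)
  names(up) <- ids
  names(mask) <- ids
  if (all(!unlist(mask))) mask <- NULL
  assembly(up, name = name, species = species, mask = mask)
}

#' Write sequences to FASTA
#'
#' @param x an `Assembly`, or a named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  seqs <- if (inherits(x, "Assembly")) x$contigs else x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Six-frame translation
#'
#' Translates a DNA string in all six frames using the standard genetic
#' code. Stop codons are rendered `*`; codons containing `N` render `X`.
#'
#' @param dna a single DNA string (length >= 3).
#' @return data.frame with columns `frame` (+1,+2,+3,-1,-2,-3), `strand`,
#'   `offset` (0-based offset of the frame on its strand) and `peptide`.
#' @export
six_frame_translate <- function(dna) {
  stopifnot(nchar(dna) >= 3)
  rc <- revcomp(dna)
  out <- data.frame(frame = integer(0), strand = character(0),
                    offset = integer(0), peptide = character(0),
                    stringsAsFactors = FALSE)
  for (off in 0:2) {
    out <- rbind(out, data.frame(
      frame = off + 1L, strand = "+", offset = off,
      peptide = translate_dna(substring(dna, off + 1)),
      stringsAsFactors = FALSE))
  }
  for (off in 0:2) {
    out <- rbind(out, data.frame(
      frame = -(off + 1L), strand = "-", offset = off,
      peptide = translate_dna(substring(rc, off + 1)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Read / write BED (0-based half-open)
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, and where present
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6],
                          fill = TRUE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname read_bed
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(df, path) {
  std <- c("chrom", "start", "end", "name", "score", "strand")
  stopifnot(all(std[1:3] %in% names(df)))
  last <- max(c(3L, which(std %in% names(df))))
  defaults <- list(name = ".", score = 0L, strand = ".")
  out <- df[, std[1:3], drop = FALSE]
  for (col in std[seq_len(last)][-(1:3)]) {
    out[[col]] <- if (col %in% names(df)) df[[col]] else defaults[[col]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write GFF3 (1-based inclusive)
#'
#' @param path file path.
#' @return data.frame with the nine GFF3 columns.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), score = character(0),
                      strand = character(0), phase = character(0),
                      attributes = character(0), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("seqid", "source", "type", "start",
                                        "end", "score", "strand", "phase",
                                        "attributes"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname read_gff3
#' @param df data.frame with the nine GFF3 columns.
#' @export
write_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert between BED and GFF3 interval conventions
#'
#' BED `[start, end)` 0-based maps to GFF3 `[start+1, end]` 1-based.
#'
#' @param bed,gff data.frames as returned by [read_bed()] / [read_gff3()].
#' @param source,type GFF3 source and feature type for the conversion.
#' @return converted data.frame.
#' @export
bed_to_gff3 <- function(bed, source = "circomine", type = "CVe_locus") {
  data.frame(seqid = bed$chrom, source = source, type = type,
             start = bed$start + 1L, end = bed$end, score = ".",
             strand = if ("strand" %in% names(bed)) bed$strand else ".",
             phase = ".",
             attributes = if ("name" %in% names(bed)) {
               paste0("ID=", bed$name)
             } else ".",
             stringsAsFactors = FALSE)
}

#' @rdname bed_to_gff3
#' @export
gff3_to_bed <- function(gff) {
  nm <- sub("^ID=", "", sub(";.*$", "", gff$attributes))
  data.frame(chrom = gff$seqid, start = gff$start - 1L, end = gff$end,
             name = nm, score = 0L, strand = gff$strand,
             stringsAsFactors = FALSE)
}

#' Read a newick timetree with node ages
#'
#' Branch lengths are in million years (My). Node ages are derived from
#' root-to-tip path lengths and the tree is required to be ultrametric to
#' a relative tolerance of `tol` times the root age; otherwise the worst
#' leaf discrepancy is reported. Optional per-node age ranges (for
#' published divergence-time intervals such as 72-90 My) can be supplied
#' as a sidecar table keyed by internal node label.
#'
#' @param path newick file, or a newick string.
#' @param age_ranges optional data.frame with columns `node`, `lo`, `hi`.
#' @param tol relative ultrametricity tolerance.
#' @return a `HostTimeTree`: list with `tree` (ape phylo), `ages` (numeric
#'   per node, leaves 0), `tags` (species tag per leaf), `age_ranges`.
#' @export
read_newick_with_ages <- function(path, age_ranges = NULL, tol = 1e-6) {
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  host_timetree(tree, age_ranges = age_ranges, tol = tol)
}

#' @rdname read_newick_with_ages
#' @param tree an ape `phylo` with branch lengths in My.
#' @export
host_timetree <- function(tree, age_ranges = NULL, tol = 1e-6) {
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth[seq_len(ntip)])
  disc <- abs(depth[seq_len(ntip)] - root_age)
  if (max(disc) > tol * root_age) {
    worst <- which.max(disc)
    stop(sprintf(
      "tree is not ultrametric: leaf '%s' root-path differs by %.6g My",
      tree$tip.label[worst], max(disc)))
  }
  ages <- root_age - depth
  ages[seq_len(ntip)] <- 0
  tags <- make_species_tags(tree$tip.label)
  if (!is.null(age_ranges)) {
    stopifnot(all(c("node", "lo", "hi") %in% names(age_ranges)))
  }
  structure(list(tree = tree, ages = ages, tags = tags,
                 age_ranges = age_ranges),
            class = "HostTimeTree")
}

#' @export
print.HostTimeTree <- function(x, ...) {
  cat(sprintf("<HostTimeTree> %d species, root age %.1f My\n",
              length(x$tree$tip.label), max(x$ages)))
  invisible(x)
}

#' Six-letter species tags
#'
#' Builds the standard genus+species abbreviation used in CVe
#' identifiers, e.g. `Ursus_maritimus` -> `UrsMar`. Tags must be unique;
#' collisions are disambiguated with a trailing digit.
#'
#' @param species character vector of `Genus_species` labels.
#' @return named character vector of tags.
#' @export
make_species_tags <- function(species) {
  parts <- strsplit(species, "[_ ]+")
  tag1 <- function(p) {
    g <- p[1]
    s <- if (length(p) >= 2) p[2] else "sp"
    cap <- function(w) paste0(toupper(substring(w, 1, 1)),
                              tolower(substring(w, 2, 3)))
    paste0(cap(g), cap(s))
  }
  tags <- vapply(parts, tag1, character(1))
  if (anyDuplicated(tags)) {
    for (t in unique(tags[duplicated(tags)])) {
      at <- which(tags == t)
      tags[at] <- paste0(t, seq_along(at))
    }
  }
  setNames(tags, species)
}
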