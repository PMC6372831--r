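# Synthetic-data module: generates host assemblies containing planted
# viral insertions with known evolutionary history (insertion branch,
# neutral decay, tandem arrays, LINE-adjacent duplications, assembly
# fragmentation), plus a complete ground-truth table, so every
# downstream stage is verifiable offline.
#
# Background host sequence is i.i.d. nucleotide at a specified GC and is
# deliberately repeat-free apart from injected LINE cassettes. All
# coordinates are 0-based half-open.

#' Synthesise a circovirus-like reference
#'
#' A ~2 kb ambisense genome: `rep` CDS on the plus strand, `cap` CDS on
#' the minus strand, both built from random non-stop codons so they
#' translate cleanly.
#'
#' @param name reference ID.
#' @param rep_len,cap_len protein lengths (residues).
#' @param genome_len total genome length (nt).
#' @param gc GC fraction of intergenic sequence.
#' @param seed RNG seed.
#' @return a [viral_reference()].
#' @export
synth_reference <- function(name = "SynCV1", rep_len = 300, cap_len = 230,
                            genome_len = 2000, gc = 0.45, seed = 1) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, stops)
  rand_cds <- function(n_aa) {
    paste0("ATG", paste(sample(sense, n_aa - 1, replace = TRUE),
                        collapse = ""), "TAA")
  }
  rep_cds <- rand_cds(rep_len)
  cap_cds <- rand_cds(cap_len)
  rep_start <- 60L
  rep_end <- rep_start + nchar(rep_cds)
  cap_end_g <- genome_len - 40L
  cap_start_g <- cap_end_g - nchar(cap_cds)
  stopifnot(cap_start_g > rep_end + 20)
  genome <- strsplit(random_dna(genome_len, gc), "")[[1]]
  genome[(rep_start + 1):rep_end] <- strsplit(rep_cds, "")[[1]]
  genome[(cap_start_g + 1):cap_end_g] <- strsplit(revcomp(cap_cds), "")[[1]]
  viral_reference(name, paste(genome, collapse = ""),
                  data.frame(gene = c("rep", "cap"),
                             start = c(rep_start, cap_start_g),
                             end = c(rep_end, cap_end_g),
                             strand = c("+", "-"),
                             stringsAsFactors = FALSE))
}

#' Decay rates
#'
#' Neutral decay rates per site per My. Values are user parameters, not
#' estimates: no substitution-rate calibration exists for CVe decay.
#'
#' @param sub substitutions per site per My (Jukes-Cantor style process:
#'   events are Poisson with this rate, targets uniform over the other
#'   three bases).
#' @param indel indel events per site per My (geometric lengths, mean
#'   2 nt, insertions and deletions equally likely).
#' @param stop targeted stop-gain events per viral codon per My.
#' @return named list of rates.
#' @export
decay_rates <- function(sub = 0.002, indel = 2e-4, stop = 0) {
  stopifnot(sub >= 0, indel >= 0, stop >= 0)
  list(sub = sub, indel = indel, stop = stop)
}

#' Define an insertion scenario
#'
#' @param id scenario ID.
#' @param branch label of the tree node (tip or internal) below the
#'   branch on which insertion occurs; all species descending from it
#'   inherit the insertion.
#' @param region 0-based half-open interval of the viral genome
#'   inserted; NULL for the full genome.
#' @param tandem_copies number of head-to-tail copies (>= 1).
#' @param rates [decay_rates()].
#' @param time insertion time in My; defaults to the branch midpoint.
#' @param line NULL, or `list(node =, copies =, cassette_len =)`
#'   describing a LINE-mediated copy-number expansion in the lineage
#'   below `node`: each descendant species gains `copies` extra copies
#'   of the element, each preceded by the scenario's LINE cassette.
#' @return an `InsertionScenario` list.
#' @export
insertion_scenario <- function(id, branch, region = NULL,
                               tandem_copies = 1, rates = decay_rates(),
                               time = NULL, line = NULL) {
  stopifnot(tandem_copies >= 1)
  structure(list(id = id, branch = branch, region = region,
                 tandem_copies = as.integer(tandem_copies), rates = rates,
                 time = time, line = line),
            class = "InsertionScenario")
}

node_by_label <- function(timetree, label) {
  tips <- timetree$tree$tip.label
  at <- match(label, tips)
  if (!is.na(at)) return(at)
  at <- match(label, timetree$tree$node.label)
  if (is.na(at)) stop("no tree node labelled: ", label)
  length(tips) + at
}

node_leaves <- function(timetree, node) {
  ntip <- length(timetree$tree$tip.label)
  if (node <= ntip) return(timetree$tree$tip.label[node])
  ape::extract.clade(timetree$tree, node)$tip.label
}

parent_node <- function(tree, node) {
  e <- tree$edge
  at <- which(e[, 2] == node)
  if (length(at) == 0) return(NA_integer_)
  e[at, 1]
}

# Apply neutral decay to a sequence, tracking marked boundary positions
# (0-based). Substitutions follow a per-site Poisson process with
# uniform choice among the other three bases; indel lengths are
# geometric with mean 2 nt; stop gains rewrite a random in-frame viral
# codon to TAA within [stop_from, stop_to) at the given frame.
decay_seq <- function(seq, t, rates, marks = integer(0),
                      stop_from = NA, stop_to = NA) {
  L <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n_sub <- rpois(1, L * rates$sub * t)
  if (n_sub > 0) {
    at <- sample.int(L, n_sub, replace = TRUE)
    for (p in at) {
      v[p] <- sample(setdiff(bases, v[p]), 1)
    }
  }
  if (rates$stop > 0 && !is.na(stop_from)) {
    n_codon <- (stop_to - stop_from) %/% 3
    n_stop <- rpois(1, n_codon * rates$stop * t)
    if (n_stop > 0) {
      ci <- sample.int(n_codon, min(n_stop, n_codon))
      for (k in ci) {
        p <- stop_from + 3 * (k - 1)
        v[(p + 1):(p + 3)] <- c("T", "A", "A")
      }
    }
  }
  n_indel <- rpois(1, L * rates$indel * t)
  if (n_indel > 0) {
    for (q in seq_len(n_indel)) {
      Lc <- length(v)
      len <- rgeom(1, 0.5) + 1L
      pos <- sample.int(Lc, 1) # 1-based position of the event
      if (runif(1) < 0.5) { # insertion before pos
        v <- append(v, sample(bases, len, replace = TRUE), after = pos - 1)
        marks <- ifelse(marks >= pos, marks + len, marks)
      } else { # deletion of [pos, pos+len)
        len <- min(len, Lc - pos + 1)
        v <- v[-(pos:(pos + len - 1))]
        marks <- ifelse(marks >= pos + len - 1, marks - len,
                        ifelse(marks >= pos, pos - 1L, marks))
      }
    }
  }
  list(seq = paste(v, collapse = ""), marks = as.integer(marks))
}

#' Simulate host assemblies with planted insertions
#'
#' Each scenario's insertion is present in exactly the species
#' descending from its branch, at homologous positions with shared
#' (ancestral) flanking sequence; decay is applied independently per
#' descendant lineage in proportion to the time since insertion. Contig
#' lengths are drawn once per contig index and shared across species so
#' planted positions are homologous by construction.
#'
#' @param timetree a [host_timetree()].
#' @param scenarios list of [insertion_scenario()].
#' @param reference a [viral_reference()] (default: [synth_reference()]
#'   seeded from `seed`).
#' @param n_contigs contigs per species.
#' @param contig_len mean contig length (nt, >= 1 kb); lengths are drawn
#'   uniformly in ±25% of this.
#' @param gc background GC fraction.
#' @param ancestral_flank length of shared ancestral flank planted
#'   either side of each insertion (nt).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return list: `assemblies` (named list of [assembly()]), `truth`
#'   (data.frame: `species`, `contig`, `start`, `end`, `strand`,
#'   `scenario`, `duplicate`, `is_tandem`, `is_line_copy`), `reference`,
#'   `timetree`, `scenarios`.
#' @export
simulate_assembly <- function(timetree, scenarios, reference = NULL,
                              n_contigs = 2, contig_len = 20000,
                              gc = 0.41, ancestral_flank = 1500,
                              seed = 1) {
  stopifnot(length(timetree$tree$tip.label) >= 1, contig_len >= 1000)
  set.seed(seed)
  if (is.null(reference)) reference <- synth_reference(seed = seed)
  species <- timetree$tree$tip.label
  lens <- as.integer(round(runif(n_contigs, 0.75 * contig_len,
                                 1.25 * contig_len)))
  contigs <- list()
  for (sp in species) {
    contigs[[sp]] <- lapply(lens, function(L) random_dna(L, gc))
    names(contigs[[sp]]) <- sprintf("%s_ctg%d", sp, seq_len(n_contigs))
  }
  # plan insertions: one plan row per (scenario, species) plus LINE copies
  plans <- list() # each: species, contig index, pos, cassette parts
  for (sc in scenarios) {
    node <- node_by_label(timetree, sc$branch)
    desc <- node_leaves(timetree, node)
    parent <- parent_node(timetree$tree, node)
    t_child <- unname(timetree$ages[node])
    t_parent <- if (is.na(parent)) unname(max(timetree$ages)) else
      unname(timetree$ages[parent])
    t_ins <- sc$time %||% ((t_child + t_parent) / 2)
    region <- sc$region %||% c(0L, reference$genome_len)
    stopifnot(region[1] >= 0, region[2] <= reference$genome_len,
              region[2] > region[1])
    unit <- substring(reference$genome, region[1] + 1, region[2])
    insert <- paste(rep(unit, sc$tandem_copies), collapse = "")
    fU <- random_dna(ancestral_flank, gc)
    fD <- random_dna(ancestral_flank, gc)
    ci <- sample.int(n_contigs, 1)
    total_len <- 2 * ancestral_flank + nchar(insert)
    if (total_len >= lens[ci] - 2000) {
      stop("scenario ", sc$id, ": insertion (", total_len,
           " nt with flanks) too long for target contig of ", lens[ci],
           " nt")
    }
    pos <- sample(1000:(lens[ci] - total_len - 1000), 1)
    line_cassette <- if (!is.null(sc$line)) {
      random_dna(sc$line$cassette_len %||% 500, gc)
    } else NULL
    line_leaves <- if (!is.null(sc$line)) {
      node_leaves(timetree, node_by_label(timetree, sc$line$node))
    } else character(0)
    for (sp in desc) {
      # shared cassette decayed independently along each leaf lineage
      marks <- ancestral_flank +
        as.integer(nchar(unit)) * (0:sc$tandem_copies)
      dec <- decay_seq(paste0(fU, insert, fD), t_ins, sc$rates,
                       marks = marks,
                       stop_from = ancestral_flank,
                       stop_to = ancestral_flank + nchar(insert))
      plans[[length(plans) + 1L]] <- list(
        species = sp, ci = ci, pos = pos, seq = dec$seq,
        copy_bounds = dec$marks, scenario = sc$id,
        is_tandem = sc$tandem_copies > 1, is_line = FALSE)
      if (sp %in% line_leaves) {
        n_extra <- sc$line$copies %||% 3
        for (k in seq_len(n_extra)) {
          dec2 <- decay_seq(paste0(line_cassette, unit), t_ins / 2,
                            sc$rates,
                            marks = c(nchar(line_cassette),
                                      nchar(line_cassette) + nchar(unit)),
                            stop_from = nchar(line_cassette),
                            stop_to = nchar(line_cassette) + nchar(unit))
          cj <- sample.int(n_contigs, 1)
          pj <- sample(500:(lens[cj] - nchar(dec2$seq) - 500), 1)
          plans[[length(plans) + 1L]] <- list(
            species = sp, ci = cj, pos = pj, seq = dec2$seq,
            copy_bounds = dec2$marks, scenario = sc$id,
            is_tandem = FALSE, is_line = TRUE)
        }
      }
    }
  }
  # stitch insertions into contigs (ascending position, single pass per
  # contig) and emit truth records with final coordinates
  truth <- list()
  assemblies <- list()
  for (sp in species) {
    ctgs <- contigs[[sp]]
    mine <- Filter(function(p) p$species == sp, plans)
    for (ci in seq_len(n_contigs)) {
      here <- Filter(function(p) p$ci == ci, mine)
      if (length(here) == 0) next
      ord <- order(vapply(here, function(p) p$pos, numeric(1)))
      here <- here[ord]
      base <- ctgs[[ci]]
      out <- character(0)
      cursor <- 0L # consumed prefix of base contig
      shift <- 0L
      for (p in here) {
        out <- c(out, substring(base, cursor + 1, p$pos))
        ins_at <- p$pos + shift
        out <- c(out, p$seq)
        cursor <- p$pos
        # truth: one record per planted viral copy
        cb <- p$copy_bounds
        n_copies <- length(cb) - 1L
        for (k in seq_len(n_copies)) {
          truth[[length(truth) + 1L]] <- data.frame(
            species = sp, contig = names(ctgs)[ci],
            start = ins_at + cb[k], end = ins_at + cb[k + 1],
            strand = "+", scenario = p$scenario,
            duplicate = if (p$is_line) NA_integer_ else k,
            is_tandem = p$is_tandem, is_line_copy = p$is_line,
            stringsAsFactors = FALSE)
        }
        shift <- shift + nchar(p$seq)
      }
      out <- c(out, substring(base, cursor + 1))
      ctgs[[ci]] <- paste(out, collapse = "")
    }
    assemblies[[sp]] <- assembly(unlist(ctgs), name = paste0(sp, "_asm"),
                                 species = sp)
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(species = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               scenario = character(0), duplicate = integer(0),
               is_tandem = logical(0), is_line_copy = logical(0),
               stringsAsFactors = FALSE)
  # number LINE copies per (species, scenario)
  if (nrow(truth) > 0) {
    for (key in unique(paste(truth$species, truth$scenario))) {
      at <- which(paste(truth$species, truth$scenario) == key &
                    truth$is_line_copy)
      if (length(at) > 0) {
        truth$duplicate[at] <- max(0, truth$duplicate[
          paste(truth$species, truth$scenario) == key &
            !truth$is_line_copy], na.rm = TRUE) + seq_along(at)
      }
    }
  }
  rownames(truth) <- NULL
  list(assemblies = assemblies, truth = truth, reference = reference,
       timetree = timetree, scenarios = scenarios)
}

#' Fragment an assembly
#'
#' Splits contigs at random points and overwrites random segments with
#' N runs, emulating short contigs and undetermined flanking sequence.
#' Truth coordinates are remapped; a break inside a planted locus
#' yields one truth record per fragment, flagged with a `fragment`
#' index.
#'
#' @param sim output of [simulate_assembly()].
#' @param break_rate expected breaks per nt.
#' @param n_run_rate expected N runs per nt (runs of 60 nt).
#' @param seed RNG seed.
#' @param forced_breaks optional named list `contig -> positions` for
#'   deterministic breaks (applied in addition to random ones).
#' @return `sim` with fragmented assemblies and remapped truth (extra
#'   column `fragment`).
#' @export
fragment_assembly <- function(sim, break_rate = 0, n_run_rate = 0,
                              seed = 1, forced_breaks = NULL) {
  stopifnot(break_rate >= 0, n_run_rate >= 0)
  set.seed(seed)
  truth <- sim$truth
  truth$fragment <- 1L
  new_truth <- list()
  for (sp in names(sim$assemblies)) {
    asm <- sim$assemblies[[sp]]
    new_ctgs <- character(0)
    for (cn in names(asm$contigs)) {
      dna <- asm$contigs[[cn]]
      L <- nchar(dna)
      n_br <- rpois(1, L * break_rate)
      brk <- sort(unique(c(
        if (n_br > 0) sample.int(L - 1, min(n_br, L - 1)) else integer(0),
        as.integer(forced_breaks[[cn]] %||% integer(0)))))
      bounds <- c(0L, brk, L)
      n_nr <- rpois(1, L * n_run_rate)
      if (n_nr > 0) {
        v <- strsplit(dna, "")[[1]]
        for (q in seq_len(n_nr)) {
          p0 <- sample.int(max(1, L - 60), 1)
          v[p0:(p0 + 59)] <- "N"
        }
        dna <- paste(v, collapse = "")
      }
      pieces <- length(bounds) - 1L
      for (k in seq_len(pieces)) {
        s0 <- bounds[k]
        e0 <- bounds[k + 1]
        nm <- if (pieces == 1) cn else sprintf("%s_p%d", cn, k)
        new_ctgs[nm] <- substring(dna, s0 + 1, e0)
        here <- truth[truth$species == sp & truth$contig == cn &
                        truth$start < e0 & truth$end > s0, , drop = FALSE]
        if (nrow(here) > 0) {
          frag <- here
          frag$fragment <- ifelse(here$start >= s0 & here$end <= e0,
                                  here$fragment, here$fragment)
          split_flag <- !(here$start >= s0 & here$end <= e0)
          frag$contig <- nm
          frag$start <- pmax(here$start, s0) - s0
          frag$end <- pmin(here$end, e0) - s0
          frag$fragment <- ifelse(split_flag, k, 1L)
          new_truth[[length(new_truth) + 1L]] <- frag
        }
      }
    }
    sim$assemblies[[sp]] <- assembly(new_ctgs, name = asm$name,
                                     species = sp)
  }
  sim$truth <- if (length(new_truth) > 0) {
    out <- do.call(rbind, new_truth)
    rownames(out) <- NULL
    out
  } else {
    truth[0, , drop = FALSE]
  }
  sim
}

#' Write a truth table as BED
#'
#' BED name field is `scenario:duplicate`.
#'
#' @param truth truth table from [simulate_assembly()].
#' @param path output file.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$contig, start = truth$start,
                    end = truth$end,
                    name = paste0(truth$scenario, ":", truth$duplicate),
                    score = 0L, strand = truth$strand,
                    stringsAsFactors = FALSE)
  write_bed(bed, path)
}
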