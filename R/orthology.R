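# Orthology from genomic flanks: orthologous CVe insertions in different
# species share flanking host sequence. Flank comparison yields
# confirmed/potential/rejected edges; connected components are ortholog
# groups; conservative conventions turn groups into bounds on the number
# of germline incorporation events.

#' Orthology parameters
#'
#' Thresholds separating orthologous flanks (neutral host divergence)
#' from unrelated sequence. Confirmed orthology requires at least one
#' complete flank pair aligning at `flank_min_identity` percent over at
#' least `flank_min_len` nt; potential orthology requires locus-level
#' identity of `locus_min_identity` percent plus a shared reference
#' footprint when flank evidence is unavailable.
#'
#' @param flank_min_identity,flank_min_len flank thresholds.
#' @param locus_min_identity locus threshold for potential status.
#' @return named list of parameters.
#' @export
orthology_params <- function(flank_min_identity = 80, flank_min_len = 100,
                             locus_min_identity = 70) {
  list(flank_min_identity = flank_min_identity,
       flank_min_len = flank_min_len,
       locus_min_identity = locus_min_identity)
}

# global-with-free-end-gaps nucleotide alignment; percent identity over
# aligned columns and aligned length
overlap_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    return(c(identity = 0, aligned = 0))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  len <- Biostrings::nchar(aln)
  if (length(len) == 0 || len == 0) return(c(identity = 0, aligned = 0))
  c(identity = 100 * Biostrings::nmatch(aln) / len, aligned = len)
}

#' Compare two loci for orthology
#'
#' Aligns corresponding flanks (upstream to upstream, downstream to
#' downstream, in locus orientation) with free end gaps, plus the locus
#' sequences themselves. Status is `confirmed` with at least one
#' complete flank pair above thresholds, `potential` with sufficient
#' locus identity and a shared reference footprint but no usable flank
#' evidence, otherwise `rejected`. Two loci from the same species are
#' not orthology candidates (rejected; within-species merging handles
#' them).
#'
#' @param a,b single-row locus records carrying `species`, `locus_id`,
#'   `flank_up`, `flank_down`, `flank_up_complete`, `flank_down_complete`,
#'   `locus_seq`, and (after classification join) `gene`, `best_ref`.
#' @param params [orthology_params()].
#' @param same_region do the loci share a reference footprint? Computed
#'   from `gene` equality when NULL.
#' @return one-row data.frame edge: locus pair, `status`, flank and locus
#'   identities.
#' @export
compare_flanks <- function(a, b, params = orthology_params(),
                           same_region = NULL) {
  if (is.null(same_region)) {
    same_region <- isTRUE(a$gene == b$gene) ||
      (grepl("rep", a$gene) && grepl("rep", b$gene)) ||
      (grepl("cap", a$gene) && grepl("cap", b$gene))
  }
  up <- overlap_identity(a$flank_up, b$flank_up)
  dn <- overlap_identity(a$flank_down, b$flank_down)
  loc <- overlap_identity(a$locus_seq, b$locus_seq)
  up_complete <- isTRUE(a$flank_up_complete) && isTRUE(b$flank_up_complete)
  dn_complete <- isTRUE(a$flank_down_complete) && isTRUE(b$flank_down_complete)
  flank_pass <- function(v, complete) {
    complete && v["identity"] >= params$flank_min_identity &&
      v["aligned"] >= params$flank_min_len
  }
  # locus-level similarity only counts over a substantial alignment;
  # free-end-gap alignments of unrelated sequences find short perfect
  # overlaps by chance
  min_locus_aln <- max(params$flank_min_len,
                       0.5 * min(nchar(a$locus_seq), nchar(b$locus_seq)))
  status <- if (identical(a$species, b$species)) {
    "rejected"
  } else if (flank_pass(up, up_complete) || flank_pass(dn, dn_complete)) {
    "confirmed"
  } else if (same_region && loc["identity"] >= params$locus_min_identity &&
             loc["aligned"] >= min_locus_aln) {
    "potential"
  } else {
    "rejected"
  }
  data.frame(locus_a = a$locus_id, locus_b = b$locus_id, status = status,
             up_identity = unname(up["identity"]),
             up_aligned = unname(up["aligned"]),
             down_identity = unname(dn["identity"]),
             down_aligned = unname(dn["aligned"]),
             locus_identity = unname(loc["identity"]),
             stringsAsFactors = FALSE)
}

#' All pairwise orthology edges across species
#'
#' Computes [compare_flanks()] for every cross-species locus pair within
#' the same closest-reference cluster (same assigned gene class).
#'
#' @param loci locus table joined with classification columns.
#' @param params [orthology_params()].
#' @return edge table.
#' @export
orthology_edges <- function(loci, params = orthology_params()) {
  rows <- list()
  n <- nrow(loci)
  gene_sets <- strsplit(gsub("\\+", ",", loci$gene %||% loci$genes), ",")
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (identical(loci$species[i], loci$species[j])) next
      # only loci from the same reference cluster are candidates
      if (length(intersect(gene_sets[[i]], gene_sets[[j]])) == 0) next
      rows[[length(rows) + 1L]] <- compare_flanks(loci[i, ], loci[j, ],
                                                  params)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      status = character(0), up_identity = numeric(0),
                      up_aligned = numeric(0), down_identity = numeric(0),
                      down_aligned = numeric(0),
                      locus_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build ortholog groups from edges
#'
#' Groups are connected components over confirmed and potential edges.
#' A group is `confirmed` when its confirmed edges alone connect all
#' members, `potential` when it has no confirmed edge, `mixed`
#' otherwise; singletons are `single`. Group IDs are deterministic
#' (sorted member loci).
#'
#' @param edges [orthology_edges()] output.
#' @param loci locus table (all loci, including singletons).
#' @return data.frame: `group_id`, `status`, `n_loci`, `n_species`, plus
#'   list-columns `members`, `species`.
#' @export
build_groups <- function(edges, loci) {
  ids <- loci$locus_id
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  keep <- edges[edges$status %in% c("confirmed", "potential"), ,
                drop = FALSE]
  if (nrow(keep) > 0) {
    g <- igraph::add_edges(g, rbind(match(keep$locus_a, ids),
                                    match(keep$locus_b, ids)))
    g <- igraph::set_edge_attr(g, "status", value = keep$status)
  }
  comp <- igraph::components(g)
  conf <- keep[keep$status == "confirmed", , drop = FALSE]
  gc <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  gc <- igraph::set_vertex_attr(gc, "name", value = ids)
  if (nrow(conf) > 0) {
    gc <- igraph::add_edges(gc, rbind(match(conf$locus_a, ids),
                                      match(conf$locus_b, ids)))
  }
  comp_conf <- igraph::components(gc)
  rows <- list()
  for (k in seq_len(comp$no)) {
    members <- sort(ids[comp$membership == k])
    sp <- sort(unique(loci$species[match(members, ids)]))
    n_conf_edges <- if (nrow(conf) > 0) {
      sum(conf$locus_a %in% members | conf$locus_b %in% members)
    } else 0L
    status <- if (length(members) == 1) {
      "single"
    } else if (length(unique(comp_conf$membership[match(members, ids)])) == 1) {
      "confirmed"
    } else if (n_conf_edges > 0) {
      "mixed"
    } else {
      "potential"
    }
    row <- data.frame(status = status, n_loci = length(members),
                      n_species = length(sp), stringsAsFactors = FALSE)
    row$members <- I(list(members))
    row$species <- I(list(sp))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(vapply(out$members, `[`, character(1), 1)), ,
             drop = FALSE]
  out <- cbind(group_id = sprintf("G%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge within-species loci into element candidates
#'
#' Conservative within-species merging: loci on one contig within
#' `max_distance` whose reference footprints do not overlap are treated
#' as the fragmented remains of a single ancestrally acquired element.
#' Tandem arrays are one element: nearby same-gene loci with
#' near-identical footprints arranged in genomic series (the
#' interleaved plus/minus loci of a head-to-tail ambisense array, gaps
#' at most `tandem_gap`) also merge. Loci on different contigs with no
#' flank evidence remain separate candidates flagged ambiguous.
#'
#' @param loci locus table for one species with `contig`, `start`,
#'   `end`, `tandem`, and list-column `ref_intervals` (from the
#'   classification join); missing intervals are treated as
#'   non-overlapping.
#' @param max_distance merge radius (nt).
#' @param tandem_gap maximum genomic gap between series copies still
#'   treated as one tandem array (about one viral genome length).
#' @return data.frame: `element_id`, `n_loci`, `ambiguous`, list-column
#'   `members`.
#' @export
merge_within_species <- function(loci, max_distance = 10000,
                                 tandem_gap = 2500) {
  stopifnot(length(unique(loci$species)) <= 1)
  if (nrow(loci) == 0) {
    out <- data.frame(element_id = character(0), n_loci = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
    out$members <- I(list())
    return(out)
  }
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  grp <- seq_len(nrow(loci))
  has_iv <- "ref_intervals" %in% names(loci)
  footprints <- lapply(seq_len(nrow(loci)), function(i) {
    if (!has_iv || is.null(loci$ref_intervals[[i]])) return(NULL)
    loci$ref_intervals[[i]]
  })
  overlap_fp <- function(a, b) {
    if (is.null(a) || is.null(b)) return(FALSE)
    shared <- intersect(a$gene, b$gene)
    for (g in shared) {
      ia <- a[a$gene == g, ]
      ib <- b[b$gene == g, ]
      for (x in seq_len(nrow(ia))) for (y in seq_len(nrow(ib))) {
        if (min(ia$pend[x], ib$pend[y]) > max(ia$pstart[x], ib$pstart[y])) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  tandem_series <- function(i, j) {
    # same-footprint copies in close genomic series = tandem array
    a <- footprints[[i]]
    b <- footprints[[j]]
    if (is.null(a) || is.null(b)) return(FALSE)
    loci$start[j] - loci$end[i] <= tandem_gap ||
      loci$start[j] < loci$end[i] # interleaved strands overlap
  }
  for (i in seq_len(nrow(loci))[-1]) {
    prev <- i - 1L
    if (loci$contig[i] != loci$contig[prev]) next
    close_enough <- loci$start[i] - loci$end[prev] <= max_distance
    fp_clash <- overlap_fp(footprints[[i]], footprints[[prev]])
    if (close_enough && (!fp_clash || tandem_series(prev, i))) {
      grp[i] <- grp[prev]
    }
  }
  rows <- list()
  for (k in unique(grp)) {
    at <- which(grp == k)
    row <- data.frame(n_loci = length(at), stringsAsFactors = FALSE)
    row$members <- I(list(loci$locus_id[at]))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out <- cbind(element_id = sprintf("E%03d", seq_along(rows)), out,
               stringsAsFactors = FALSE)
  # with several surviving candidates the single-element hypothesis can
  # be neither confirmed nor ruled out
  out$ambiguous <- nrow(out) > 1
  rownames(out) <- NULL
  out
}

#' Element-level ortholog groups
#'
#' Collapses each species' loci into element candidates with
#' [merge_within_species()], lifts locus-level orthology edges to
#' element pairs (an element pair inherits the strongest status among
#' its member-pair edges), and returns connected components. This is
#' the unit at which germline incorporation events are counted: a
#' full-genome insertion whose rep and cap halves screen as separate
#' loci is one element, and its orthologs across species form one
#' group.
#'
#' @param loci classified locus table (all species).
#' @param edges [orthology_edges()] output.
#' @param max_distance within-species merge radius (nt).
#' @param statuses edge statuses used to connect elements (default
#'   confirmed only; add "potential" to pool unconfirmed links).
#' @return data.frame like [build_groups()] but over elements:
#'   `group_id`, `status`, `n_elements`, `n_species`, list-columns
#'   `members` (element keys `species|element_id`), `loci`, `species`.
#' @export
element_groups <- function(loci, edges, max_distance = 10000,
                           statuses = "confirmed") {
  elems <- list()
  for (sp in unique(loci$species)) {
    e <- merge_within_species(loci[loci$species == sp, , drop = FALSE],
                              max_distance = max_distance)
    e$species <- sp
    e$key <- paste(sp, e$element_id, sep = "|")
    elems[[sp]] <- e
  }
  elems <- do.call(rbind, elems)
  locus2elem <- setNames(rep(elems$key,
                             vapply(elems$members, length, integer(1))),
                         unlist(elems$members))
  keep <- edges[edges$status %in% statuses, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(elems), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = elems$key)
  if (nrow(keep) > 0) {
    ea <- unname(locus2elem[keep$locus_a])
    eb <- unname(locus2elem[keep$locus_b])
    ok <- !is.na(ea) & !is.na(eb) & ea != eb
    if (any(ok)) {
      g <- igraph::add_edges(g, rbind(match(ea[ok], elems$key),
                                      match(eb[ok], elems$key)))
    }
  }
  comp <- igraph::components(g)
  rows <- list()
  for (k in seq_len(comp$no)) {
    members <- sort(elems$key[comp$membership == k])
    sp <- sort(unique(elems$species[match(members, elems$key)]))
    lids <- sort(unlist(elems$members[match(members, elems$key)]))
    row <- data.frame(status = if (length(members) > 1) "confirmed"
                        else "single",
                      n_elements = length(members),
                      n_species = length(sp), stringsAsFactors = FALSE)
    row$members <- I(list(members))
    row$loci <- I(list(lids))
    row$species <- I(list(sp))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(vapply(out$members, `[`, character(1), 1)), ,
             drop = FALSE]
  out <- cbind(group_id = sprintf("EG%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count germline incorporation events
#'
#' Conservative event counting over CVe groups. Each group contributes
#' one event by default. Conventions are directives over clade labels:
#' `collapse` pools all groups of a clade into one event in the minimum
#' bound (e.g. treating all ray-finned-fish CVe as one ancestral
#' integration); `exclude-tentative` drops tentative groups from the
#' minimum; `split` lets each group in a clade contribute its `n_units`
#' alternative subdivision in the maximum bound.
#'
#' @param groups data.frame with `group_id`, `clade`, and optionally
#'   `tentative` (logical) and `n_units` (integer, default 1).
#' @param conventions data.frame with `clade`, `action` in
#'   `c("collapse", "split", "exclude-tentative")`.
#' @return list: `min_events`, `max_events`, `table` (per-group
#'   contributions), `conventions`.
#' @export
count_events <- function(groups, conventions = NULL) {
  if (is.null(conventions) || nrow(conventions) == 0) {
    conventions <- data.frame(clade = character(0), action = character(0),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(conventions$action %in%
                  c("collapse", "split", "exclude-tentative")))
  unknown <- setdiff(conventions$clade, groups$clade)
  if (length(unknown) > 0) {
    stop("convention names unknown clade: ", paste(unknown, collapse = ", "))
  }
  tentative <- if ("tentative" %in% names(groups)) groups$tentative else
    rep(FALSE, nrow(groups))
  n_units <- if ("n_units" %in% names(groups)) groups$n_units else
    rep(1L, nrow(groups))
  collapse_clades <- conventions$clade[conventions$action == "collapse"]
  split_clades <- conventions$clade[conventions$action == "split"]
  excl_clades <- conventions$clade[conventions$action == "exclude-tentative"]
  min_contrib <- numeric(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    if (tentative[i] && groups$clade[i] %in% excl_clades) {
      min_contrib[i] <- 0
    } else if (groups$clade[i] %in% collapse_clades) {
      # all groups of a collapsed clade share one event
      first <- which(groups$clade == groups$clade[i] &
                       !(tentative & groups$clade %in% excl_clades))[1]
      min_contrib[i] <- if (i == first) 1 else 0
    } else {
      min_contrib[i] <- 1
    }
  }
  max_contrib <- ifelse(groups$clade %in% split_clades, n_units, 1L)
  tab <- data.frame(group_id = groups$group_id, clade = groups$clade,
                    tentative = tentative, min_contribution = min_contrib,
                    max_contribution = max_contrib,
                    stringsAsFactors = FALSE)
  list(min_events = as.integer(sum(min_contrib)),
       max_events = as.integer(sum(max_contrib)), table = tab,
       conventions = conventions)
}
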