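# Copy-number expansion analysis: pairwise distances among duplicate
# loci, neighbor-joining clustering, detection of within-lineage
# expansions on the midpoint-rooted tree, and an exact test of
# association between expanded copies and flanking repeat annotations
# (LINE-1 style).

#' Pairwise p-distance matrix
#'
#' Proportion of differing positions over columns where both sequences
#' are ungapped, on pre-aligned nucleotide or amino-acid sequences.
#' Pairs sharing fewer than `min_coverage` of alignment columns are
#' flagged unreliable (distance NA).
#'
#' @param seqs named character vector of aligned sequences (equal
#'   length; `-` for gaps).
#' @param min_coverage minimum shared ungapped fraction.
#' @return list: `d` (symmetric matrix, zero diagonal), `unreliable`
#'   (logical matrix).
#' @export
p_distance_matrix <- function(seqs, min_coverage = 0.5) {
  stopifnot(length(seqs) >= 2, length(unique(nchar(seqs))) == 1)
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- nchar(seqs[[1]])
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  unrel <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]
    b <- chars[[j]]
    ok <- a != "-" & b != "-"
    if (sum(ok) < min_coverage * L) {
      d[i, j] <- d[j, i] <- NA_real_
      unrel[i, j] <- unrel[j, i] <- TRUE
    } else {
      d[i, j] <- d[j, i] <- mean(a[ok] != b[ok])
    }
  }
  list(d = d, unreliable = unrel)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Saitou-Nei, as implemented in ape). On an
#' additive distance matrix the returned tree reproduces the matrix
#' path lengths exactly.
#'
#' @param d symmetric distance matrix (>= 3 taxa, finite entries).
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  stopifnot(nrow(d) >= 3)
  if (any(!is.finite(d))) stop("non-finite distances in matrix")
  ape::nj(stats::as.dist(d))
}

#' Detect within-lineage copy-number expansions
#'
#' Midpoint-roots the duplicate tree and reports maximal monophyletic
#' sets of leaves that all belong to one host lineage and reach
#' `min_size` members.
#'
#' @param tree `phylo` over duplicate loci.
#' @param lineage named character vector: leaf -> lineage label.
#' @param min_size smallest clade size called an expansion.
#' @return data.frame: `expansion_id`, `lineage`, `size`, list-column
#'   `members`; zero rows when no clade qualifies.
#' @export
detect_expansions <- function(tree, lineage, min_size = 3) {
  stopifnot(all(tree$tip.label %in% names(lineage)))
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  clades <- list()
  for (node in (ntip + 1):(ntip + rooted$Nnode)) {
    leaves <- ape::extract.clade(rooted, node)$tip.label
    lin <- unique(lineage[leaves])
    if (length(lin) == 1 && length(leaves) >= min_size) {
      clades[[length(clades) + 1L]] <- list(node = node, leaves = leaves,
                                            lineage = lin)
    }
  }
  # keep maximal clades only
  keep <- rep(TRUE, length(clades))
  for (i in seq_along(clades)) for (j in seq_along(clades)) {
    if (i != j && keep[i] &&
        all(clades[[i]]$leaves %in% clades[[j]]$leaves) &&
        length(clades[[j]]$leaves) > length(clades[[i]]$leaves)) {
      keep[i] <- FALSE
    }
  }
  clades <- clades[keep]
  if (length(clades) == 0) {
    out <- data.frame(expansion_id = character(0), lineage = character(0),
                      size = integer(0), stringsAsFactors = FALSE)
    out$members <- I(list())
    return(out)
  }
  ord <- order(vapply(clades, function(x) sort(x$leaves)[1], character(1)))
  clades <- clades[ord]
  out <- data.frame(
    expansion_id = sprintf("X%02d", seq_along(clades)),
    lineage = vapply(clades, function(x) x$lineage, character(1)),
    size = vapply(clades, function(x) length(x$leaves), integer(1)),
    stringsAsFactors = FALSE)
  out$members <- I(lapply(clades, function(x) sort(x$leaves)))
  out
}

#' Exact two-sided test for a 2x2 table
#'
#' Fisher's exact test by full hypergeometric enumeration (two-sided by
#' the probability method: the p-value sums all tables with the given
#' margins whose probability does not exceed the observed table's).
#' Odds ratio is the sample odds ratio, with the Haldane 0.5 correction
#' when any cell is zero.
#'
#' @param a,b,c,d cell counts: rows = expansion / non-expansion,
#'   columns = repeat-adjacent / not.
#' @return list: `p`, `odds_ratio`, `table`.
#' @export
exact_2x2_test <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  N <- r1 + r2
  if (N == 0) stop("empty table")
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  ks <- lo:hi
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1)
  p_obs <- logp[ks == a]
  p <- sum(exp(logp[logp <= p_obs + 1e-7]))
  p <- min(1, p)
  or <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p = p, odds_ratio = or,
       table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                      dimnames = list(c("expansion", "other"),
                                      c("repeat_adjacent", "clean"))))
}

#' Association between expansion membership and flanking repeats
#'
#' A locus is repeat-adjacent when any repeat interval overlaps a
#' window of `window` nt either side of it (same contig). Builds the
#' 2x2 expansion-by-adjacency table and applies [exact_2x2_test()].
#'
#' @param loci locus table with `locus_id`, `contig`, `start`, `end`.
#' @param expansion_members character vector of locus IDs belonging to
#'   expansions.
#' @param repeats repeat annotations as a BED-style data.frame
#'   (`chrom`, `start`, `end`).
#' @param window flank window (nt) on each side.
#' @return [exact_2x2_test()] result plus `window` and per-locus
#'   adjacency, or a list with `defined = FALSE` when the repeat track
#'   is empty.
#' @export
repeat_association <- function(loci, expansion_members, repeats,
                               window = 500) {
  if (is.null(repeats) || nrow(repeats) == 0) {
    return(list(defined = FALSE,
                reason = "empty repeat track: association undefined"))
  }
  win <- IRanges::IRanges(pmax(0L, loci$start - window) + 1L,
                          loci$end + window)
  adjacent <- logical(nrow(loci))
  for (ctg in unique(loci$contig)) {
    at <- which(loci$contig == ctg)
    rp <- repeats[repeats$chrom == ctg, , drop = FALSE]
    if (nrow(rp) == 0) next
    ov <- IRanges::countOverlaps(win[at],
                                 IRanges::IRanges(rp$start + 1L, rp$end))
    adjacent[at] <- ov > 0
  }
  in_exp <- loci$locus_id %in% expansion_members
  a <- sum(in_exp & adjacent)
  b <- sum(in_exp & !adjacent)
  c <- sum(!in_exp & adjacent)
  d <- sum(!in_exp & !adjacent)
  res <- exact_2x2_test(a, b, c, d)
  res$defined <- TRUE
  res$window <- window
  res$adjacent <- setNames(adjacent, loci$locus_id)
  res
}
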