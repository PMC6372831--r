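# Insertion-age calibration on a host timetree. Orthologous copies in
# distinct host lineages place the insertion before their divergence
# (minimum age); documented absence from a screened sister lineage
# places it after that divergence (maximum age). Ages are read from the
# provided timetree, never estimated from sequence divergence.

tree_node_of <- function(timetree, species_set) {
  tips <- timetree$tree$tip.label
  missing <- setdiff(species_set, tips)
  if (length(missing) > 0) {
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  }
  if (length(species_set) == 1) return(match(species_set, tips))
  ape::getMRCA(timetree$tree, species_set)
}

node_age_range <- function(timetree, node) {
  age <- timetree$ages[node]
  lo <- hi <- age
  ntip <- length(timetree$tree$tip.label)
  if (!is.null(timetree$age_ranges) && node > ntip) {
    lab <- timetree$tree$node.label[node - ntip]
    at <- match(lab, timetree$age_ranges$node)
    if (!is.na(at)) {
      lo <- timetree$age_ranges$lo[at]
      hi <- timetree$age_ranges$hi[at]
    }
  }
  c(age = unname(age), lo = unname(lo), hi = unname(hi))
}

#' Minimum insertion age of an ortholog group
#'
#' The age of the most recent common ancestor of the group's species; a
#' single-species group has minimum age 0.
#'
#' @param species_set species carrying orthologous copies.
#' @param timetree a [host_timetree()].
#' @return named numeric: `age`, `lo`, `hi` (point value and published
#'   range where one is recorded for the node), in My.
#' @export
min_age <- function(species_set, timetree) {
  species_set <- unique(species_set)
  if (length(species_set) == 1) return(c(age = 0, lo = 0, hi = 0))
  node <- tree_node_of(timetree, species_set)
  node_age_range(timetree, node)
}

#' Maximum insertion age from documented absence
#'
#' The age of the shallowest node separating a group member from a
#' screened species lacking the element. Absence is only informative for
#' species whose assemblies were screened.
#'
#' @param species_set species carrying the element.
#' @param timetree a [host_timetree()].
#' @param screened species whose assemblies were screened.
#' @param carriers all species carrying any copy of the element
#'   (defaults to `species_set`).
#' @return named numeric as [min_age()], or NULL when no screened
#'   negative relative exists.
#' @export
max_age <- function(species_set, timetree, screened,
                    carriers = species_set) {
  negatives <- setdiff(screened, carriers)
  negatives <- intersect(negatives, timetree$tree$tip.label)
  if (length(negatives) == 0) return(NULL)
  lower <- min_age(species_set, timetree)["age"]
  ages <- vapply(negatives, function(s) {
    unname(timetree$ages[tree_node_of(timetree, c(species_set, s))])
  }, numeric(1))
  names(ages) <- negatives
  ages <- ages[ages >= lower]
  if (length(ages) == 0) return(NULL)
  node <- tree_node_of(timetree,
                       c(species_set, names(ages)[which.min(ages)]))
  node_age_range(timetree, node)
}

#' Age estimates for ortholog groups
#'
#' @param groups [build_groups()] output (list-column `species`).
#' @param timetree a [host_timetree()].
#' @param screened species whose assemblies were screened (absence is
#'   informative only for these); defaults to all tree species.
#' @return data.frame: `group_id`, `min_age`, `min_lo`, `min_hi`,
#'   `max_age`, `max_lo`, `max_hi`, `basis` in
#'   `c("confirmed", "potential", "none")`.
#' @export
age_estimates <- function(groups, timetree,
                          screened = timetree$tree$tip.label) {
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sp <- groups$species[[i]]
    basis <- switch(groups$status[i],
                    confirmed = "confirmed",
                    mixed = "potential",
                    potential = "potential",
                    single = "none")
    mn <- min_age(sp, timetree)
    mx <- max_age(sp, timetree, screened)
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = groups$group_id[i], min_age = mn["age"],
      min_lo = mn["lo"], min_hi = mn["hi"],
      max_age = if (is.null(mx)) NA_real_ else mx["age"],
      max_lo = if (is.null(mx)) NA_real_ else mx["lo"],
      max_hi = if (is.null(mx)) NA_real_ else mx["hi"],
      basis = basis, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Timeline of CVe evolution
#'
#' Orders age estimates oldest first and assigns display categories:
#' `confirmed` (dated via confirmed orthologs), `potential` (dated via
#' potential orthologs only), `undated` (single-species presence).
#'
#' @param estimates [age_estimates()] output.
#' @return the estimates, sorted by `min_age` descending, with a
#'   `category` column.
#' @export
cve_timeline <- function(estimates) {
  stopifnot(nrow(estimates) >= 1)
  estimates$category <- c(confirmed = "confirmed", potential = "potential",
                          none = "undated")[estimates$basis]
  out <- estimates[order(-estimates$min_age, estimates$group_id), ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}
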