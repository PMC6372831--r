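# End-to-end orchestration over flat files: simulate (optional) ->
# screen -> classify -> orf -> orthology -> events -> date -> catalog
# -> expansions/repeats, with a run manifest recording resolved
# parameters and per-stage counts. Stage outputs are plain TSV/BED/
# GFF3/JSON so every stage is individually re-runnable.

default_config <- function() {
  list(seed = 1L,
       out_dir = "circomine_run",
       simulate = list(enabled = TRUE, n_contigs = 2L,
                       contig_len = 20000L, gc = 0.41,
                       scenarios = list()),
       tree = NULL,            # newick path, or NULL to require simulate
       assemblies = NULL,      # named FASTA paths (species -> path)
       screen = screen_params(),
       orf = orf_params(),
       orthology = orthology_params(),
       conventions = NULL,     # data.frame(clade, action) or TSV path
       repeats = NULL,         # BED path for repeat annotations
       expansion_min_size = 3L)
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  merged <- base
  for (k in names(config)) {
    if (k %in% c("simulate", "screen", "orf", "orthology")) {
      unknown2 <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(unknown2) > 0) {
        stop("unknown config keys: ",
             paste(paste0(k, "$", unknown2), collapse = ", "))
      }
      sub <- base[[k]]
      for (k2 in names(config[[k]])) sub[[k2]] <- config[[k]][[k2]]
      merged[[k]] <- sub
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  if (!isTRUE(merged$simulate$enabled) && is.null(merged$assemblies)) {
    stop("config needs either simulate$enabled or assemblies")
  }
  if (!isTRUE(merged$simulate$enabled) && is.null(merged$tree)) {
    stop("dating requires a tree when not simulating")
  }
  merged
}

write_tsv <- function(df, path) {
  flat <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full CVe pipeline
#'
#' Executes every stage over a configuration list (see the vignette for
#' the schema), writing stage outputs and a JSON manifest into
#' `out_dir`. Reruns with the same config and inputs are byte-identical
#' apart from the manifest timestamp. A stage failure halts the run,
#' names the failing stage, and leaves a `FAILED` marker next to the
#' partial outputs.
#'
#' @param config configuration list (unknown keys rejected); or a YAML
#'   file path.
#' @return invisibly, a list with the main stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  result <- tryCatch({
    set.seed(cfg$seed)
    # --- inputs -----------------------------------------------------
    stage <- "simulate"
    if (isTRUE(cfg$simulate$enabled)) {
      tt <- if (is.null(cfg$tree)) {
        host_timetree(ape::rcoal(4, tip.label = sprintf("sp%02d", 1:4),
                                 br = "coalescent"))
      } else read_newick_with_ages(cfg$tree)
      scens <- cfg$simulate$scenarios
      if (length(scens) == 0) {
        scens <- list(insertion_scenario("S1",
                                         tt$tree$tip.label[1]))
      }
      sim <- simulate_assembly(tt, scens,
                               n_contigs = cfg$simulate$n_contigs,
                               contig_len = cfg$simulate$contig_len,
                               gc = cfg$simulate$gc, seed = cfg$seed)
      assemblies <- sim$assemblies
      refs <- list(sim$reference)
      for (sp in names(assemblies)) {
        write_fasta(assemblies[[sp]],
                    file.path(cfg$out_dir, paste0(sp, ".fa")))
      }
      write_truth_bed(sim$truth, file.path(cfg$out_dir, "truth.bed"))
      timetree <- tt
    } else {
      timetree <- read_newick_with_ages(cfg$tree)
      assemblies <- lapply(names(cfg$assemblies), function(sp) {
        read_fasta(cfg$assemblies[[sp]], species = sp)
      })
      names(assemblies) <- names(cfg$assemblies)
      refs <- list(synth_reference(seed = cfg$seed))
    }
    probes <- probes_from_references(refs)
    counts$species <- length(assemblies)
    counts$probes <- nrow(probes)
    # --- screening + classification --------------------------------
    stage <- "screen"
    loci <- do.call(rbind, lapply(assemblies, function(a) {
      screen_assembly(a, probes, cfg$screen)
    }))
    if (is.null(loci)) loci <- data.frame()
    counts$loci <- nrow(loci)
    write_tsv(loci, file.path(cfg$out_dir, "loci.tsv"))
    if (nrow(loci) > 0) {
      bed <- data.frame(chrom = loci$contig, start = loci$start,
                        end = loci$end, name = loci$locus_id, score = 0L,
                        strand = loci$strand, stringsAsFactors = FALSE)
      write_gff3(bed_to_gff3(bed), file.path(cfg$out_dir, "loci.gff3"))
    }
    stage <- "classify"
    cls <- if (nrow(loci) > 0) classify_loci(loci, refs, cfg$screen) else
      data.frame()
    write_tsv(cls, file.path(cfg$out_dir, "classification.tsv"))
    stage <- "orf"
    orf <- if (nrow(loci) > 0) orf_report(loci, cls, refs, cfg$orf) else
      data.frame()
    counts$intact_orfs <- sum(orf$intact %||% logical(0))
    write_tsv(orf, file.path(cfg$out_dir, "orf_report.tsv"))
    # --- orthology, events, dating ----------------------------------
    stage <- "orthology"
    merged <- if (nrow(loci) > 0) {
      merge(loci, cls[, c("locus_id", "gene", "best_ref")],
            by = "locus_id", suffixes = c("", ".cls"))
    } else loci
    if (nrow(loci) > 0 && "gene.cls" %in% names(merged)) {
      merged$gene <- merged$gene.cls
      merged$gene.cls <- NULL
    }
    edges <- if (nrow(loci) > 1) orthology_edges(merged, cfg$orthology)
      else data.frame()
    groups <- if (nrow(loci) > 0) build_groups(edges, merged) else
      data.frame()
    counts$groups <- nrow(groups)
    write_tsv(edges, file.path(cfg$out_dir, "orthology_edges.tsv"))
    write_tsv(groups, file.path(cfg$out_dir, "groups.tsv"))
    stage <- "events"
    conventions <- cfg$conventions
    if (is.character(conventions)) {
      conventions <- utils::read.table(conventions, sep = "\t",
                                       header = TRUE,
                                       stringsAsFactors = FALSE)
    }
    # events are counted over element-level groups: within-species
    # fragments and tandem arrays are one element, confirmed orthologs
    # across species one event
    egroups <- if (nrow(loci) > 0) element_groups(merged, edges) else
      data.frame()
    events <- if (nrow(egroups) > 0) {
      gr <- egroups
      gr$clade <- "all"
      count_events(gr, if (!is.null(conventions) &&
                             all(conventions$clade %in% gr$clade))
                         conventions else NULL)
    } else list(min_events = 0L, max_events = 0L)
    counts$min_events <- events$min_events
    counts$max_events <- events$max_events
    jsonlite::write_json(events[c("min_events", "max_events")],
                         file.path(cfg$out_dir, "events.json"),
                         auto_unbox = TRUE)
    stage <- "date"
    ages <- if (nrow(groups) > 0) {
      est <- age_estimates(groups, timetree)
      cve_timeline(est)
    } else data.frame()
    write_tsv(ages, file.path(cfg$out_dir, "timeline.tsv"))
    # --- catalog ----------------------------------------------------
    stage <- "catalog"
    catalog <- if (nrow(loci) > 0) {
      cat0 <- merged
      cat0$group <- "Synthetic"
      gid <- setNames(groups$group_id,
                      vapply(groups$members, `[`, character(1), 1))
      memb <- setNames(rep(groups$group_id,
                           vapply(groups$members, length, integer(1))),
                       unlist(groups$members))
      cat0$insertion <- unname(memb[cat0$locus_id])
      assign_ids(cat0)
    } else data.frame()
    export_catalog(catalog, file.path(cfg$out_dir, "catalog"))
    # --- manifest ---------------------------------------------------
    stage <- "manifest"
    manifest <- list(package_version = as.character(
                       utils::packageVersion("circomine")),
                     seed = cfg$seed,
                     params = cfg[c("screen", "orf", "orthology",
                                    "expansion_min_size")],
                     counts = counts)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(loci = loci, classification = cls, orf = orf, edges = edges,
         groups = groups, events = events, timeline = ages,
         catalog = catalog, counts = counts)
  }, error = on_fail)
  invisible(result)
}
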