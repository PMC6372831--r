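# Flank-based orthology, grouping, within-species merging, event counts.

mk_locus <- function(id, species, up, down, seq, up_ok = TRUE,
                     dn_ok = TRUE, gene = "rep", contig = "c1",
                     start = 0L, end = 100L) {
  out <- data.frame(locus_id = id, species = species, contig = contig,
                    start = start, end = end, strand = "+",
                    tandem = FALSE, flank_up = up, flank_down = down,
                    flank_up_complete = up_ok, flank_down_complete = dn_ok,
                    locus_seq = seq, gene = gene,
                    stringsAsFactors = FALSE)
  out
}

test_that("identical complete flanks confirm orthology; symmetry holds", {
  set.seed(3)
  up <- circomine:::random_dna(1000)
  dn <- circomine:::random_dna(1000)
  seq <- circomine:::random_dna(900)
  a <- mk_locus("A.L1", "A", up, dn, seq)
  b <- mk_locus("B.L1", "B", up, dn, seq)
  e1 <- compare_flanks(a, b)
  e2 <- compare_flanks(b, a)
  expect_identical(e1$status, "confirmed")
  expect_identical(e1$status, e2$status)
})

test_that("flank-incomplete similar loci are potential, never confirmed", {
  set.seed(4)
  seq <- circomine:::random_dna(900)
  seq2 <- seq
  # ~15% divergence
  at <- sample(nchar(seq), 135)
  for (p in at) substr(seq2, p, p) <- sample(setdiff(c("A","C","G","T"),
                                              substr(seq2, p, p)), 1)
  a <- mk_locus("A.L1", "A", "", "", seq, up_ok = FALSE, dn_ok = FALSE)
  b <- mk_locus("B.L1", "B", "", "", seq2, up_ok = FALSE, dn_ok = FALSE)
  e <- compare_flanks(a, b)
  expect_identical(e$status, "potential")
  expect_gte(e$locus_identity, 70)
})

test_that("unrelated loci with random flanks are rejected", {
  set.seed(5)
  for (q in 1:10) {
    a <- mk_locus("A.L1", "A", circomine:::random_dna(1000),
                  circomine:::random_dna(1000),
                  circomine:::random_dna(900))
    b <- mk_locus("B.L1", "B", circomine:::random_dna(1000),
                  circomine:::random_dna(1000),
                  circomine:::random_dna(900))
    e <- compare_flanks(a, b)
    expect_identical(e$status, "rejected")
  }
})

test_that("same-species pairs are rejected as orthology candidates", {
  set.seed(6)
  up <- circomine:::random_dna(1000)
  a <- mk_locus("A.L1", "A", up, up, circomine:::random_dna(900))
  b <- mk_locus("A.L2", "A", up, up, a$locus_seq)
  expect_identical(compare_flanks(a, b)$status, "rejected")
})

test_that("groups are connected components with correct status labels", {
  loci <- rbind(mk_locus("A.L1", "A", "", "", "ACGT"),
                mk_locus("B.L1", "B", "", "", "ACGT"),
                mk_locus("C.L1", "C", "", "", "ACGT"),
                mk_locus("D.L1", "D", "", "", "ACGT"),
                mk_locus("E.L1", "E", "", "", "ACGT"))
  edge <- function(a, b, st) data.frame(locus_a = a, locus_b = b,
                                        status = st,
                                        stringsAsFactors = FALSE)
  # chain: A-B confirmed, B-C potential -> one mixed group
  gr <- build_groups(rbind(edge("A.L1", "B.L1", "confirmed"),
                           edge("B.L1", "C.L1", "potential")), loci)
  expect_equal(nrow(gr), 3) # {A,B,C}, {D}, {E}
  big <- gr[gr$n_loci == 3, ]
  expect_identical(big$status, "mixed")
  expect_identical(gr$status[gr$n_loci == 1], c("single", "single"))
  # no edges -> all singletons
  gr0 <- build_groups(edge(character(0), character(0), character(0)),
                      loci)
  expect_equal(nrow(gr0), 5)
})

test_that("within-species merging is conservative", {
  # rep fragment + cap fragment 3 kb apart -> one element
  a <- mk_locus("A.L1", "A", "", "", "ACGT", contig = "c1",
                start = 1000L, end = 1500L, gene = "rep")
  b <- mk_locus("A.L2", "A", "", "", "ACGT", contig = "c1",
                start = 4500L, end = 5200L, gene = "cap")
  a$ref_intervals <- I(list(data.frame(gene = "rep", ref = "r",
                                       pstart = 0L, pend = 150L)))
  b$ref_intervals <- I(list(data.frame(gene = "cap", ref = "r",
                                       pstart = 0L, pend = 200L)))
  el <- merge_within_species(rbind(a, b))
  expect_equal(nrow(el), 1)
  expect_setequal(el$members[[1]], c("A.L1", "A.L2"))

  # same footprint far apart on different contigs -> two ambiguous
  b2 <- a
  b2$locus_id <- "A.L2"
  b2$contig <- "c2"
  el2 <- merge_within_species(rbind(a, b2))
  expect_equal(nrow(el2), 2)
  expect_true(all(el2$ambiguous))

  # tandem series: same footprint, adjacent -> one element
  b3 <- a
  b3$locus_id <- "A.L2"
  b3$start <- 1600L
  b3$end <- 2100L
  el3 <- merge_within_species(rbind(a, b3))
  expect_equal(nrow(el3), 1)
})

test_that("event counting reproduces the published 19-26 bounds", {
  groups <- load_group_catalog()
  groups$group_id <- groups$group
  conv_min <- data.frame(clade = c("Fish", "Agnatha"),
                         action = c("collapse", "exclude-tentative"),
                         stringsAsFactors = FALSE)
  ev <- count_events(groups, conv_min)
  expect_equal(ev$min_events, 19L)
  expect_equal(ev$max_events, 26L)
})

test_that("event counting basics and monotonicity", {
  gr <- data.frame(group_id = c("g1", "g2", "g3"),
                   clade = c("x", "x", "y"),
                   tentative = c(FALSE, FALSE, TRUE),
                   n_units = c(2L, 3L, 1L), stringsAsFactors = FALSE)
  ev0 <- count_events(gr[1, ], NULL)
  expect_equal(ev0$min_events, 1L)
  expect_equal(ev0$max_events, 1L)
  ev1 <- count_events(gr, NULL)
  ev2 <- count_events(gr, data.frame(clade = "x", action = "collapse"))
  expect_lte(ev2$min_events, ev1$min_events)
  ev3 <- count_events(gr, data.frame(clade = "x", action = "split"))
  expect_gte(ev3$max_events, ev1$max_events)
  expect_error(count_events(gr, data.frame(clade = "zz",
                                           action = "collapse")),
               "unknown clade")
})

test_that("confirmed orthologs across two species count one event", {
  loci <- rbind(mk_locus("A.L1", "A", "", "", "ACGT"),
                mk_locus("B.L1", "B", "", "", "ACGT"))
  edges <- data.frame(locus_a = "A.L1", locus_b = "B.L1",
                      status = "confirmed", stringsAsFactors = FALSE)
  gr <- build_groups(edges, loci)
  gr$clade <- "all"
  ev <- count_events(gr, NULL)
  expect_equal(c(ev$min_events, ev$max_events), c(1L, 1L))
})

test_that("simulated clade insertions recover their ortholog group", {
  tt <- read_newick_with_ages(
    "(((A:10,B:10)ab:10,C:20)abc:10,(D:25,E:25)de:5)root;")
  sim <- simulate_assembly(
    tt, list(insertion_scenario("S1", "abc",
                                rates = decay_rates(sub = 0.0015,
                                                    indel = 1e-5))),
    contig_len = 12000, seed = 101)
  probes <- probes_from_references(list(sim$reference))
  loci <- do.call(rbind, lapply(sim$assemblies, screen_assembly,
                                probes = probes))
  cls <- classify_loci(loci, list(sim$reference))
  merged <- merge(loci, cls[, c("locus_id", "gene", "best_ref",
                                "ref_intervals")], by = "locus_id")
  merged$gene <- merged$gene.y
  edges <- orthology_edges(merged)
  eg <- element_groups(merged, edges)
  multi <- eg[eg$n_species > 1, ]
  expect_equal(nrow(multi), 1)
  expect_setequal(multi$species[[1]], c("A", "B", "C"))
  expect_identical(multi$status, "confirmed")
})
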