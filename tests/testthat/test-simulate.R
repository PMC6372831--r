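# The synthetic-data generator: determinism, inheritance, decay
# calibration, fragmentation.

test_that("identical seeds give byte-identical assemblies and truth", {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sc <- list(insertion_scenario("S1", "ab"))
  s1 <- simulate_assembly(tt, sc, seed = 5)
  s2 <- simulate_assembly(tt, sc, seed = 5)
  expect_identical(lapply(s1$assemblies, `[[`, "contigs"),
                   lapply(s2$assemblies, `[[`, "contigs"))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_assembly(tt, sc, seed = 6)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("insertions are inherited by exactly the descendant species", {
  tt <- read_newick_with_ages("(((A:5,B:5)ab:5,C:10)abc:10,D:20)r;")
  # indel-free decay so homologous coordinates are position-identical
  nosub <- decay_rates(sub = 0.001, indel = 0)
  sc <- list(insertion_scenario("root_ins", "r", rates = nosub),
             insertion_scenario("ab_ins", "ab", rates = nosub),
             insertion_scenario("c_ins", "C", rates = nosub))
  sim <- simulate_assembly(tt, sc, seed = 7)
  tr <- sim$truth
  expect_setequal(tr$species[tr$scenario == "root_ins"],
                  c("A", "B", "C", "D"))
  expect_setequal(tr$species[tr$scenario == "ab_ins"], c("A", "B"))
  expect_setequal(tr$species[tr$scenario == "c_ins"], "C")
  # orthology by construction: species share a scenario iff they
  # descend from its branch, at homologous coordinates
  ab <- tr[tr$scenario == "ab_ins", ]
  expect_equal(length(unique(ab$start)), 1)
})

test_that("zero decay leaves sister copies bit-identical", {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sc <- list(insertion_scenario("S1", "ab",
                                rates = decay_rates(sub = 0, indel = 0)))
  sim <- simulate_assembly(tt, sc, seed = 8)
  tr <- sim$truth
  seqs <- vapply(c("A", "B"), function(sp) {
    r <- tr[tr$species == sp, ]
    substring(sim$assemblies[[sp]]$contigs[[r$contig]], r$start + 1,
              r$end)
  }, character(1))
  expect_identical(seqs[["A"]], seqs[["B"]])
  expect_identical(seqs[["A"]],
                   sim$reference$genome)
})

test_that("substitution decay matches the Jukes-Cantor expectation", {
  set.seed(16)
  src <- circomine:::random_dna(1000)
  r <- 0.002
  t <- 50
  pd <- vapply(1:200, function(i) {
    d <- circomine:::decay_seq(src, t, decay_rates(sub = r, indel = 0))
    mean(strsplit(d$seq, "")[[1]] != strsplit(src, "")[[1]])
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-4 * r * t / 3))
  se <- sd(pd) / sqrt(length(pd))
  expect_lt(abs(mean(pd) - expected), 3 * se)
})

test_that("disruption load is non-decreasing in insertion age", {
  # count stop codons in the planted rep frame at two ages
  set.seed(18)
  ref <- fixture_reference()
  cds <- substring(ref$genome, 61, 960)
  count_stops <- function(t) {
    mean(vapply(1:100, function(i) {
      d <- circomine:::decay_seq(cds, t, decay_rates(sub = 0.002))$seq
      pep <- circomine:::translate_dna(d)
      lengths(regmatches(pep, gregexpr("*", pep, fixed = TRUE)))
    }, integer(1)))
  }
  young <- count_stops(5)
  old <- count_stops(80)
  expect_gte(old, young)
})

test_that("oversized insertions are rejected with a clear error", {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sc <- list(insertion_scenario("S1", "ab", tandem_copies = 50))
  expect_error(simulate_assembly(tt, sc, contig_len = 5000, seed = 1),
               "too long")
})

test_that("LINE expansion plants extra cassette-adjacent copies", {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sc <- list(insertion_scenario(
    "S1", "ab", region = c(60, 963),
    line = list(node = "A", copies = 4, cassette_len = 400)))
  sim <- simulate_assembly(tt, sc, contig_len = 25000, seed = 19)
  tr <- sim$truth
  expect_equal(sum(tr$is_line_copy & tr$species == "A"), 4)
  expect_equal(sum(tr$is_line_copy & tr$species == "B"), 0)
  # duplicates are uniquely numbered within species
  a <- tr[tr$species == "A", ]
  expect_false(anyDuplicated(a$duplicate) > 0)
})

test_that("fragmentation is a no-op at zero rates and remaps truth", {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sc <- list(insertion_scenario("S1", "ab"))
  sim <- simulate_assembly(tt, sc, seed = 20)
  f0 <- fragment_assembly(sim, 0, 0, seed = 1)
  expect_identical(lapply(f0$assemblies, `[[`, "contigs"),
                   lapply(sim$assemblies, `[[`, "contigs"))
  expect_identical(f0$truth$start, sim$truth$start)

  # forced break at 5 kb splits a contig and shifts coordinates
  ctg <- sim$truth$contig[sim$truth$species == "A"]
  rec <- sim$truth[sim$truth$species == "A", ]
  fb <- list(c(5000L))
  names(fb) <- ctg
  f1 <- fragment_assembly(sim, 0, 0, seed = 1, forced_breaks = fb)
  asmA <- f1$assemblies$A
  expect_true(any(grepl("_p1$", names(asmA$contigs))))
  expect_equal(nchar(asmA$contigs[[paste0(ctg, "_p1")]]), 5000)
  recA <- f1$truth[f1$truth$species == "A", ]
  if (rec$start >= 5000) {
    expect_equal(recA$start, rec$start - 5000)
    expect_identical(recA$contig, paste0(ctg, "_p2"))
  }

  # a break inside the locus yields two flagged fragments
  mid <- as.integer((rec$start + rec$end) / 2)
  fb2 <- list(mid)
  names(fb2) <- ctg
  f2 <- fragment_assembly(sim, 0, 0, seed = 1, forced_breaks = fb2)
  recs <- f2$truth[f2$truth$species == "A", ]
  expect_equal(nrow(recs), 2)
  expect_equal(sum(recs$end - recs$start), rec$end - rec$start)
  expect_setequal(recs$fragment, 1:2)
})

test_that("truth BED export uses scenario:duplicate names", {
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sim <- simulate_assembly(tt, list(
    insertion_scenario("S1", "ab", region = c(60, 963),
                       tandem_copies = 2)), seed = 21)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_truth_bed(sim$truth, tmp)
  bed <- read_bed(tmp)
  expect_true(all(grepl("^S1:[0-9]+$", bed$name)))
  expect_equal(nrow(bed), nrow(sim$truth))
})
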