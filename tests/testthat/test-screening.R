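# Seeded translated search, hit merging, locus extraction.

test_that("an exact probe match scores the BLOSUM62 diagonal sum", {
  set.seed(1)
  ref <- fixture_reference()
  prot <- ref$proteins[["rep"]]
  cds <- substring(ref$genome, ref$cds_table$start[1] + 1,
                   ref$cds_table$end[1] - 3) # drop the stop codon
  contig <- paste0(circomine:::random_dna(4000), cds,
                   circomine:::random_dna(4000))
  asm <- assembly(c(c1 = contig), species = "sp")
  probes <- probe_set("p_rep", ref$name, "rep", prot)
  hits <- seeded_search(asm, probes)
  expect_equal(nrow(hits), 1)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  diag_sum <- sum(vapply(strsplit(prot, "")[[1]],
                         function(ch) e$BLOSUM62[ch, ch], numeric(1)))
  expect_equal(hits$raw_score, diag_sum)
  expect_equal(hits$start, 4000)
  expect_equal(hits$end, 4000 + nchar(cds))
})

test_that("a diverged planted fragment is recovered near its true interval", {
  set.seed(21)
  ref <- fixture_reference()
  cds <- substring(ref$genome, ref$cds_table$start[1] + 1,
                   ref$cds_table$end[1] - 3)
  mut <- mutate_cds_divergence(cds, 0.30)
  contig <- paste0(circomine:::random_dna(25000), mut,
                   circomine:::random_dna(24000))
  asm <- assembly(c(c1 = contig), species = "sp")
  probes <- probes_from_references(list(ref), genes = "rep")
  hits <- seeded_search(asm, probes)
  expect_gte(nrow(hits), 1)
  best <- hits[which.max(hits$raw_score), ]
  expect_lte(abs(best$start - 25000), 15)
  expect_lte(abs(best$end - (25000 + nchar(mut))), 15)
  # score agrees with the independent exhaustive Smith-Waterman oracle
  expect_equal(best$raw_score, sw_oracle_best(contig, ref$proteins[["rep"]]))
})

test_that("random sequence yields no hits at the default threshold", {
  set.seed(7)
  asm <- assembly(c(c1 = circomine:::random_dna(10000)), species = "sp")
  probes <- probes_from_references(list(fixture_reference()))
  hits <- seeded_search(asm, probes)
  expect_equal(nrow(hits), 0)
  # the exhaustive oracle confirms the best score is below threshold
  p <- screen_params()
  ms <- circomine:::min_raw_score(300, 10000 / 3, p)
  expect_lt(sw_oracle_best(asm$contigs[["c1"]],
                           fixture_reference()$proteins[["rep"]]), ms)
})

test_that("probe shorter than the seed word is an error", {
  asm <- assembly(c(c1 = strrep("ACGT", 100)), species = "sp")
  expect_error(seeded_search(asm, probe_set("p", "r", "rep", "MK")),
               "shorter")
})

test_that("hit merging respects gaps, strands and tandem series", {
  h <- function(start, end, strand = "+", gene = "rep", ps = 0, pe = 100) {
    data.frame(contig = "c1", start = start, end = end, strand = strand,
               frame = 1L, probe_id = "p", gene = gene, raw_score = 500L,
               bit_score = 200, e_value = 1e-50, probe_start = ps,
               probe_end = pe, stringsAsFactors = FALSE)
  }
  # two same-strand hits 50 nt apart merge
  loci <- merge_hits(rbind(h(100, 400, pe = 100), h(450, 800, ps = 110,
                                                    pe = 220)))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 100)
  expect_equal(loci$end, 800)
  expect_false(loci$tandem)
  # opposite strands at the same position stay separate
  loci <- merge_hits(rbind(h(100, 400), h(100, 400, strand = "-")))
  expect_equal(nrow(loci), 2)
  # hits beyond max_gap stay separate
  loci <- merge_hits(rbind(h(100, 400), h(1500, 1800)))
  expect_equal(nrow(loci), 2)
  # same probe region repeated in series sets the tandem flag
  loci <- merge_hits(rbind(h(100, 400), h(500, 800), h(900, 1200)))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_hits, 3)
  expect_true(loci$tandem)
})

test_that("three clean tandem copies screen as one tandem locus", {
  set.seed(5)
  ref <- fixture_reference()
  unit <- substring(ref$genome, ref$cds_table$start[1] + 1,
                    ref$cds_table$end[1])
  contig <- paste0(circomine:::random_dna(3000), strrep(unit, 3),
                   circomine:::random_dna(3000))
  asm <- assembly(c(c1 = contig), species = "sp")
  loci <- merge_hits(seeded_search(asm,
                                   probes_from_references(list(ref),
                                                          genes = "rep")))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_hits, 3)
  expect_true(loci$tandem)
})

test_that("flank extraction handles edges, strand and N runs", {
  set.seed(9)
  ref <- fixture_reference()
  cds <- substring(ref$genome, 61, 960)
  left <- circomine:::random_dna(2000)
  right <- circomine:::random_dna(2000)
  probes <- probes_from_references(list(ref), genes = "rep")

  # locus at the very start of a contig: upstream flank empty, incomplete
  asm <- assembly(c(c1 = paste0(cds, right)), species = "sp")
  loci <- extract_locus(asm, merge_hits(seeded_search(asm, probes)))
  expect_equal(loci$start, 0)
  expect_identical(loci$flank_up, "")
  expect_false(loci$flank_up_complete)
  expect_true(loci$flank_down_complete)

  # minus-strand locus: upstream flank is the revcomp of the 3' side
  asm <- assembly(c(c1 = paste0(left, revcomp(cds), right)),
                  species = "sp")
  loci <- extract_locus(asm, merge_hits(seeded_search(asm, probes)))
  expect_identical(loci$strand, "-")
  expect_identical(loci$flank_up,
                   revcomp(substring(right, 1, 1000)))
  expect_identical(loci$flank_down,
                   revcomp(substring(left, 1001, 2000)))

  # a 60 nt N run in a flank marks it undetermined
  leftN <- paste0(substring(left, 1, 1500), strrep("N", 60),
                  substring(left, 1561, 2000))
  asm <- assembly(c(c1 = paste0(leftN, cds, right)), species = "sp")
  loci <- extract_locus(asm, merge_hits(seeded_search(asm, probes)))
  expect_false(loci$flank_up_complete)
  expect_true(loci$flank_down_complete)
})

test_that("screening the reverse-complemented assembly mirrors loci", {
  set.seed(13)
  ref <- fixture_reference()
  cds <- substring(ref$genome, 61, 963)
  contig <- paste0(circomine:::random_dna(5000), cds,
                   circomine:::random_dna(5000))
  L <- nchar(contig)
  probes <- probes_from_references(list(ref))
  h1 <- seeded_search(assembly(c(c1 = contig), species = "s"), probes)
  h2 <- seeded_search(assembly(c(c1 = revcomp(contig)), species = "s"),
                      probes)
  expect_equal(nrow(h1), nrow(h2))
  o1 <- order(h1$start)
  o2 <- order(-h2$end)
  expect_equal(h2$start[o2], L - h1$end[o1])
  expect_equal(h2$end[o2], L - h1$start[o1])
  expect_true(all(h2$strand[o2] != h1$strand[o1]))
  expect_equal(h2$raw_score[o2], h1$raw_score[o1])
})

test_that("seeded search with k=4 equals the exhaustive k=1 search", {
  ref <- fixture_reference()
  probes <- probes_from_references(list(ref))
  for (seed in 1:5) {
    set.seed(seed)
    cds <- substring(ref$genome, 61, 960)
    planted <- seed %% 2 == 0
    contig <- if (planted) {
      paste0(circomine:::random_dna(8000),
             mutate_cds_divergence(cds, runif(1, 0, 0.35)),
             circomine:::random_dna(8000))
    } else {
      circomine:::random_dna(16000)
    }
    asm <- assembly(c(c1 = contig), species = "s")
    h4 <- seeded_search(asm, probes, screen_params(word_size = 4))
    h1 <- seeded_search(asm, probes, screen_params(word_size = 1))
    expect_equal(h4[, c("start", "end", "strand", "probe_id",
                        "raw_score")],
                 h1[, c("start", "end", "strand", "probe_id",
                        "raw_score")])
  }
})
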