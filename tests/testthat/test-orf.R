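# Frameshift-aware ORF reconstruction and disruption counting.

test_that("an exact CDS copy is intact with zero disruptions", {
  ref <- fixture_reference()
  prot <- ref$proteins[["rep"]]
  cds <- substring(ref$genome, 61, 960)
  a <- codon_aware_align(cds, prot)
  expect_true(a$alignable)
  expect_equal(a$n_frameshifts, 0)
  expect_equal(a$n_premature_stops, 0)
  expect_equal(a$aligned_fraction, 1)
})

test_that("single constructed disruptions are counted exactly", {
  ref <- fixture_reference()
  prot <- ref$proteins[["rep"]]
  cds <- substring(ref$genome, 61, 960)
  # one nucleotide deleted at codon 10 -> exactly 1 frameshift
  mut <- paste0(substring(cds, 1, 28), substring(cds, 30))
  a <- codon_aware_align(mut, prot)
  expect_equal(a$n_frameshifts, 1)
  expect_equal(a$n_premature_stops, 0)
  # codon 5 -> TAA and a 2 nt insertion at codon 50
  v <- cds
  substr(v, 13, 15) <- "TAA"
  v <- paste0(substring(v, 1, 147), "GC", substring(v, 148))
  a <- codon_aware_align(v, prot)
  expect_equal(a$n_frameshifts, 1)
  expect_equal(a$n_premature_stops, 1)
  expect_true(grepl("!", a$peptide, fixed = TRUE))
  expect_true(grepl("*", a$peptide, fixed = TRUE))
})

test_that("planted well-separated disruptions are recovered exactly", {
  ref <- fixture_reference()
  prot <- ref$proteins[["rep"]]
  cds <- substring(ref$genome, 61, 960)
  set.seed(17)
  for (rep_i in 1:25) {
    n_codon <- nchar(cds) / 3
    # disruptions at least 12 codons apart so they cannot interact
    k <- sample(2:5, 1)
    cods <- sort(sample(seq(10, n_codon - 10, by = 12), k))
    v <- cds
    types <- sample(c("del1", "ins1", "ins2", "stop"), k, replace = TRUE)
    offset <- 0L
    n_fs_true <- sum(types != "stop")
    n_stop_true <- sum(types == "stop")
    for (q in seq_len(k)) {
      p <- 3 * (cods[q] - 1) + 1 + offset
      if (types[q] == "del1") {
        v <- paste0(substring(v, 1, p - 1), substring(v, p + 1))
        offset <- offset - 1L
      } else if (types[q] == "ins1") {
        v <- paste0(substring(v, 1, p - 1), "G", substring(v, p))
        offset <- offset + 1L
      } else if (types[q] == "ins2") {
        v <- paste0(substring(v, 1, p - 1), "GC", substring(v, p))
        offset <- offset + 2L
      } else {
        substr(v, p, p + 2) <- "TAA"
      }
    }
    a <- codon_aware_align(v, prot)
    expect_equal(a$n_frameshifts, n_fs_true, info = paste("seed rep", rep_i))
    expect_equal(a$n_premature_stops, n_stop_true,
                 info = paste("seed rep", rep_i))
  }
})

test_that("low-coverage fragments are not intact", {
  ref <- fixture_reference()
  prot <- ref$proteins[["rep"]]
  cds <- substring(ref$genome, 61, 960)
  frag <- substring(cds, 1, round(nchar(cds) * 0.4))
  a <- codon_aware_align(frag, prot)
  expect_equal(a$n_frameshifts, 0)
  expect_lt(a$aligned_fraction, 0.95)
  loci <- data.frame(locus_id = "L1", locus_seq = frag,
                     stringsAsFactors = FALSE)
  cls <- classify_loci(loci, list(ref))
  rep_row <- orf_report(loci, cls, list(ref))
  expect_false(rep_row$intact)
})

test_that("frameshift DP score matches an independent R implementation", {
  ref <- fixture_reference()
  set.seed(23)
  for (q in 1:8) {
    m <- sample(20:40, 1)
    prot <- substring(ref$proteins[["rep"]], 1, m)
    cds <- substring(ref$genome, 61, 60 + 3 * m)
    dna <- mutate_cds_divergence(cds, runif(1, 0, 0.2))
    # sprinkle an indel half the time
    if (q %% 2 == 0) {
      p <- sample(10:(nchar(dna) - 10), 1)
      dna <- paste0(substring(dna, 1, p), substring(dna, p + 2))
    }
    a <- codon_aware_align(dna, prot, orf_params(min_score = 1))
    expect_equal(a$score, fs_align_score_R(dna, prot), info = paste("case", q))
  }
})

test_that("frameshift states never score below the frame-0 alignment", {
  ref <- fixture_reference()
  prot <- ref$proteins[["rep"]]
  set.seed(29)
  for (q in 1:10) {
    cds <- substring(ref$genome, 61, 960)
    dna <- mutate_cds_divergence(cds, runif(1, 0, 0.4))
    # random indels to force frame damage
    for (z in seq_len(sample(0:3, 1))) {
      p <- sample(10:(nchar(dna) - 10), 1)
      dna <- paste0(substring(dna, 1, p), substring(dna, p + 1 +
                                                      sample(1:2, 1)))
    }
    a <- codon_aware_align(dna, prot, orf_params(min_score = 1))
    pep0 <- circomine:::translate_dna(dna)
    S <- circomine:::score_matrix128()
    h <- circomine:::cpp_seeded_hits(pep0, prot, S, 1L, 12L, 2L, 1L,
                                     nchar(prot))
    naive <- if (nrow(h) > 0) max(h$score) else 0
    expect_gte(a$score, naive)
  }
})

test_that("degraded simulator loci yield non-intact reports, age-0 intact", {
  ref <- fixture_reference()
  tt <- read_newick_with_ages("((A:10,B:10)ab:20,C:30)r;")
  sim <- simulate_assembly(tt, list(
    insertion_scenario("S1", "A", region = c(60, 963),
                       rates = decay_rates(sub = 0), time = 0)),
    reference = ref, contig_len = 10000, seed = 41)
  probes <- probes_from_references(list(ref), genes = "rep")
  loci <- screen_assembly(sim$assemblies$A, probes)
  cls <- classify_loci(loci, list(ref))
  rep0 <- orf_report(loci, cls, list(ref))
  expect_true(all(rep0$intact))
})
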