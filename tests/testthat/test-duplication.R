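# Distances, neighbor joining, expansion detection, repeat association.

test_that("p-distances behave on identical and partly diverged inputs", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTTT")
  pd <- p_distance_matrix(seqs)
  expect_equal(unname(diag(pd$d)), c(0, 0, 0))
  expect_equal(pd$d["a", "b"], 0)
  expect_equal(pd$d["a", "c"], 0.2)
  expect_identical(pd$d, t(pd$d))
  # heavy gapping flags the pair unreliable
  seqs2 <- c(a = "ACGTACGTAC", b = "ACGT------")
  pd2 <- p_distance_matrix(seqs2)
  expect_true(pd2$unreliable["a", "b"])
  expect_true(is.na(pd2$d["a", "b"]))
})

test_that("neighbor joining is exact on additive matrices", {
  # fixed 4-taxon additive case
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- cophenetic(tr)
  nj <- nj_tree(d)
  expect_equal(cophenetic(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  # three taxa: closed-form star resolution
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- nj_tree(d3)
  expect_equal(cophenetic(nj3)[c("A", "B", "C"), c("A", "B", "C")], d3,
               tolerance = 1e-10)
  dInf <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3)
  expect_error(nj_tree(dInf), "non-finite")
})

test_that("neighbor joining recovers 100 random additive trees exactly", {
  set.seed(91)
  for (q in 1:100) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    d <- cophenetic(tr)
    nj <- nj_tree(d)
    expect_equal(cophenetic(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("expansions are maximal single-lineage clades of min size", {
  # simulate duplicates: 10-copy ursid expansion, singletons elsewhere
  tr <- ape::read.tree(text = paste0(
    "(((u1:1,u2:1):1,((u3:1,u4:1):1,(u5:1,(u6:0.5,u7:0.5):0.5):1):1):3,",
    "((u8:1,(u9:0.5,u10:0.5):0.5):4,(p1:2,(m1:1,m2:3):1):2):1);"))
  lineage <- c(setNames(rep("ursid", 10), paste0("u", 1:10)),
               p1 = "pinniped", m1 = "mustelid", m2 = "mustelid")
  ex <- detect_expansions(tr, lineage, min_size = 3)
  # u1..u7 form one maximal ursid clade; u8..u10 another
  expect_true(all(ex$lineage == "ursid"))
  expect_equal(sum(ex$size), 10)
  # permutation invariance of leaf order
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  ex2 <- detect_expansions(tr2, lineage, min_size = 3)
  expect_setequal(unlist(ex$members), unlist(ex2$members))
  # nothing reaches min_size -> empty
  ex0 <- detect_expansions(tr, setNames(paste0("l", 1:13),
                                        names(lineage)), min_size = 3)
  expect_equal(nrow(ex0), 0)
})

test_that("two independent lineage expansions come out as two groups", {
  tr <- ape::read.tree(text = paste0(
    "(((u1:1,u2:1):1,u3:2):2,((p1:1,p2:1):1,p3:2):2);"))
  lineage <- c(u1 = "ursid", u2 = "ursid", u3 = "ursid",
               p1 = "pinniped", p2 = "pinniped", p3 = "pinniped")
  ex <- detect_expansions(tr, lineage, min_size = 3)
  expect_equal(nrow(ex), 2)
  expect_setequal(ex$lineage, c("ursid", "pinniped"))
})

test_that("exact 2x2 test matches hand enumeration on reference tables", {
  # margins (1,1): two tables, each probability 1/2
  expect_equal(exact_2x2_test(1, 0, 0, 1)$p, 1.0)
  # [[10,0],[0,10]]: two extreme tables out of C(20,10)
  expect_equal(exact_2x2_test(10, 0, 0, 10)$p, 2 / choose(20, 10),
               tolerance = 1e-12)
  # Haldane-corrected odds ratio on a zero cell
  expect_equal(exact_2x2_test(10, 0, 0, 10)$odds_ratio,
               (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("exact test equals fisher.test over random tables", {
  set.seed(13)
  for (q in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    mine <- exact_2x2_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ft <- stats::fisher.test(tab)
    expect_equal(mine$p, ft$p.value, tolerance = 1e-12)
  }
})

test_that("repeat association flags cassette-adjacent expansions", {
  set.seed(14)
  loci <- data.frame(
    locus_id = sprintf("L%02d", 1:30),
    contig = "c1",
    start = seq(10000, by = 20000, length.out = 30),
    stringsAsFactors = FALSE)
  loci$end <- loci$start + 900
  expansion <- loci$locus_id[1:10]
  # repeats right next to every expansion locus, nowhere else
  repeats <- data.frame(chrom = "c1", start = loci$start[1:10] - 400,
                        end = loci$start[1:10] - 100,
                        stringsAsFactors = FALSE)
  res <- repeat_association(loci, expansion, repeats, window = 500)
  expect_true(res$defined)
  expect_lt(res$p, 0.01)
  expect_equal(unname(res$table[1, 1]), 10)
  expect_equal(unname(res$table[2, 1]), 0)
  # empty repeat track: undefined, reported as such
  res0 <- repeat_association(loci, expansion,
                             repeats[0, , drop = FALSE])
  expect_false(res0$defined)
})

test_that("simulated decay distances stay consistent with divergence times", {
  # ultrametric decay: duplicates decayed independently for equal times
  # should show no triangle-inequality violations
  set.seed(15)
  src <- circomine:::random_dna(600)
  leaves <- lapply(1:6, function(i) {
    circomine:::decay_seq(src, 40, decay_rates(sub = 0.002, indel = 0))$seq
  })
  names(leaves) <- paste0("d", 1:6)
  pd <- p_distance_matrix(unlist(leaves))
  d <- pd$d
  for (i in 1:4) for (j in (i + 1):5) for (k in (j + 1):6) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
  }
})
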