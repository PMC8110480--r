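make_aln <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  LineageAlignment(m, "amino_acid")
}

test_that("the scan requires focal fixation and outgroup difference", {
  part <- LineagePartition(c("f1", "f2", "f3"), c("o1", "o2"))
  aln <- make_aln(list(f1 = "MAL", f2 = "MAL", f3 = "MAL",
                       o1 = "LAL", o2 = "LAL"))
  hits <- scanLsg(aln, part)
  expect_equal(hits$column, 1L)
  expect_equal(hits$focalState, "M")
  expect_equal(hits$outgroupStates, "L,L")

  # focal polymorphism disqualifies
  aln2 <- make_aln(list(f1 = "M", f2 = "M", f3 = "L", o1 = "K", o2 = "K"))
  expect_equal(nrow(scanLsg(aln2, part)), 0L)

  # polymorphic outgroups still count (default policy)
  aln3 <- make_aln(list(f1 = "M", f2 = "M", f3 = "M", o1 = "L", o2 = "K"))
  expect_equal(nrow(scanLsg(aln3, part)), 1L)
  expect_equal(nrow(scanLsg(aln3, part, outgroupMonomorphic = TRUE)), 0L)

  # focal gap disqualifies; outgroup gaps reduce the present count
  aln4 <- make_aln(list(f1 = "-M", f2 = "MM", f3 = "MM",
                        o1 = "LL", o2 = "L-"))
  h4 <- scanLsg(aln4, part)
  expect_equal(h4$column, integer(0))   # col1: focal gap; col2: 1 outgroup
  h4b <- scanLsg(aln4, part, minOutgroupPresent = 1)
  expect_equal(h4b$column, 2L)

  expect_error(scanLsg(aln, LineagePartition(c("f1", "zz"), "o1")),
               "missing from alignment")
})

test_that("the scan is invariant under row permutation", {
  set.seed(17)
  sim <- simulateTree(4, 3, 0.2, seed = 17)
  ca <- simulateCodonAlignment(sim$tree, NULL, omegaBg = 1, nCodons = 200,
                               seed = 18)
  m <- as.matrix(ca$alignment)
  aln <- LineageAlignment(m, "codon")
  alnPerm <- LineageAlignment(m[sample(nrow(m)), ], "codon")
  h1 <- scanLsg(aln, sim$partition)
  h2 <- scanLsg(alnPerm, sim$partition)
  expect_equal(h1$column, h2$column)
  expect_equal(h1$focalState, h2$focalState)
})

test_that("marginal posteriors match brute-force enumeration on a 4-leaf tree", {
  tree <- readNewickTree("((a:0.2,b:0.35):0.15,(c:0.4,d:0.1):0.25);")
  set.seed(5)
  for (rep in 1:5) {
    m <- random_nt_matrix(c("a", "b", "c", "d"), 1)
    aln <- LineageAlignment(cbind(m, m), "nucleotide")  # >=2 cols for matrix
    recon <- ancestralMarginal(aln, tree, model = "jc_nt")
    tr <- recon$tree
    Pedge <- lapply(seq_len(nrow(tr$edge)),
                    function(e) oracle_jc_pmat(tr$edge.length[e], 4))
    tips <- match(m[tr$tip.label, 1], c("A", "C", "G", "T"))
    oracle <- oracle_column(tr, Pedge, tips, rep(1 / 4, 4))
    for (n in rownames(recon$map)) {
      expect_equal(unname(recon$prob[[n]][, 1]), unname(oracle$post[n, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("posteriors normalize, dominate for invariant data, and respect zero-length limits", {
  tree <- readNewickTree("((a:0.2,b:0.3):0.1,(c:0.2,d:0.4):0.3);")
  set.seed(9)
  m <- random_nt_matrix(letters[1:4], 50)
  recon <- ancestralMarginal(LineageAlignment(m, "nucleotide"), tree, "jc_nt")
  for (n in names(recon$prob))
    expect_true(all(abs(colSums(recon$prob[[n]]) - 1) < 1e-9))

  mono <- matrix("A", 4, 3, dimnames = list(letters[1:4]))
  rmono <- ancestralMarginal(LineageAlignment(mono, "nucleotide"), tree,
                             "jc_nt")
  expect_true(all(rmono$map == "A"))

  # zero-length pendant edge pins the parent to the leaf state
  t2 <- readNewickTree("((a:0,b:0.3):0.1,c:0.4);")
  m2 <- matrix(c("A", "C", "G"), 3, 2, dimnames = list(c("a", "b", "c")))
  r2 <- ancestralMarginal(LineageAlignment(m2, "nucleotide"), t2, "jc_nt")
  parent_of_a <- as.character(r2$tree$edge[match(which(r2$tree$tip.label == "a"),
                                                 r2$tree$edge[, 2]), 1])
  expect_equal(unname(r2$prob[[parent_of_a]]["A", 1]), 1, tolerance = 1e-12)

  # all-gap column: uniform posterior, flagged uninformative
  m3 <- mono; m3[, 2] <- "-"
  r3 <- ancestralMarginal(LineageAlignment(m3, "nucleotide"), tree, "jc_nt")
  expect_true(r3$uninformative[2])
  expect_equal(unname(r3$prob[[names(r3$prob)[1]]][, 2]), rep(0.25, 4))
})

test_that("validation confirms stem substitutions and rejects ancestral-state conflicts", {
  sim <- simulateTree(4, 4, 0.1, seed = 33)
  part <- sim$partition
  # declared outgroups are only the distant ones; o1/o2 stay undeclared
  declared <- LineagePartition(focalTaxa(part), c("o3", "o4"))
  aln <- invariant_aa_alignment(sim$tree$tip.label, 120)
  planted <- plantLsg(aln, declared, nSites = 8, seed = 34)
  m <- as.matrix(planted$alignment)
  # adversarial column: focal + undeclared sisters share M, declared differ
  adv <- ncol(m)
  m[, adv] <- "L"
  m[c(focalTaxa(part), "o1", "o2"), adv] <- "M"
  aln2 <- LineageAlignment(m, "amino_acid")
  hits <- scanLsg(aln2, declared)
  expect_setequal(hits$column, c(planted$truth$column, adv))
  recon <- ancestralMarginal(aln2, sim$tree, "poisson_aa")
  val <- validateLsg(hits, recon, sim$tree, declared)
  expect_true(all(val$confirmed[val$column != adv]))
  expect_false(val$confirmed[val$column == adv])
  expect_true(all(val$pMrca >= 0 & val$pMrca <= 1))

  # non-monophyletic focal set: validation is undefined
  badpart <- LineagePartition(c("f1", "o3"), "o4")
  bh <- scanLsg(aln2, badpart)
  expect_error(validateLsg(hits, recon, sim$tree, badpart),
               "monophyletic")
})
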