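test_that("GY94 rate matrix has the stated structure and normalization", {
  cods <- senseCodons()
  # omega = 0 kills every nonsynonymous rate
  Q0 <- buildGY94(kappa = 2, omega = 0)
  aa <- translateCodons(cods)
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(Q0[nonsyn] == 0))

  # equal frequencies, kappa = omega = 1: symmetric, rows sum to zero
  Q1 <- buildGY94(1, 1)
  expect_lt(max(abs(Q1 - t(Q1))), 1e-12)
  expect_lt(max(abs(rowSums(Q1))), 1e-12)

  # normalization: one expected substitution per unit branch length
  set.seed(2)
  pif <- rexp(61); pif <- pif / sum(pif)
  Q <- buildGY94(kappa = 3.1, omega = 0.7, codonFreqs = pif)
  expect_equal(-sum(pif * diag(Q)), 1, tolerance = 1e-10)
  expect_lt(max(abs(rowSums(Q))), 1e-10)

  # multi-nucleotide changes are structural zeros
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["AAA", "CCC"], 0)

  # detailed balance (reversibility): pi_i q_ij = pi_j q_ji
  expect_lt(max(abs(pif * Q - t(pif * Q))), 1e-12)
})

test_that("transition probabilities satisfy the Chapman-Kolmogorov relations", {
  set.seed(4)
  pif <- rexp(61); pif <- pif / sum(pif)
  eig <- lineagescan:::.gy94_eigen(2.3, 0.4, pif)
  P0 <- lineagescan:::.pmat(eig, 0)
  expect_equal(P0, diag(61), tolerance = 1e-9)
  Pt <- lineagescan:::.pmat(eig, 0.17)
  Ps <- lineagescan:::.pmat(eig, 0.05)
  Pts <- lineagescan:::.pmat(eig, 0.22)
  expect_equal(Pt %*% Ps, Pts, tolerance = 1e-9)
  expect_equal(unname(rowSums(Pt)), rep(1, 61), tolerance = 1e-12)
})

test_that("the codon likelihood matches direct summation and is root-invariant", {
  # two taxa, one codon site: direct sum over the ancestral codon
  pif <- rep(1 / 61, 61)
  tr <- readNewickTree("(a:0.3,b:0.2);")
  m <- matrix(c("ATG", "ACG"), 2, 1, dimnames = list(c("a", "b")))
  # duplicate the column so the container accepts it, then halve
  aln <- LineageAlignment(m, "codon")
  ll <- codonLoglik(aln, tr, kappa = 2.5, omega = 0.4, codonFreqs = pif)
  P1 <- oracle_gy94_pmat(2.5, 0.4, pif, 0.3)
  P2 <- oracle_gy94_pmat(2.5, 0.4, pif, 0.2)
  direct <- log(sum(pif * P1[, "ATG"] * P2[, "ACG"]))
  expect_equal(ll[1], direct, tolerance = 1e-10)

  # large branch lengths: independence limit pi_a * pi_b
  llbig <- codonLoglik(aln, readNewickTree("(a:60,b:60);"),
                       kappa = 2, omega = 0.5, codonFreqs = pif)
  expect_equal(llbig[1], log(pif[1]^2), tolerance = 1e-6)

  # reversibility: likelihood is invariant to root placement
  sim <- simulateTree(2, 2, 0.2, seed = 8)
  ca <- simulateCodonAlignment(sim$tree, NULL, kappa = 2, omegaBg = 0.3,
                               nCodons = 80, seed = 9)
  base <- codonLoglik(ca$alignment, sim$tree, kappa = 2, omega = 0.3)
  for (node in c(2L, 3L, 4L)) {
    rr <- ape::root(ape::unroot(sim$tree), node = NULL,
                    outgroup = sim$tree$tip.label[node],
                    resolve.root = TRUE)
    expect_equal(codonLoglik(ca$alignment, rr, kappa = 2, omega = 0.3)[1],
                 base[1], tolerance = 1e-8)
  }
})

test_that("missing data and degenerate alignments are handled", {
  tr <- readNewickTree("((a:0.1,b:0.1):0.1,c:0.2);")
  m <- matrix(c("ATG", "---", "ATG",
                "AAA", "AAA", "AAA",
                "CCC", "CCC", "NNN"), 3, 3,
              dimnames = list(c("a", "b", "c")))
  aln <- LineageAlignment(m, "codon")
  ll <- codonLoglik(aln, tr, kappa = 2, omega = 0.5)
  expect_true(is.finite(ll[1]))
  # a gap codon equals marginalizing that taxon out
  m2 <- m[c("a", "c"), , drop = FALSE]
  tr2 <- ape::drop.tip(tr, "b")
  llcol <- attr(ll, "siteLnL")
  ll2 <- attr(codonLoglik(LineageAlignment(m2, "codon"), tr2,
                          kappa = 2, omega = 0.5), "siteLnL")
  expect_equal(llcol[1], ll2[1], tolerance = 1e-9)

  mono <- LineageAlignment(matrix("ATG", 3, 4,
                                  dimnames = list(c("a", "b", "c"))),
                           "codon")
  expect_error(fitM0(mono, tr), "unidentifiable")

  tr0 <- tr; tr0$edge.length[] <- 0
  vari <- LineageAlignment(matrix(c("ATG", "ACG", "ATG", "AAA", "AAA", "AAC"),
                                  3, 2, dimnames = list(c("a", "b", "c"))),
                           "codon")
  expect_error(fitM0(vari, tr0), "no information")
})

test_that("the two-ratio fit nests the one-ratio fit and recovers parameters", {
  sim <- simulateTree(4, 3, 0.2, seed = 41)
  ca <- simulateCodonAlignment(sim$tree, sim$partition, kappa = 2,
                               omegaFg = 1.8, omegaBg = 0.2,
                               nCodons = 800, seed = 42)
  m0 <- fitM0(ca$alignment, sim$tree, codonFreqs = "equal")
  fit <- fitBranchModel(ca$alignment, sim$tree, partition = sim$partition,
                        codonFreqs = "equal", m0 = m0)
  expect_s4_class(fit, "BranchModelFit")
  expect_gte(fit@lnLBranch, fit@lnLM0 - 1e-6)
  expect_true(fit@converged)
  # foreground omega well separated from background
  expect_gt(fit@omega0, fit@omega1)
  expect_gt(fit@omega0, 1.0)
  expect_lt(fit@omega1, 0.6)
  expect_equal(fit@kappa, 2, tolerance = 0.5)
  # omega2 is the M0 (whole-tree) estimate
  expect_equal(fit@omega2, m0$omega)
})

test_that("selection calls follow the omega-ordering and significance rules", {
  mk <- function(w0, w1, w2, dlnL) {
    new("BranchModelFit", omega0 = w0, omega1 = w1, omega2 = w2, kappa = 2,
        lnLBranch = -1000, lnLM0 = -1000 - dlnL, converged = TRUE,
        nCodons = 500L, scale = 1)
  }
  expect_equal(classifySelection(mk(2.5, 0.3, 0.35, 5.5))$class, "PSG")
  expect_equal(classifySelection(mk(0.8, 0.2, 0.25, 3.5))$class, "REG")
  expect_equal(classifySelection(mk(0.9, 0.2, 0.25, 0.8))$class, "NS")
  # significant but omega0 below the background: never called
  expect_equal(classifySelection(mk(0.1, 0.9, 0.5, 8))$class, "NS")
  # non-converged fits fall back to NS
  nc <- mk(2.5, 0.3, 0.3, 8); nc@converged <- FALSE
  expect_equal(classifySelection(nc)$class, "NS")
  expect_equal(classifySelection(mk(2, 0.3, 0.3, 8))$lrt, 16)
})
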