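block_from_rows <- function(rows, ref = names(rows)[1], refStart = 0) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  info <- data.frame(src = paste0(names(rows), ".chr1"),
                     start = c(refStart, rep(0, length(rows) - 1L)),
                     size = as.integer(rowSums(m != "-")),
                     strand = "+", srcSize = 100000L,
                     row.names = names(rows), stringsAsFactors = FALSE)
  new("AlignmentBlock", aln = m, info = info, ref = ref)
}

test_that("per-site similarity is mean pairwise identity with presence counts", {
  part <- LineagePartition(c("f1", "f2", "f3"), c("o1", "o2"))
  b <- block_from_rows(list(f1 = "AAT", f2 = "AAT", f3 = "CA-",
                            o1 = "A--", o2 = "A--"))
  tr <- computeTracks(b, part)
  # site 1: focal {A,A,C} -> pairs AA=1, AC=0, AC=0 -> 1/3
  expect_equal(tr@focalSim[1], 1 / 3)
  expect_equal(tr@focalSim[2], 1)              # all identical
  expect_equal(tr@focalPresent, c(3L, 3L, 2L))
  expect_equal(tr@outgroupPresent, c(2L, 0L, 0L))
  expect_true(is.na(tr@outgroupSim[2]))        # all outgroups gapped
  expect_equal(tr@outgroupSim[1], 1)

  # reference gap columns carry no coordinate: ref with a gap shrinks track
  b2 <- block_from_rows(list(f1 = "A-T", f2 = "AAT", f3 = "AAT",
                             o1 = "AAT", o2 = "AAT"))
  expect_equal(length(computeTracks(b2, part)), 2L)

  expect_error(computeTracks(b, part, refTaxon = "nope"), "absent")
})

test_that("similarity is invariant to block row permutation", {
  part <- LineagePartition(paste0("f", 1:4), c("o1", "o2"))
  set.seed(1)
  rows <- setNames(as.list(replicate(
    6, paste(sample(c("A", "C", "G", "T", "-"), 40, replace = TRUE),
             collapse = ""))), c(paste0("f", 1:4), "o1", "o2"))
  rows$f1 <- gsub("-", "A", rows$f1)   # keep the reference gap-free
  b <- block_from_rows(rows)
  bperm <- block_from_rows(rows[c(1, sample(2:6))], ref = "f1")
  t1 <- computeTracks(b, part); t2 <- computeTracks(bperm, part)
  expect_equal(t1@focalSim, t2@focalSim)
  expect_equal(t1@outgroupSim, t2@outgroupSim)
})

test_that("element calling enforces the length and presence rules", {
  mk_track <- function(q, nFocal = 10, present = nFocal) {
    n <- length(q)
    new("SimilarityTrack", refSeqname = "chr1", refStart = 0L,
        focalSim = ifelse(q, 1, 0), outgroupSim = rep(NA_real_, n),
        focalPresent = rep(as.integer(present), n),
        outgroupPresent = rep(0L, n),
        nFocal = as.integer(nFocal), nOutgroup = 3L)
  }
  run25 <- mk_track(c(rep(FALSE, 5), rep(TRUE, 25), rep(FALSE, 5)))
  el <- callElements(run25)
  expect_length(el, 1L)
  expect_equal(GenomicRanges::width(el), 25L)
  expect_equal(GenomicRanges::start(el), 6L)   # 1-based on the reference

  run19 <- mk_track(c(rep(FALSE, 5), rep(TRUE, 19), rep(FALSE, 5)))
  expect_length(callElements(run19), 0L)       # < 20 bp removed

  # "more than eight species": 8 present fails the default min_present = 9
  only8 <- mk_track(rep(TRUE, 30), present = 8)
  expect_length(callElements(only8), 0L)
  expect_length(callElements(mk_track(rep(TRUE, 30), present = 9)), 1L)

  expect_error(callElements(mk_track(rep(TRUE, 30), nFocal = 5, present = 5),
                            minPresent = 9), "exceeds focal group size")

  # max_join_gap bridges short interruptions
  split <- mk_track(c(rep(TRUE, 12), FALSE, rep(TRUE, 12)))
  expect_length(callElements(split), 0L)
  joined <- callElements(split, maxJoinGap = 1)
  expect_equal(GenomicRanges::width(joined), 25L)
})

test_that("planted elements are recovered and every called site qualifies", {
  part <- LineagePartition(paste0("f", 1:10), paste0("o", 1:3))
  spec <- data.frame(start = c(100, 300), len = c(30, 40),
                     mode = "outgroup_absent")
  sim <- simulateCneRegion(part, regionLen = 600, elements = spec,
                           seed = 77)
  track <- computeTracks(sim$blocks, part)
  el <- callElements(track)
  expect_length(el, 2L)
  ov <- GenomicRanges::findOverlaps(el, sim$truth$elements)
  expect_equal(length(ov), 2L)
  expect_true(all(abs(GenomicRanges::start(el) -
                      GenomicRanges::start(sim$truth$elements)) <= 2))
  expect_true(all(abs(GenomicRanges::end(el) -
                      GenomicRanges::end(sim$truth$elements)) <= 2))
  # re-evaluate the qualifying predicate over every called site
  for (i in seq_along(el)) {
    span <- (GenomicRanges::start(el)[i]):(GenomicRanges::end(el)[i])
    idx <- span - track@refStart
    expect_true(all(track@focalPresent[idx] >= 9 &
                    track@focalSim[idx] >= 0.8 &
                    track@outgroupPresent[idx] == 0))
  }
})

test_that("diverged-outgroup elements are found in low_similarity mode", {
  # chance agreement among few random outgroup rows breaks strict
  # contiguity, so this mode is exercised with a small join gap and an
  # overlap (rather than exact-boundary) recovery check
  part <- LineagePartition(paste0("f", 1:10), paste0("o", 1:3))
  sim <- simulateCneRegion(part, regionLen = 600,
                           elements = data.frame(start = 300, len = 40,
                                                 mode = "outgroup_diverged"),
                           seed = 78)
  track <- computeTracks(sim$blocks, part)
  expect_length(callElements(track, outgroupMode = "absent"), 0L)
  el <- callElements(track, outgroupMode = "low_similarity", maxJoinGap = 2)
  ov <- GenomicRanges::findOverlaps(el, sim$truth$elements)
  expect_gte(length(ov), 1L)
  inter <- GenomicRanges::intersect(el, sim$truth$elements)
  expect_gte(sum(GenomicRanges::width(inter)), 0.8 * 40)
})

test_that("raising tauFocal or minPresent never increases total element length", {
  part <- LineagePartition(paste0("f", 1:10), paste0("o", 1:3))
  sim <- simulateCneRegion(part, regionLen = 800,
                           elements = data.frame(start = c(50, 400),
                                                 len = c(60, 35),
                                                 mode = "outgroup_absent"),
                           elementDivergence = 0.05, seed = 13)
  track <- computeTracks(sim$blocks, part)
  totlen <- function(tau, mp = 9) {
    sum(GenomicRanges::width(callElements(track, tauFocal = tau,
                                          minPresent = mp)))
  }
  taus <- c(0.5, 0.7, 0.8, 0.9, 0.99)
  expect_true(all(diff(sapply(taus, totlen)) <= 0))
  expect_true(all(diff(sapply(8:10, function(mp) totlen(0.8, mp))) <= 0))
})

test_that("CDS masking clips, re-filters, and is the identity on an empty mask", {
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 140),
                               name = "scne_1", score = 950L,
                               meanFocalSim = 0.95, minFocalPresent = 9L)
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(121, 200))
  out <- subtractMask(el, cds)
  expect_length(out, 1L)
  expect_equal(GenomicRanges::start(out), 101L)
  expect_equal(GenomicRanges::end(out), 120L)   # 20 bp fragment kept

  el2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 130),
                                name = "scne_1", score = 900L,
                                meanFocalSim = 0.9, minFocalPresent = 9L)
  cds2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(111, 125))
  expect_length(subtractMask(el2, cds2), 0L)    # fragments 10 + 5 dropped

  expect_equal(subtractMask(el, GenomicRanges::GRanges()), el)
})
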