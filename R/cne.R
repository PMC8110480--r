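#' Per-site similarity tracks over reference-anchored blocks
#'
#' For every gap-free reference position of a block, computes the mean
#' pairwise identity among the focal rows that align a base there, the
#' same for the outgroup rows, and the per-group present counts. A group
#' member is "present" at a position when its row carries an unambiguous
#' base (A/C/G/T, case-insensitive) rather than a gap; similarity is the
#' mean over all unordered pairs of present members of the identity
#' indicator, and is `NA` where fewer than two members are present.
#' Partition taxa absent from a block count as not present. Insertions
#' relative to the reference carry no reference coordinate and are skipped.
#'
#' @param blocks an [AlignmentBlock-class] or a list of them.
#' @param partition a [LineagePartition-class].
#' @param refTaxon reference taxon id; default: each block's own anchor.
#' @return A [SimilarityTrack-class], or a list of tracks when `blocks` is
#'   a list of several blocks.
#' @export
computeTracks <- function(blocks, partition, refTaxon = NULL) {
  if (is(blocks, "AlignmentBlock")) return(.track_one(blocks, partition,
                                                      refTaxon))
  out <- lapply(blocks, .track_one, partition = partition,
                refTaxon = refTaxon)
  if (length(out) == 1L) out[[1]] else out
}

.group_counts <- function(sub, present) {
  ## base counts among present members, per column: 4 x nCol
  cnt <- sapply(c("A", "C", "G", "T"),
                function(b) colSums(sub == b & present))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
  k <- rowSums(cnt)
  pairsSame <- rowSums(cnt * (cnt - 1) / 2)
  pairsAll <- k * (k - 1) / 2
  sim <- ifelse(pairsAll > 0, pairsSame / pairsAll, NA_real_)
  list(sim = sim, present = as.integer(k))
}

.track_one <- function(block, partition, refTaxon = NULL) {
  stopifnot(is(block, "AlignmentBlock"))
  ref <- if (is.null(refTaxon)) block@ref else refTaxon
  if (!ref %in% rownames(block@aln))
    stop("reference taxon '", ref, "' absent from block")
  inf <- block@info[ref, ]
  if (inf$strand != "+")
    stop("reference row must be on the forward strand")
  keep <- which(block@aln[ref, ] != "-")
  groupStats <- function(taxaSet) {
    present_taxa <- intersect(taxaSet, rownames(block@aln))
    mat <- block@aln[present_taxa, keep, drop = FALSE]
    mat[] <- toupper(mat)
    present <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
    .group_counts(mat, present)
  }
  fo <- groupStats(focalTaxa(partition))
  og <- groupStats(outgroupTaxa(partition))
  new("SimilarityTrack",
      refSeqname = sub("^[^.]*\\.", "", inf$src),
      refStart = as.integer(inf$start),
      focalSim = fo$sim, outgroupSim = og$sim,
      focalPresent = fo$present, outgroupPresent = og$present,
      nFocal = length(focalTaxa(partition)),
      nOutgroup = length(outgroupTaxa(partition)))
}

#' Call lineage-specific conserved noncoding elements from a track
#'
#' A site qualifies when at least `minPresent` focal species align a base
#' there, the focal similarity reaches `tauFocal`, and the outgroup
#' condition holds: no outgroup base at all (`outgroupMode = "absent"`),
#' or outgroup similarity at most `tauOutgroup` (or no outgroup present)
#' under `"low_similarity"`. Maximal runs of qualifying sites (allowing up
#' to `maxJoinGap` non-qualifying sites inside a run) become elements;
#' elements shorter than `minLen` (default 20 bp) are removed.
#'
#' @param track a [SimilarityTrack-class] or a list of tracks.
#' @param minPresent minimum focal species aligning a base (default 9,
#'   i.e. "more than eight").
#' @param tauFocal focal similarity threshold (default 0.8).
#' @param outgroupMode `"absent"` or `"low_similarity"`.
#' @param tauOutgroup outgroup similarity ceiling for
#'   `"low_similarity"` mode.
#' @param minLen minimum element length in bp.
#' @param maxJoinGap maximum run of non-qualifying sites bridged inside an
#'   element (default 0: strict contiguity).
#' @return A `GRanges` of elements on the reference (sorted, disjoint)
#'   with metadata columns `name`, `score` (1000 x mean focal similarity,
#'   rounded), `meanFocalSim`, `minFocalPresent`.
#' @export
callElements <- function(track, minPresent = 9, tauFocal = 0.8,
                         outgroupMode = c("absent", "low_similarity"),
                         tauOutgroup = 0.5, minLen = 20, maxJoinGap = 0) {
  outgroupMode <- match.arg(outgroupMode)
  if (is.list(track)) {
    grl <- lapply(track, callElements, minPresent = minPresent,
                  tauFocal = tauFocal, outgroupMode = outgroupMode,
                  tauOutgroup = tauOutgroup, minLen = minLen,
                  maxJoinGap = maxJoinGap)
    out <- sort(do.call(c, grl))
    out$name <- sprintf("scne_%d", seq_along(out))
    return(out)
  }
  stopifnot(is(track, "SimilarityTrack"))
  if (minPresent > track@nFocal)
    stop("minPresent (", minPresent, ") exceeds focal group size (",
         track@nFocal, ")")
  q <- track@focalPresent >= minPresent &
       !is.na(track@focalSim) & track@focalSim >= tauFocal
  q <- q & if (outgroupMode == "absent") {
    track@outgroupPresent == 0L
  } else {
    track@outgroupPresent == 0L |
      (!is.na(track@outgroupSim) & track@outgroupSim <= tauOutgroup)
  }
  if (maxJoinGap > 0) {
    r <- rle(q)
    inside <- !r$values & r$lengths <= maxJoinGap &
      seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[inside] <- TRUE
    q <- inverse.rle(r)
  }
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  if (!any(keep))
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  name = character(0), score = integer(0),
                                  meanFocalSim = numeric(0),
                                  minFocalPresent = integer(0)))
  s <- starts[keep]; e <- ends[keep]
  meanSim <- mapply(function(a, b) mean(track@focalSim[a:b]), s, e)
  minPres <- mapply(function(a, b) min(track@focalPresent[a:b]), s, e)
  GenomicRanges::GRanges(
    track@refSeqname,
    IRanges::IRanges(start = track@refStart + s, end = track@refStart + e),
    name = sprintf("scne_%d", seq_along(s)),
    score = as.integer(round(1000 * meanSim)),
    meanFocalSim = meanSim,
    minFocalPresent = as.integer(minPres))
}

#' Remove coding overlap from called elements
#'
#' Clips each element against the union of CDS intervals, re-filters the
#' fragments by `minLen`, and returns them sorted and non-overlapping.
#' Fragments inherit the statistics of their parent element. An empty mask
#' is the identity.
#'
#' @param elements `GRanges` from [callElements()].
#' @param cds `GRanges` of coding intervals on the same reference.
#' @param minLen minimum fragment length kept (default 20 bp).
#' @return A `GRanges` of noncoding fragments.
#' @export
subtractMask <- function(elements, cds, minLen = 20) {
  if (length(cds) == 0L || length(elements) == 0L) return(sort(elements))
  frag <- GenomicRanges::setdiff(elements, GenomicRanges::reduce(cds),
                                 ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(frag, elements)
  frag <- frag[S4Vectors::queryHits(hit)]
  S4Vectors::mcols(frag) <- S4Vectors::mcols(elements)[
    S4Vectors::subjectHits(hit), , drop = FALSE]
  frag <- frag[GenomicRanges::width(frag) >= minLen]
  frag <- sort(frag)
  if (length(frag)) frag$name <- sprintf("scne_%d", seq_along(frag))
  frag
}
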