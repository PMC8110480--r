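#' @useDynLib lineagescan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats optim pchisq pnorm rexp rpois runif setNames rmultinom
#' @importFrom utils head tail
NULL

.ALPHABETS <- c("nucleotide", "amino_acid", "codon")

## symbols treated as missing by downstream scans (beyond the gap '-')
.NT_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U", "?")
.AA_AMBIG <- c("X", "B", "Z", "J", "U", "O", "*", "?")

#' Columnar multiple sequence alignment
#'
#' A light container for a columnar alignment: one row per taxon, one column
#' per site (or per codon when `alphabet = "codon"`, in which case each cell
#' is a three-letter codon string). The gap symbol is `-` (`---` for codons).
#'
#' @slot seqs character matrix, rows named by taxon.
#' @slot alphabet one of `"nucleotide"`, `"amino_acid"`, `"codon"`.
#'
#' @export
setClass("LineageAlignment",
  representation(seqs = "matrix", alphabet = "character"),
  validity = function(object) {
    m <- object@seqs
    if (!is.character(m)) return("'seqs' must be a character matrix")
    if (nrow(m) < 2L) return("alignment needs >= 2 taxa")
    tx <- rownames(m)
    if (is.null(tx) || anyDuplicated(tx) || any(tx == ""))
      return("taxon names must be present and unique")
    if (length(object@alphabet) != 1L ||
        !object@alphabet %in% .ALPHABETS)
      return(sprintf("alphabet must be one of %s",
                     paste(.ALPHABETS, collapse = ", ")))
    TRUE
  })

#' Focal-lineage / outgroup partition of taxa
#'
#' Every lineage-specific scan conditions on this split: the focal clade
#' (e.g. the Pleuronectoidei species in a flatfish data set) versus the
#' declared outgroup taxa. Taxa on the tree that belong to neither set are
#' allowed; they are ignored by the scans but still inform ancestral-state
#' reconstruction.
#'
#' @slot focal character vector of focal taxon ids (>= 2).
#' @slot outgroup character vector of outgroup taxon ids (>= 1).
#'
#' @export
setClass("LineagePartition",
  representation(focal = "character", outgroup = "character"),
  validity = function(object) {
    if (length(object@focal) < 2L) return("need >= 2 focal taxa")
    if (length(object@outgroup) < 1L) return("need >= 1 outgroup taxon")
    if (length(intersect(object@focal, object@outgroup)))
      return("focal and outgroup sets must be disjoint")
    if (anyDuplicated(c(object@focal, object@outgroup)))
      return("duplicated taxon ids in partition")
    TRUE
  })

#' Reference-anchored alignment block (MAF-style)
#'
#' One block of a multiple whole-genome alignment: aligned rows keyed by
#' taxon plus per-row source coordinates. Coordinates in `info` are
#' forward-strand 0-based half-open starts on the source sequence,
#' regardless of the strand the MAF row was written on.
#'
#' @slot aln character matrix of aligned rows (with gaps), rownames = taxon.
#' @slot info data.frame with one row per alignment row: `src` (full source
#'   sequence name), `start` (forward-strand 0-based), `size` (ungapped
#'   length), `strand` (`+`/`-`), `srcSize`.
#' @slot ref taxon id of the reference row.
#'
#' @export
setClass("AlignmentBlock",
  representation(aln = "matrix", info = "data.frame", ref = "character"),
  validity = function(object) {
    if (nrow(object@aln) < 1L) return("empty block")
    if (nrow(object@info) != nrow(object@aln))
      return("info rows must match alignment rows")
    need <- c("src", "start", "size", "strand", "srcSize")
    if (!all(need %in% names(object@info)))
      return(sprintf("info needs columns %s", paste(need, collapse = ", ")))
    if (!object@ref %in% rownames(object@aln))
      return("reference taxon absent from block")
    TRUE
  })

#' Per-site similarity track over a reference-anchored block
#'
#' For each (gap-free) reference position: the mean pairwise identity among
#' present focal rows, the same for outgroup rows, and the counts of present
#' members per group. Similarity is `NA` (sentinel) where fewer than two
#' group members align.
#'
#' @slot refSeqname reference source sequence name (chromosome/scaffold).
#' @slot refStart forward-strand 0-based start of the track on the reference.
#' @slot focalSim,outgroupSim numeric per-site similarity in \[0,1\] or NA.
#' @slot focalPresent,outgroupPresent integer per-site present-member counts.
#' @slot nFocal,nOutgroup group sizes.
#'
#' @export
setClass("SimilarityTrack",
  representation(refSeqname = "character", refStart = "integer",
                 focalSim = "numeric", outgroupSim = "numeric",
                 focalPresent = "integer", outgroupPresent = "integer",
                 nFocal = "integer", nOutgroup = "integer"),
  validity = function(object) {
    n <- length(object@focalSim)
    if (length(object@outgroupSim) != n ||
        length(object@focalPresent) != n ||
        length(object@outgroupPresent) != n)
      return("track arrays must have equal length")
    if (any(object@focalPresent > object@nFocal) ||
        any(object@outgroupPresent > object@nOutgroup))
      return("present counts exceed group sizes")
    ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
    if (!ok(object@focalSim) || !ok(object@outgroupSim))
      return("similarities must lie in [0,1] or be NA")
    TRUE
  })

#' Branch-model (two-ratio) fit of the GY94 codon model
#'
#' Holds the one-ratio (M0) and two-ratio branch-model maximum-likelihood
#' fits for one gene: omega0 is the foreground (appointed-branch) dN/dS,
#' omega1 the background dN/dS, omega2 the whole-tree dN/dS from the M0 fit.
#'
#' @slot omega0,omega1,omega2,kappa numeric parameter estimates.
#' @slot lnLBranch,lnLM0 log-likelihoods of the two-ratio and one-ratio fits.
#' @slot converged logical.
#' @slot nCodons integer.
#' @slot scale fitted global branch-length scale of the two-ratio model.
#'
#' @export
setClass("BranchModelFit",
  representation(omega0 = "numeric", omega1 = "numeric", omega2 = "numeric",
                 kappa = "numeric", lnLBranch = "numeric", lnLM0 = "numeric",
                 converged = "logical", nCodons = "integer",
                 scale = "numeric"),
  validity = function(object) {
    if (object@lnLBranch < object@lnLM0 - 1e-6)
      return("two-ratio lnL below nested one-ratio lnL")
    if (any(c(object@omega0, object@omega1, object@omega2) < 0))
      return("omega estimates must be non-negative")
    if (object@kappa <= 0) return("kappa must be positive")
    TRUE
  })

## ---- constructors ----

#' Build a LineageAlignment from a character matrix
#'
#' @param seqs character matrix with unique rownames (taxa); for
#'   `alphabet = "codon"` each cell is a codon string such as `"ATG"`.
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `"codon"`.
#' @return A [LineageAlignment-class] object.
#' @export
LineageAlignment <- function(seqs, alphabet) {
  seqs[] <- toupper(seqs)
  new("LineageAlignment", seqs = seqs, alphabet = alphabet)
}

#' Build a LineagePartition
#'
#' @param focal character vector of focal (foreground-clade) taxon ids.
#' @param outgroup character vector of outgroup taxon ids.
#' @return A [LineagePartition-class] object.
#' @examples
#' LineagePartition(c("f1", "f2", "f3"), c("o1", "o2"))
#' @export
LineagePartition <- function(focal, outgroup) {
  new("LineagePartition", focal = as.character(focal),
      outgroup = as.character(outgroup))
}

## ---- accessors & methods ----

#' @describeIn LineageAlignment-class taxon ids, in row order.
#' @param x,object a `LineageAlignment`.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname LineageAlignment-class
#' @export
setMethod("taxa", "LineageAlignment", function(x) rownames(x@seqs))

#' @describeIn LineageAlignment-class the declared alphabet tag.
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname LineageAlignment-class
#' @export
setMethod("alphabet", "LineageAlignment", function(x) x@alphabet)

#' @rdname LineageAlignment-class
#' @export
setMethod("dim", "LineageAlignment", function(x) dim(x@seqs))

#' @rdname LineageAlignment-class
#' @export
setMethod("as.matrix", "LineageAlignment", function(x) x@seqs)

setMethod("show", "LineageAlignment", function(object) {
  cat(sprintf("LineageAlignment: %d taxa x %d %s columns\n",
              nrow(object@seqs), ncol(object@seqs),
              switch(object@alphabet, codon = "codon",
                     nucleotide = "nucleotide", amino_acid = "amino-acid")))
  cat("  taxa:", paste(head(taxa(object), 6), collapse = ", "),
      if (nrow(object@seqs) > 6) "..." else "", "\n")
})

#' @describeIn LineagePartition-class focal taxon ids.
#' @param x,object a `LineagePartition`.
#' @export
setGeneric("focalTaxa", function(x) standardGeneric("focalTaxa"))

#' @rdname LineagePartition-class
#' @export
setMethod("focalTaxa", "LineagePartition", function(x) x@focal)

#' @describeIn LineagePartition-class outgroup taxon ids.
#' @export
setGeneric("outgroupTaxa", function(x) standardGeneric("outgroupTaxa"))

#' @rdname LineagePartition-class
#' @export
setMethod("outgroupTaxa", "LineagePartition", function(x) x@outgroup)

setMethod("show", "LineagePartition", function(object) {
  cat(sprintf("LineagePartition: %d focal vs %d outgroup taxa\n",
              length(object@focal), length(object@outgroup)))
})

setMethod("show", "AlignmentBlock", function(object) {
  cat(sprintf("AlignmentBlock: %d rows x %d aligned columns, ref = %s (%s:%d)\n",
              nrow(object@aln), ncol(object@aln), object@ref,
              object@info$src[match(object@ref, rownames(object@aln))],
              object@info$start[match(object@ref, rownames(object@aln))]))
})

#' @rdname SimilarityTrack-class
#' @param x a `SimilarityTrack`.
#' @export
setMethod("length", "SimilarityTrack", function(x) length(x@focalSim))

setMethod("show", "SimilarityTrack", function(object) {
  cat(sprintf(
    "SimilarityTrack on %s:%d-%d (%d focal, %d outgroup taxa)\n",
    object@refSeqname, object@refStart,
    object@refStart + length(object), object@nFocal, object@nOutgroup))
})

setMethod("show", "BranchModelFit", function(object) {
  cat("GY94 branch-model fit\n")
  cat(sprintf("  omega0 (foreground) = %.4f\n", object@omega0))
  cat(sprintf("  omega1 (background) = %.4f\n", object@omega1))
  cat(sprintf("  omega2 (whole tree) = %.4f\n", object@omega2))
  cat(sprintf("  kappa = %.3f, lnL(two-ratio) = %.3f, lnL(M0) = %.3f\n",
              object@kappa, object@lnLBranch, object@lnLM0))
  cat(sprintf("  %d codons, converged: %s\n", object@nCodons,
              object@converged))
})

## internal: the per-alphabet symbol sets
.missing_symbols <- function(alphabet) {
  switch(alphabet,
         nucleotide = .NT_AMBIG,
         amino_acid = .AA_AMBIG,
         codon = character(0))
}

## TRUE where a cell is gap or ambiguous for scanning purposes
.is_missing <- function(m, alphabet) {
  if (alphabet == "codon") {
    m == "---" | grepl("[^ACGT]", m)
  } else {
    m == "-" | matrix(m %in% .missing_symbols(alphabet), nrow = nrow(m))
  }
}
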