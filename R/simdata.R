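#' Simulate a species tree with a monophyletic focal clade
#'
#' Pure-birth topology for the focal clade, with outgroups attached as
#' successive sisters outside it; every branch length is an independent
#' exponential draw scaled by `branchScale`. The focal clade is
#' monophyletic by construction and the returned partition matches the
#' tree.
#'
#' @param nFocal number of focal-clade tips (>= 2), labelled `f1..`.
#' @param nOutgroup number of outgroup tips (>= 1), labelled `o1..`.
#' @param branchScale mean branch length (expected substitutions/site).
#' @param seed RNG seed (deterministic output per seed).
#' @return list(tree = `ape::phylo`, partition = [LineagePartition-class]).
#' @examples
#' sim <- simulateTree(3, 2, 0.1, seed = 7)
#' ape::is.monophyletic(sim$tree, focalTaxa(sim$partition))
#' @export
simulateTree <- function(nFocal, nOutgroup, branchScale = 0.1, seed = NULL) {
  if (nFocal < 2) stop("need nFocal >= 2")
  if (nOutgroup < 1) stop("need nOutgroup >= 1")
  if (branchScale <= 0) stop("branchScale must be positive")
  if (!is.null(seed)) set.seed(seed)
  ft <- ape::rphylo(nFocal, birth = 1, death = 0)
  ft$tip.label <- paste0("f", seq_len(nFocal))
  ft$edge.length <- NULL
  s <- sub(";$", "", ape::write.tree(ft))
  for (i in seq_len(nOutgroup)) s <- sprintf("(%s,o%d)", s, i)
  tr <- ape::read.tree(text = paste0(s, ";"))
  tr$edge.length <- rexp(nrow(tr$edge)) * branchScale
  list(tree = tr,
       partition = LineagePartition(paste0("f", seq_len(nFocal)),
                                    paste0("o", seq_len(nOutgroup))))
}

#' Simulate a codon alignment under GY94 with branch-specific omega
#'
#' Evolves in-frame codon sequences site-independently down the tree under
#' the same GY94 process the likelihood code uses: states are sampled per
#' branch from the exact transition matrix `exp(Qt)` (spectral form), so no
#' stop codons can arise. Branches inside (and leading to) the focal clade
#' use `omegaFg`, the rest `omegaBg`; with `partition = NULL` the whole
#' tree uses `omegaBg`.
#'
#' @param tree rooted `ape::phylo` with branch lengths (substitutions per
#'   codon site).
#' @param partition [LineagePartition-class] or NULL.
#' @param kappa transition/transversion rate ratio.
#' @param omegaFg,omegaBg foreground / background dN/dS.
#' @param nCodons number of codon sites.
#' @param codonFreqs length-61 equilibrium frequencies (sum to 1 within
#'   1e-9); default equal.
#' @param seed RNG seed.
#' @return list(alignment = codon [LineageAlignment-class],
#'   truth = list of generating parameters plus the root codon sequence).
#' @export
simulateCodonAlignment <- function(tree, partition = NULL, kappa = 2,
                                   omegaFg = NULL, omegaBg = 0.2,
                                   nCodons = 500,
                                   codonFreqs = rep(1 / 61, 61),
                                   seed = NULL) {
  if (nCodons <= 0) stop("nCodons must be positive")
  if (abs(sum(codonFreqs) - 1) > 1e-9)
    stop("codon frequencies must sum to 1")
  if (kappa <= 0 || omegaBg < 0 || (!is.null(omegaFg) && omegaFg < 0))
    stop("kappa must be > 0 and omegas >= 0")
  if (!is.null(seed)) set.seed(seed)
  fg <- if (!is.null(partition)) foregroundEdges(tree, partition)
        else integer(0)
  if (length(fg) && is.null(omegaFg))
    stop("omegaFg required when a partition is given")
  eig <- list(bg = .gy94_eigen(kappa, omegaBg, codonFreqs))
  if (length(fg)) eig$fg <- .gy94_eigen(kappa, omegaFg, codonFreqs)
  tr <- stats::reorder(tree, "postorder")
  nTip <- ape::Ntip(tr)
  nNode <- nTip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  states <- matrix(NA_integer_, nNode, nCodons)
  states[root, ] <- sample.int(61, nCodons, replace = TRUE,
                               prob = codonFreqs)
  for (e in rev(seq_len(nrow(tr$edge)))) {       # preorder
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    cls <- if (child %in% fg) "fg" else "bg"
    P <- .pmat(eig[[cls]], tr$edge.length[e])
    ps <- states[parent, ]
    cs <- integer(nCodons)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(61, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[child, ] <- cs
  }
  m <- matrix(.GC$codons[states[seq_len(nTip), ]], nrow = nTip,
              dimnames = list(tr$tip.label, NULL))
  list(alignment = LineageAlignment(m, "codon"),
       truth = list(kappa = kappa, omegaFg = omegaFg, omegaBg = omegaBg,
                    nCodons = nCodons,
                    rootCodons = .GC$codons[states[root, ]],
                    foreground = fg, tree = tr))
}

#' Plant lineage-specific substitutions into an alignment
#'
#' Picks `nSites` columns that are currently invariant (same non-gap,
#' non-ambiguous symbol in every row), and at each sets all focal rows to a
#' new symbol while outgroup (and any other) rows keep the original state —
#' the signature of a substitution fixed on the focal stem.
#'
#' @param aln a [LineageAlignment-class] (nucleotide or amino-acid).
#' @param partition a [LineagePartition-class].
#' @param nSites number of columns to plant.
#' @param seed RNG seed.
#' @return list(alignment = modified alignment, truth = data.frame with
#'   `column`, `focalState`, `ancestralState`).
#' @export
plantLsg <- function(aln, partition, nSites, seed = NULL) {
  stopifnot(is(aln, "LineageAlignment"))
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(aln)
  miss <- .is_missing(m, alphabet(aln))
  invariant <- which(vapply(seq_len(ncol(m)), function(j) {
    !any(miss[, j]) && length(unique(m[, j])) == 1L
  }, logical(1)))
  if (nSites == 0L)
    return(list(alignment = aln,
                truth = data.frame(column = integer(0),
                                   focalState = character(0),
                                   ancestralState = character(0))))
  if (length(invariant) < nSites)
    stop("insufficient invariant columns: have ", length(invariant),
         ", need ", nSites)
  cols <- sort(sample(invariant, nSites))
  pool <- switch(alphabet(aln),
                 nucleotide = c("A", "C", "G", "T"),
                 amino_acid = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 codon = .GC$codons)
  anc <- m[1, cols]
  newState <- vapply(anc, function(a) sample(setdiff(pool, a), 1L),
                     character(1))
  foc <- match(focalTaxa(partition), rownames(m))
  if (anyNA(foc)) stop("focal taxa absent from alignment")
  for (i in seq_along(cols)) m[foc, cols[i]] <- newState[i]
  list(alignment = LineageAlignment(m, alphabet(aln)),
       truth = data.frame(column = cols, focalState = unname(newState),
                          ancestralState = unname(anc),
                          stringsAsFactors = FALSE))
}

#' Simulate a reference-anchored noncoding region with planted elements
#'
#' Emits one MAF-style [AlignmentBlock-class] over all partition taxa
#' (reference = first focal taxon). Inside each planted element, focal rows
#' are near-identical copies of the reference (per-row per-site divergence
#' `elementDivergence`, so expected per-site identity is well above 0.95)
#' while outgroup rows are gapped out (`mode = "outgroup_absent"`) or fully
#' randomized (`mode = "outgroup_diverged"`). Outside elements every
#' non-reference row diverges from the reference at `backgroundDivergence`
#' per site.
#'
#' @param partition a [LineagePartition-class].
#' @param regionLen region length in bp.
#' @param elements data.frame with columns `start` (0-based, on the
#'   reference), `len`, `mode` (`"outgroup_absent"` or
#'   `"outgroup_diverged"`). Overlapping or out-of-range elements are
#'   rejected.
#' @param backgroundDivergence per-site substitution probability outside
#'   elements (default 0.3).
#' @param elementDivergence per-row per-site substitution probability
#'   inside elements for non-reference focal rows (default 0.005).
#' @param refSeqname reference sequence (chromosome) name.
#' @param refStart 0-based start of the region on the reference.
#' @param seed RNG seed.
#' @return list(blocks = list of one [AlignmentBlock-class],
#'   truth = list(elements = `GRanges` of planted intervals with a `mode`
#'   column, params)).
#' @export
simulateCneRegion <- function(partition, regionLen = 1000,
                              elements = data.frame(start = 100, len = 30,
                                                    mode = "outgroup_absent"),
                              backgroundDivergence = 0.3,
                              elementDivergence = 0.005,
                              refSeqname = "scaf1", refStart = 0,
                              seed = NULL) {
  stopifnot(is(partition, "LineagePartition"))
  if (nrow(elements)) {
    if (any(elements$start < 0) ||
        any(elements$start + elements$len > regionLen))
      stop("element beyond region bounds")
    o <- order(elements$start)
    e <- elements[o, ]
    if (nrow(e) > 1 &&
        any(e$start[-1] < (e$start + e$len)[-nrow(e)]))
      stop("overlapping element specs")
    if (!all(e$mode %in% c("outgroup_absent", "outgroup_diverged")))
      stop("unknown element mode")
    elements <- e
  }
  if (!is.null(seed)) set.seed(seed)
  foc <- focalTaxa(partition); out <- outgroupTaxa(partition)
  taxa <- c(foc, out)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, regionLen, replace = TRUE)
  inElem <- rep(FALSE, regionLen)
  for (i in seq_len(nrow(elements)))
    inElem[(elements$start[i] + 1):(elements$start[i] + elements$len[i])] <- TRUE
  mutate <- function(x, p) {
    hit <- runif(length(x)) < p
    if (any(hit))
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    x
  }
  m <- matrix("", length(taxa), regionLen, dimnames = list(taxa))
  m[foc[1], ] <- ref
  for (tx in foc[-1]) {
    row <- ref
    row[!inElem] <- mutate(ref[!inElem], backgroundDivergence)
    row[inElem] <- mutate(ref[inElem], elementDivergence)
    m[tx, ] <- row
  }
  for (tx in out) {
    row <- ref
    row[!inElem] <- mutate(ref[!inElem], backgroundDivergence)
    for (i in seq_len(nrow(elements))) {
      span <- (elements$start[i] + 1):(elements$start[i] + elements$len[i])
      row[span] <- if (elements$mode[i] == "outgroup_absent") "-"
                   else sample(bases, length(span), replace = TRUE)
    }
    m[tx, ] <- row
  }
  info <- data.frame(
    src = paste(taxa, refSeqname, sep = "."),
    start = c(refStart, rep(0, length(taxa) - 1L)),
    size = as.integer(rowSums(m != "-")),
    strand = "+",
    srcSize = as.integer(refStart + regionLen + 1000L),
    row.names = taxa, stringsAsFactors = FALSE)
  block <- new("AlignmentBlock", aln = m, info = info, ref = foc[1])
  truthGr <- GenomicRanges::GRanges(
    refSeqname,
    IRanges::IRanges(start = refStart + elements$start + 1L,
                     width = elements$len),
    mode = if (nrow(elements)) elements$mode else character(0))
  list(blocks = list(block),
       truth = list(elements = truthGr,
                    params = list(backgroundDivergence = backgroundDivergence,
                                  elementDivergence = elementDivergence,
                                  regionLen = regionLen)))
}

#' Simulate a k-mer depth histogram
#'
#' Each of the `G` genomic k-mers receives a zero-truncated
#' Poisson(`coverage`) depth, so `sum(count)` equals `G` exactly when no
#' error k-mers are added. Error k-mers (sequencing-error artifacts)
#' concentrate at depth 1-2; their number is `round(G *
#' errorKmerFraction)`.
#'
#' @param G genome size (number of distinct genomic k-mers).
#' @param coverage mean k-mer depth.
#' @param errorKmerFraction error k-mers as a fraction of `G` (default 0).
#' @param k k-mer size tag carried on the histogram (default 17).
#' @param seed RNG seed.
#' @return data.frame(depth, count) with attribute `k`.
#' @export
simulateKmerHistogram <- function(G, coverage, errorKmerFraction = 0,
                                  k = 17, seed = NULL) {
  if (G <= 0) stop("G must be positive")
  if (coverage <= 0) stop("coverage must be positive")
  if (!is.null(seed)) set.seed(seed)
  d <- rpois(G, coverage)
  while (any(d == 0L)) d[d == 0L] <- rpois(sum(d == 0L), coverage)
  if (errorKmerFraction > 0) {
    nerr <- round(G * errorKmerFraction)
    d <- c(d, sample(1:2, nerr, replace = TRUE, prob = c(0.8, 0.2)))
  }
  tab <- tabulate(d)
  keep <- tab > 0L
  hist <- data.frame(depth = seq_along(tab)[keep], count = tab[keep])
  attr(hist, "k") <- k
  hist
}
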