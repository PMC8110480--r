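#' GY94 phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over the 61 sense codons, with branch-specific
#' omega classes. Gap and ambiguous codons are missing data (partial
#' likelihood 1 over all states). Site patterns are compressed before the
#' pruning pass.
#'
#' @param aln a codon [LineageAlignment-class]; its taxa must match the
#'   tree's tips.
#' @param tree rooted `ape::phylo` with branch lengths (expected
#'   substitutions per codon site).
#' @param kappa transition/transversion rate ratio.
#' @param omega background (or single-ratio) dN/dS.
#' @param codonFreqs length-61 equilibrium frequencies ([senseCodons()]
#'   order); default equal.
#' @param foreground child-node ids of foreground edges (as returned by
#'   [foregroundEdges()]); empty for a single-ratio model.
#' @param omegaFg foreground dN/dS; required when `foreground` is non-empty.
#' @param scale global branch-length multiplier.
#' @return The total log-likelihood (numeric scalar) with attribute
#'   `"siteLnL"` carrying per-column site log-likelihoods.
#' @export
codonLoglik <- function(aln, tree, kappa, omega,
                        codonFreqs = rep(1 / 61, 61),
                        foreground = integer(0), omegaFg = NULL,
                        scale = 1) {
  stopifnot(is(aln, "LineageAlignment"), alphabet(aln) == "codon")
  if (length(foreground) && is.null(omegaFg))
    stop("omegaFg required when foreground edges are given")
  prep <- .loglik_prep(aln, tree)
  patLnL <- .codon_pat_lnl(prep, kappa, omega, codonFreqs, foreground,
                           omegaFg, scale)
  if (any(!is.finite(patLnL))) {
    bad <- which(prep$patIndex == which(!is.finite(patLnL))[1])[1]
    stop("non-finite site log-likelihood at codon column ", bad)
  }
  lnL <- sum(patLnL * prep$weights)
  attr(lnL, "siteLnL") <- patLnL[prep$patIndex]
  lnL
}

## pattern log-likelihoods from a precomputed prep (hot path for the fits)
.codon_pat_lnl <- function(prep, kappa, omega, codonFreqs,
                           foreground = integer(0), omegaFg = NULL,
                           scale = 1) {
  eig <- list(.gy94_eigen(kappa, omega, codonFreqs))
  eclass <- rep(1L, nrow(prep$edge))
  if (length(foreground)) {
    eig[[2]] <- .gy94_eigen(kappa, omegaFg, codonFreqs)
    eclass[prep$edge[, 2] %in% foreground] <- 2L
  }
  codon_loglik_patterns(prep$tipStates, prep$edge, prep$elen * scale,
                        eclass, eig, codonFreqs, prep$nNode)
}

.codon_lnl <- function(prep, ...) {
  patLnL <- .codon_pat_lnl(prep, ...)
  if (any(!is.finite(patLnL))) return(-Inf)
  sum(patLnL * prep$weights)
}

## shared preprocessing: taxon matching, pattern compression, postorder edges
.loglik_prep <- function(aln, tree) {
  m <- as.matrix(aln)
  if (!all(rownames(m) %in% tree$tip.label))
    stop("alignment taxa absent from tree: ",
         paste(setdiff(rownames(m), tree$tip.label), collapse = ", "))
  if (!all(tree$tip.label %in% rownames(m)))
    stop("tree tips absent from alignment: ",
         paste(setdiff(tree$tip.label, rownames(m)), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tr <- stats::reorder(tree, "postorder")
  m <- m[tr$tip.label, , drop = FALSE]
  states <- matrix(match(m, .GC$codons, nomatch = 0L), nrow = nrow(m))
  key <- apply(states, 2, paste, collapse = ".")
  uk <- unique(key)
  patIndex <- match(key, uk)
  first <- match(uk, key)
  list(tipStates = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(patIndex, nbins = length(uk))),
       patIndex = patIndex,
       edge = tr$edge, elen = tr$edge.length,
       nNode = ape::Ntip(tr) + tr$Nnode)
}
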