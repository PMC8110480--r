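#' Scan for lineage-specific fixed substitutions
#'
#' A column is a candidate lineage-specific substitution when (i) every
#' focal row carries the same non-gap, non-ambiguous symbol, (ii) at least
#' `minOutgroupPresent` outgroup rows are non-gap, and (iii) every non-gap
#' outgroup row differs from the focal symbol. Outgroups may be polymorphic
#' by default (the scan asks only that none of them matches the focal
#' state); set `outgroupMonomorphic = TRUE` to require a single outgroup
#' state as well. Focal gaps disqualify a column; outgroup gaps reduce the
#' effective outgroup count.
#'
#' @param aln a [LineageAlignment-class] (any alphabet).
#' @param partition a [LineagePartition-class]; all partition taxa must be
#'   rows of the alignment.
#' @param minOutgroupPresent minimum number of non-gap outgroup rows
#'   (default 2, avoiding single-sequence artifacts).
#' @param outgroupMonomorphic require all non-gap outgroup rows identical.
#' @param gene gene id carried into the output.
#' @return data.frame with one row per hit, sorted by column: `gene`,
#'   `column` (1-based), `focalState`, `outgroupStates` (comma-separated),
#'   `nOutgroupPresent`, plus validation placeholders `confirmed`,
#'   `pMrca`, `pParent` (filled by [validateLsg()]).
#' @export
scanLsg <- function(aln, partition, minOutgroupPresent = 2,
                    outgroupMonomorphic = FALSE, gene = NA_character_) {
  stopifnot(is(aln, "LineageAlignment"), is(partition, "LineagePartition"))
  m <- as.matrix(aln)
  missingTaxa <- setdiff(c(focalTaxa(partition), outgroupTaxa(partition)),
                         rownames(m))
  if (length(missingTaxa))
    stop("partition taxa missing from alignment: ",
         paste(missingTaxa, collapse = ", "))
  miss <- .is_missing(m, alphabet(aln))
  f <- match(focalTaxa(partition), rownames(m))
  o <- match(outgroupTaxa(partition), rownames(m))
  hits <- lapply(seq_len(ncol(m)), function(j) {
    fv <- m[f, j]
    if (any(miss[f, j])) return(NULL)
    if (length(unique(fv)) != 1L) return(NULL)
    X <- fv[1]
    opres <- !miss[o, j]
    if (sum(opres) < minOutgroupPresent) return(NULL)
    ov <- m[o, j][opres]
    if (any(ov == X)) return(NULL)
    if (outgroupMonomorphic && length(unique(ov)) != 1L) return(NULL)
    data.frame(gene = gene, column = j, focalState = X,
               outgroupStates = paste(ov, collapse = ","),
               nOutgroupPresent = sum(opres),
               confirmed = NA, pMrca = NA_real_, pParent = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(gene = character(0), column = integer(0),
                      focalState = character(0),
                      outgroupStates = character(0),
                      nOutgroupPresent = integer(0), confirmed = logical(0),
                      pMrca = numeric(0), pParent = numeric(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marginal ancestral-state reconstruction by pruning
#'
#' Computes, for every internal node and alignment column, the marginal
#' posterior distribution over states under an equal-rate (Poisson /
#' Jukes-Cantor type) substitution model with a uniform root prior, via the
#' standard inside-outside form of Felsenstein pruning. The MAP state is
#' the posterior argmax, with exact ties broken toward the
#' lexicographically smallest symbol. Gap/ambiguous cells are missing data;
#' a column that is missing in every taxon gets a uniform posterior and is
#' flagged uninformative.
#'
#' If the tree carries no branch lengths, they are estimated from the
#' alignment by least squares on multiple-hit-corrected pairwise
#' p-distances.
#'
#' @param aln a [LineageAlignment-class] (`amino_acid` or `nucleotide`).
#' @param tree rooted `ape::phylo`; its tips must cover the alignment taxa.
#' @param model `"poisson_aa"` (20-state equal-rate) or `"jc_nt"`.
#' @return An object of class `"ancestralReconstruction"`: list with
#'   `prob` (list of nStates x nColumns posterior matrices keyed by
#'   internal node id), `map` (character matrix, internal nodes x columns),
#'   `states`, `uninformative` (per-column flag), `siteLogLik` (per-column
#'   log-likelihood under the same model), `tree` (with the branch
#'   lengths actually used).
#' @export
ancestralMarginal <- function(aln, tree, model = c("poisson_aa", "jc_nt")) {
  model <- match.arg(model)
  stopifnot(is(aln, "LineageAlignment"))
  states <- switch(model,
                   poisson_aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   jc_nt = c("A", "C", "G", "T"))
  m <- as.matrix(aln)
  if (!all(rownames(m) %in% tree$tip.label))
    stop("alignment taxa absent from tree: ",
         paste(setdiff(rownames(m), tree$tip.label), collapse = ", "))
  tree <- ape::keep.tip(tree, rownames(m))
  if (is.null(tree$edge.length) || isTRUE(attr(tree, "missingLengths")) ||
      sum(tree$edge.length) == 0)
    tree$edge.length <- .estimate_blens(m, tree, length(states),
                                        alphabet(aln))
  tr <- stats::reorder(tree, "postorder")
  nTip <- ape::Ntip(tr)
  nNode <- nTip + tr$Nnode
  nCol <- ncol(m)
  nS <- length(states)
  miss <- .is_missing(m, alphabet(aln))
  m <- m[tr$tip.label, , drop = FALSE]
  miss <- miss[tr$tip.label, , drop = FALSE]

  pmat <- function(t) {
    r <- nS / (nS - 1)
    pd <- (1 - exp(-r * t)) / nS
    P <- matrix(pd, nS, nS)
    diag(P) <- 1 / nS + (1 - 1 / nS) * exp(-r * t)
    P
  }
  tipL <- function(i) {
    L <- matrix(0, nS, nCol)
    s <- match(m[i, ], states)
    for (j in seq_len(nCol)) {
      if (miss[i, j] || is.na(s[j])) L[, j] <- 1 else L[s[j], j] <- 1
    }
    L
  }

  L <- vector("list", nNode)      # inside partials
  Dn <- vector("list", nNode)     # per-child message P %*% L[child]
  Pe <- vector("list", nNode)     # P matrix of the edge above each node
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    if (child <= nTip) L[[child]] <- tipL(child)
    P <- pmat(tr$edge.length[e])
    Pe[[child]] <- P
    Dn[[child]] <- P %*% L[[child]]
    L[[parent]] <- if (is.null(L[[parent]])) Dn[[child]]
                   else L[[parent]] * Dn[[child]]
  }
  root <- tr$edge[nrow(tr$edge), 1]

  Up <- vector("list", nNode)     # outside partials (include root prior)
  Up[[root]] <- matrix(1 / nS, nS, nCol)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    sibs <- setdiff(children[[as.character(parent)]], child)
    M <- Up[[parent]]
    for (s2 in sibs) M <- M * Dn[[s2]]
    Up[[child]] <- crossprod(Pe[[child]], M)
  }

  internal <- (nTip + 1L):nNode
  uninformative <- apply(miss, 2, all)
  siteLogLik <- log(colSums(L[[root]]) / nS)   # uniform root prior
  prob <- list()
  map <- matrix("", length(internal), nCol,
                dimnames = list(as.character(internal), NULL))
  for (n in internal) {
    post <- L[[n]] * Up[[n]]
    tot <- colSums(post)
    bad <- tot <= 0
    post[, !bad] <- sweep(post[, !bad, drop = FALSE], 2, tot[!bad], "/")
    post[, bad] <- 1 / nS
    rownames(post) <- states
    prob[[as.character(n)]] <- post
    map[as.character(n), ] <- states[apply(post, 2, which.max)]
  }
  structure(list(prob = prob, map = map, states = states,
                 uninformative = uninformative, siteLogLik = siteLogLik,
                 tree = tr, model = model),
            class = "ancestralReconstruction")
}

#' @export
print.ancestralReconstruction <- function(x, ...) {
  cat(sprintf(
    "Marginal ancestral reconstruction (%s): %d internal nodes x %d columns\n",
    x$model, nrow(x$map), ncol(x$map)))
  invisible(x)
}

## least-squares branch lengths from corrected pairwise distances
.estimate_blens <- function(m, tree, nStates, alphabet) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  miss <- .is_missing(m, alphabet)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !miss[i, ] & !miss[j, ]
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    pmaxv <- 1 - 1 / nStates
    p <- min(p, pmaxv - 1e-6)
    d[i, j] <- d[j, i] <- -(1 - 1 / nStates) * log(1 - p / pmaxv)
  }
  fitted <- phangorn::nnls.tree(stats::as.dist(d), tree, method = "unrooted")
  pmax(fitted$edge.length[match(paste(tree$edge[, 1], tree$edge[, 2]),
                                paste(fitted$edge[, 1], fitted$edge[, 2]))],
       0)
}

#' Validate candidate lineage-specific substitutions by ancestral states
#'
#' A hit is confirmed when the MAP ancestral state of the focal-clade MRCA
#' equals the focal state while the MAP state of the MRCA's parent does
#' not — i.e. the substitution is placed on the focal stem branch rather
#' than predating the clade or arising in the outgroups. The posterior
#' probability of the focal state at both nodes is stored on the hit.
#'
#' @param hits data.frame from [scanLsg()].
#' @param recon an `"ancestralReconstruction"` from [ancestralMarginal()]
#'   computed on a tree containing the focal MRCA and its parent.
#' @param tree the tree used for the reconstruction.
#' @param partition a [LineagePartition-class]; the focal clade must be
#'   monophyletic on `tree`.
#' @return `hits` with `confirmed`, `pMrca`, `pParent` filled in.
#' @export
validateLsg <- function(hits, recon, tree = recon$tree, partition) {
  if (!nrow(hits)) return(hits)
  if (!setequal(tree$tip.label, recon$tree$tip.label))
    stop("tree tips do not match the reconstruction's tree")
  focalMrca(tree, partition)             # errors if not monophyletic
  ## node ids must come from the reconstruction's own (possibly pruned) tree
  mrca <- focalMrca(recon$tree, partition)
  parent <- .parent_node(recon$tree, mrca)
  if (is.na(parent))
    stop("focal MRCA is the root; its ancestor is undefined")
  km <- as.character(mrca); kp <- as.character(parent)
  if (!km %in% names(recon$prob) || !kp %in% names(recon$prob))
    stop("reconstruction does not cover the focal MRCA and its parent")
  for (i in seq_len(nrow(hits))) {
    j <- hits$column[i]
    X <- hits$focalState[i]
    mapM <- recon$map[km, j]
    mapP <- recon$map[kp, j]
    hits$confirmed[i] <- (mapM == X) && (mapP != X)
    hits$pMrca[i] <- if (X %in% recon$states) recon$prob[[km]][X, j] else 0
    hits$pParent[i] <- if (X %in% recon$states) recon$prob[[kp]][X, j] else 0
  }
  hits
}
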